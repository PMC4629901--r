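# shared equilibrated states; equilibrate() memoises per session, so these
# are computed once per test run (about a second each)
normal_conditions <- cell_conditions()
normal_rest <- function() equilibrate(normal_conditions)

# small synthetic AP trace: rest -85, instant upstroke to +35 at t = 10,
# plateau to 110, linear repolarisation to -85 at 210 (closed-form APD90 = 190)
trapezoid_ap <- function(dt = 0.01) {
  tt <- seq(0, 250, by = dt)
  V <- ifelse(tt < 10, -85,
       ifelse(tt <= 110, 35,
       ifelse(tt <= 210, 35 - (tt - 110) * 1.2, -85)))
  tibble::tibble(time = tt, V = V)
}
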