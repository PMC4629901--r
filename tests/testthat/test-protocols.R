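test_that("activation detection finds debounced upward crossings", {
  rest <- tibble::tibble(time = 0:100, V = rep(-85, 101))
  expect_length(activation_times(rest), 0)
  sq <- tibble::tibble(time = seq(0, 100, by = 0.5),
                       V = c(rep(-85, 40), rep(10, 40), rep(-85, 121)))
  a <- activation_times(sq)
  expect_length(a, 1)
  expect_equal(a, 20)                     # first sample at/above threshold
  # rapid double crossing within the refractory window counts once
  jitter <- tibble::tibble(time = seq(0, 60, by = 1),
                           V = c(rep(-85, 10), 10, -85, 10,
                                 rep(-85, 48)))
  expect_length(activation_times(jitter, refractory = 50), 1)
})

test_that("APD90 matches the closed form on an idealised trapezoid AP", {
  tr <- trapezoid_ap()
  expect_equal(apd90(tr), 190, tolerance = 0.01)
  expect_equal(apd90(tr, activation_time = 10), 190, tolerance = 0.01)
  short <- tr[tr$time < 150, ]            # ends mid-plateau
  expect_true(is.na(apd90(short)))
  expect_true(attr(apd90(short), "incomplete"))
})

test_that("pacing schedules engage the 5 ms ramp only below the 2.7 Hz period", {
  t1 <- protocol_times(pacing_protocol(1000, n_stimuli = 7))
  expect_equal(attr(t1, "first_held"), 1L)
  expect_equal(diff(t1), rep(1000, 6))
  t2 <- protocol_times(pacing_protocol(300, n_stimuli = 4))
  expect_gt(attr(t2, "first_held"), 1L)
  iv <- diff(t2)
  ramp <- iv[seq_len(attr(t2, "first_held") - 1)]
  expect_true(all(abs(diff(ramp) + 5) < 1e-9))  # 5 ms per cycle decrements
  expect_lt(max(ramp), 1000 / 2.7 + 1e-9)
  expect_true(all(tail(iv, 3) == 300))
})

test_that("single-cell APD restitution has the physiological shape", {
  rc <- restitution_curve(normal_conditions, c(400, 1000, 2000, 3000),
                          n_beats = 5, n_ignore = 2)
  expect_true(all(diff(rc$apd90) > 0) || all(diff(rc$apd90) >= -0.5))
  expect_true(all(rc$apd90[rc$period >= 1000] > 250))
  # saturation far above 1000 ms
  expect_lt(abs(rc$apd90[rc$period == 3000] - rc$apd90[rc$period == 2000]), 2)
  # APD90 at 1 Hz close to the published TP06 epicardial value (~301 ms)
  expect_lt(abs(rc$apd90[rc$period == 1000] - 301), 10)
})

test_that("channel-block effects on APD have the known directions", {
  a_norm <- restitution_curve(normal_conditions, 1000, n_beats = 4,
                              n_ignore = 2)$apd90
  a_kr <- restitution_curve(cell_conditions(g_Kr = 0.25), 1000,
                            n_beats = 4, n_ignore = 2)$apd90
  a_cal <- restitution_curve(cell_conditions(g_CaL = 0.25), 1000,
                             n_beats = 4, n_ignore = 2)$apd90
  expect_gt(a_kr, a_norm)     # rapid delayed rectifier block prolongs APD
  expect_lt(a_cal, a_norm)    # L-type calcium block shortens APD
})

test_that("conduction matching classifies 1:1, n:m and full block", {
  stims <- seq(0, 3000, by = 500)
  prox <- stims + 30
  mc <- anisoblock:::match_conduction(prox, prox + 60, stims, 3, 500)
  expect_true(all(mc$conducted))
  alternans <- prox[seq(1, 7, by = 2)] + 60       # every second wave crosses
  mc2 <- anisoblock:::match_conduction(prox, alternans, stims, 3, 500)
  expect_equal(sum(mc2$conducted), 2)
  mc3 <- anisoblock:::match_conduction(prox, numeric(0), stims, 3, 500)
  expect_false(any(mc3$conducted))
})

test_that("toy fixtures drive the conduction classifier end to end", {
  ok <- toy_tissue_case("toy_pulse")$run(stim_times = c(0, 600))
  prox <- ok$probe_activations[[1]]; dist <- ok$probe_activations[[2]]
  expect_length(prox, 2); expect_length(dist, 2)
  mc <- anisoblock:::match_conduction(prox, dist, c(0, 600), 0, 600)
  expect_true(all(mc$conducted))
  blocked <- toy_tissue_case("toy_two_region")$run()
  expect_gt(length(blocked$probe_activations[[1]]), 0)
  expect_length(blocked$probe_activations[[2]], 0)
})

test_that("threshold bisection brackets a monotone transition", {
  trial <- function(x) if (x < pi) "conducted" else "blocked"
  res <- anisoblock:::bisect_threshold(trial, c(1.5, 8), tol = 0.01)
  expect_lt(abs(res$value - pi), 0.01)
  expect_true(res$lower < pi && res$upper > pi)
  expect_error(
    anisoblock:::bisect_threshold(function(x) "blocked", c(1.5, 8), 0.01),
    "sign change")
})

test_that("frequency search (scan and grid bisection) agree on synthetic outcomes", {
  fake <- function(f) if (f >= 1.7) "blocked" else "conducted"
  a <- critical_block_frequency(normal_conditions, 3, .trial = fake,
                                search = "scan")
  b <- critical_block_frequency(normal_conditions, 3, .trial = fake,
                                search = "bisect")
  expect_equal(a$f_block, 1.7); expect_equal(b$f_block, 1.7)
  expect_equal(a$f_pass, 1.6); expect_equal(b$f_pass, 1.6)
  expect_lt(nrow(b$history), nrow(a$history))
  none <- critical_block_frequency(normal_conditions, 3,
                                   .trial = function(f) "conducted")
  expect_true(is.na(none$f_block))
})

test_that("critical-period search returns a 5 ms bracket", {
  fake <- function(p) if (p >= 432) "conducted" else "blocked"
  res <- critical_period_at_ar(normal_conditions, 3, .trial = fake)
  expect_lte(res$T_pass - res$T_block, 5)
  expect_gte(res$T_pass, 432 - 5); expect_lte(res$T_block, 432)
  allpass <- critical_period_at_ar(normal_conditions, 3,
                                   .trial = function(p) "conducted")
  expect_true(is.na(allpass$T_block))
  expect_error(
    critical_period_at_ar(normal_conditions, 3,
                          .trial = function(p) "blocked"),
    "blocks")
})

test_that("T(AR) closed form: limits, frozen value, domain guard", {
  p <- fit_parameters(ar1 = 3.72, a = 307, b = 0.0014, c = 9.09, d = 0.333)
  expect_equal(evaluate_T(p, 1e-6), 307, tolerance = 1e-6)   # a as AR -> 0
  expect_gt(evaluate_T(p, 3.719999), 5000)                     # asymptote
  expect_equal(evaluate_T(p, 3.0), 340.9366148618, tolerance = 1e-9)
  expect_error(evaluate_T(p, 3.8), "AR1")
  expect_error(fit_parameters(0.9, 307, 1, 1, 1), "ar1")
})

test_that("curve fitting recovers known parameters from bracket data", {
  truth <- fit_parameters(3.72, 307, 0.0014, 9.09, 0.333)
  ars <- seq(2.2, 3.6, by = 0.2)
  Tm <- evaluate_T(truth, ars)
  pts <- tibble::tibble(AR = ars, T_pass = Tm + 2.5, T_block = Tm - 2.5)
  fit <- fit_T_curve(pts, ar1 = 3.72, a = 307)
  est <- fit$parameters
  expect_lt(abs(est$c - 9.09) / 9.09, 0.05)
  expect_lt(abs(est$d - 0.333) / 0.333, 0.10)
  expect_lt(abs(log(est$b / 0.0014)), 0.5)
  td <- tidy(fit)
  expect_equal(td$term, c("ar1", "a", "b", "c", "d"))
  expect_true(all(td$fixed[1:2]))
  expect_equal(glance(fit)$nobs, length(ars))
  # round trip through predict
  expect_equal(predict(fit, 3.0), evaluate_T(est, 3.0))
})
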