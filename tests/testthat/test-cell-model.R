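test_that("currents vanish at zero driving force and sum to I_ion", {
  st <- tp06_initial_state()
  Ek <- 26.713761 * log(5.4 / st[["K_i"]])
  st[["V"]] <- Ek
  cur <- compute_currents(st, normal_conditions)
  expect_lt(abs(cur$I_K1), 1e-5)
  expect_lt(abs(cur$I_Kr), 1e-5)
  expect_lt(abs(cur$I_pK), 1e-5)
  st[["V"]] <- -30
  cur <- compute_currents(st, normal_conditions)
  parts <- unlist(cur[setdiff(names(cur), "I_ion")])
  expect_equal(cur$I_ion, sum(parts), tolerance = 1e-12)
})

test_that("invalid states are rejected with the offending variable named", {
  st <- tp06_initial_state()
  st[["V"]] <- NaN
  expect_error(compute_currents(st, normal_conditions), "V")
  st <- tp06_initial_state(); st[["m"]] <- 1.5
  expect_error(compute_currents(st, normal_conditions), "m")
  st <- tp06_initial_state(); st[["Ca_i"]] <- -1e-5
  expect_error(compute_currents(st, normal_conditions), "Ca_i")
})

test_that("50 s equilibration reaches the quiescent resting state", {
  st <- normal_rest()
  expect_gt(st[["V"]], -88)
  expect_lt(st[["V"]], -84)
  expect_false(attr(st, "oscillating"))
  cur <- compute_currents(st, normal_conditions, dvdt_sign = -1)
  expect_lt(abs(cur$I_ion), 0.01)
})

test_that("equilibrated state matches the independent ODE reference", {
  ref <- read.csv(system.file("extdata", "tp06_reference_rest.csv",
                              package = "anisoblock"), comment.char = "#")
  st <- normal_rest()
  expect_equal(st[["V"]], ref$V, tolerance = 1e-3)
  expect_equal(st[["K_i"]], ref$K_i, tolerance = 1e-4)
  expect_equal(st[["Na_i"]], ref$Na_i, tolerance = 1e-3)
})

test_that("the equilibrium is a fixed point of the integrator", {
  st <- normal_rest()
  st2 <- step_cell(st, normal_conditions, dt = 0.01, n_steps = 200)
  expect_lt(abs(st2[["V"]] - st[["V"]]), 1e-4)
  expect_lt(max(abs(st2 - st)), 1e-4)
})

test_that("the explicit step is first-order consistent", {
  st <- normal_rest()
  st[["V"]] <- -30    # off-equilibrium point
  big <- step_cell(st, normal_conditions, dt = 0.02, n_steps = 1,
                   gates = "euler")
  small <- step_cell(st, normal_conditions, dt = 0.01, n_steps = 2,
                     gates = "euler")
  tiny <- step_cell(st, normal_conditions, dt = 0.005, n_steps = 4,
                    gates = "euler")
  e1 <- abs(big[["V"]] - tiny[["V"]])
  e2 <- abs(small[["V"]] - tiny[["V"]])
  expect_lt(e2, e1)            # error shrinks with dt
})

test_that("a stimulated AP matches the independent reference trajectory", {
  ref <- read.csv(system.file("extdata", "tp06_reference_ap.csv",
                              package = "anisoblock"), comment.char = "#")
  tr <- pace_cell(normal_conditions, pacing_protocol(1000, n_stimuli = 1),
                  record_stride = 1, tail_ms = 501)
  v <- tr$V[match(ref$time_ms, tr$time)]
  rms <- sqrt(mean((v - ref$V_mV)^2))
  expect_lt(rms, 1)            # mV, over the full AP
})

test_that("Rush-Larsen and forward-Euler gate modes agree at dt = 0.005", {
  st <- normal_rest()
  ap <- function(gm) {
    r <- run_tissue(cable_geometry(length = 2, border_x = 1),
                    build_conductivity(cable_geometry(length = 2,
                                                      border_x = 1), 1),
                    normal_conditions,
                    list(list(time = 0, nodes = 0:5)),
                    simulation_config(300, record_stride = 1,
                                      record_sites = 8L),
                    init_state = st, gates = gm)
    site_trace(r, 8L)$V
  }
  expect_lt(sqrt(mean((ap("rush_larsen") - ap("euler"))^2)), 0.5)
})

test_that("gates stay in [0,1] and concentrations positive after pacing", {
  for (cond in list(normal_conditions,
                    cell_conditions(g_CaL = 0.25),
                    cell_conditions(Ko = 10))) {
    st <- equilibrate(cond)
    tr <- pace_cell(cond, pacing_protocol(400, n_stimuli = 3), state = st,
                    tail_ms = 450)
    fin <- attr(tr, "final_state")
    st2 <- step_cell(st, cond, dt = 0.02, n_steps = 10)
    expect_true(all(st2[c("m", "h", "j", "d", "f", "f2", "fCass", "r",
                          "s", "xr1", "xr2", "xs")] >= 0))
    expect_true(all(st2[c("m", "h", "j", "d", "f", "f2", "fCass", "r",
                          "s", "xr1", "xr2", "xs")] <= 1))
    expect_true(all(st2[c("Na_i", "K_i", "Ca_i", "Ca_sr", "Ca_ss")] > 0))
  }
})

test_that("reducing g_Na never speeds up the upstroke", {
  vmax <- sapply(c(1, 0.75, 0.5, 0.25), function(g) {
    cond <- if (g == 1) normal_conditions else cell_conditions(g_Na = g)
    st <- equilibrate(cond)
    st[["V"]] <- -55          # just above threshold; lets I_Na fire
    r <- anisoblock:::tp06_run_cpp(matrix(as.numeric(st), ncol = 1), 1L, 1L,
                      numeric(0), numeric(0), 1, 0.005, 10,
                      anisoblock:::cond_cvec(cond), list(), integer(0),
                      -20, 50, 0L, 0.01, 0, 0L, 0, 0, 0L, 0L,
                      TRUE, 0L, FALSE, 1e-6, FALSE)
    max(diff(r$traces[, 1])) / 0.01
  })
  expect_true(all(diff(vmax) < 0))
})

test_that("hyperkalemia depolarises the resting potential", {
  v54 <- normal_rest()[["V"]]
  v8 <- equilibrate(cell_conditions(Ko = 8))[["V"]]
  v12 <- equilibrate(cell_conditions(Ko = 12))[["V"]]
  expect_true(v54 < v8 && v8 < v12)
})

test_that("strong inward-rectifier block leads to depolarisation and self-oscillation", {
  cond <- cell_conditions(g_K1 = 0.05)
  st <- suppressWarnings(equilibrate(cond, duration = 80))
  expect_true(attr(st, "oscillating"))
  expect_false(attr(st, "converged"))
})

test_that("I_K1 is outward with an interior peak between E_K and 0 mV", {
  st <- normal_rest()
  vs <- seq(-70, -1, by = 0.1)
  ik1 <- vapply(vs, function(v) {
    s <- st; s[["V"]] <- v
    compute_currents(s, normal_conditions)$I_K1
  }, numeric(1))
  expect_true(all(ik1 > 0))                  # outward throughout (-70, 0)
  ipk <- which.max(ik1)
  expect_gt(ipk, 1); expect_lt(ipk, length(vs))   # strict interior maximum
})
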