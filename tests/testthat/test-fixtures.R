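test_that("passive Gaussian variance grows as 2 sigma t", {
  case <- toy_tissue_case("passive_gaussian")
  r <- case$run(duration = 40, dt = 0.1)
  V <- r$frames[, ncol(r$frames)]
  x <- case$x
  mu <- sum(x * V) / sum(V)
  var_emp <- sum((x - mu)^2 * V) / sum(V)
  var_exp <- 2^2 + 2 * case$sigma * 40      # s0^2 + 2 sigma t
  expect_lt(abs(var_emp - var_exp) / var_exp, 0.01)
})

test_that("the toy kernel rests, propagates and blocks at a coupling jump", {
  # stable rest
  quiet <- toy_run(nx = 100, duration = 100, stim_nodes = integer(0),
                   stim_times = numeric(0))
  expect_lt(max(abs(quiet$u)), 1e-9)
  # propagating pulse reaches both probes in order
  ok <- toy_tissue_case("toy_pulse")$run()
  a <- ok$probe_activations
  expect_length(a[[1]], 1); expect_length(a[[2]], 1)
  expect_gt(a[[2]][1], a[[1]][1])
  # 20x coupling jump blocks it
  blk <- toy_tissue_case("toy_two_region")$run()
  expect_length(blk$probe_activations[[2]], 0)
})

test_that("steady-state library persists, caches and orders hyperkalemia", {
  dir <- tempfile("sslib")
  conds <- list(cell_conditions(),
                cell_conditions(Ko = 8),
                cell_conditions(Ko = 10),
                cell_conditions(Ko = 12))
  lib <- make_steady_state_library(conds, dir = dir)
  expect_equal(nrow(lib), 4)
  expect_true(all(file.exists(lib$file)))
  expect_gt(lib$V_rest[1], -88); expect_lt(lib$V_rest[1], -84)
  expect_true(all(diff(lib$V_rest) > 0))   # resting V rises with Ko
  expect_false(any(lib$oscillating))
  # idempotent re-run: identical bytes on disk, identical states
  md5_before <- tools::md5sum(lib$file)
  lib2 <- make_steady_state_library(conds, dir = dir)
  expect_identical(unname(tools::md5sum(lib2$file)), unname(md5_before))
  expect_equal(attr(lib2, "states")[[lib$key[1]]][["V"]],
               attr(lib, "states")[[lib$key[1]]][["V"]])
  expect_error(make_steady_state_library(list()), "non-empty")
})

test_that("cell states round-trip through the flat text format", {
  st <- tp06_initial_state()
  f <- tempfile()
  write_cell_state(st, f)
  st2 <- read_cell_state(f)
  expect_equal(as.numeric(st2), as.numeric(st), tolerance = 1e-15)
})
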