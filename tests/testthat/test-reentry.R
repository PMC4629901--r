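# synthetic space_time_record with a rotating-wave voltage pattern, so the
# detector can be validated against a known tip position and period
make_synthetic_rotor <- function(drift_mms = 0, omega = 2 * pi / 150,
                                 duration = 1200, stride = 5) {
  geom <- tissue_geometry(20, 20, h = 0.5, border_x = 10)
  ft <- seq(0, duration, by = stride)
  xs <- (0:(geom$nx - 1)) * geom$h
  ys <- (0:(geom$ny - 1)) * geom$h
  frames <- matrix(0, geom$nx * geom$ny, length(ft))
  for (k in seq_along(ft)) {
    cx <- 10; cy <- 10 + drift_mms * ft[k] / 1000
    th <- outer(xs - cx, ys - cy, function(a, b) atan2(b, a))
    frames[, k] <- as.vector(-40 + 60 * cos(th - omega * ft[k]))
  }
  structure(list(
    status = "completed", t_end = duration,
    frames = frames, frame_times = ft,
    stimuli = list(list(time = 0, nodes = 0L)),
    geometry = geom,
    probe_activations = list(proximal = numeric(0), distal = numeric(0))),
    class = "space_time_record")
}

test_that("the tracker finds a rotor, its period and its drift", {
  rec <- make_synthetic_rotor(drift_mms = 2)
  rep <- detect_and_track(rec)
  expect_true(rep$sustained)
  expect_equal(rep$period, 150, tolerance = 0.1)
  tr <- rep$trajectory
  expect_gt(nrow(tr), 50)
  expect_lt(max(abs(tr$x - 10)), 1.5)          # tip stays near the core x
  # upward drift at ~2 mm/s
  slope <- coef(lm(y ~ time, data = tr))[2] * 1000
  expect_equal(unname(slope), 2, tolerance = 0.3)
  expect_gt(mean(diff(tr$y) >= 0), 0.8)        # no reverse drift
})

test_that("a plane wave is not classified as reentry", {
  geom <- tissue_geometry(20, 20, h = 0.5, border_x = 10)
  ft <- seq(0, 600, by = 5)
  xs <- (0:(geom$nx - 1)) * geom$h
  frames <- sapply(ft, function(t) {
    prof <- ifelse(abs(xs - 0.05 * t) < 2, 20, -85)  # travelling bump
    rep(prof, times = geom$ny)
  })
  rec <- structure(list(
    status = "completed", t_end = 600, frames = frames, frame_times = ft,
    stimuli = list(list(time = 0, nodes = 0L)), geometry = geom,
    probe_activations = list(proximal = numeric(0), distal = numeric(0))),
    class = "space_time_record")
  rep <- detect_and_track(rec)
  expect_false(rep$sustained)
})

test_that("reentry protocol validates its geometry", {
  expect_error(reentry_protocol(delay = -1), "delay")
  expect_error(reentry_protocol(stim_offset = 0), "transverse")
  p <- reentry_protocol()
  expect_equal(p$AR, 2)
  expect_equal(p$conditions$Ko, 10)
})
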