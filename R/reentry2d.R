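#' Reentry induction protocol
#'
#' Two point stimuli delivered at the same site 6 mm to the left of the
#' fiber-orientation border, separated by a delay (S1S2 at one location).
#' The S1 wavefront is blocked frontally at the border but penetrates
#' obliquely about 1 cm away, and the S2 wave launched into the
#' S1 repolarisation tail breaks, curling into a reentrant pattern whose
#' core drifts along the border.
#'
#' @param AR anisotropy ratio (2.0 in the reference setup).
#' @param Ko extracellular potassium (mM; 10 in the reference setup).
#' @param domain width/height in mm (64 x 32 reference; 256 x 32 for the
#'   long-drift variant).
#' @param h grid spacing (mm).
#' @param stim_offset stimulus distance left of the border (mm).
#' @param stim_y_frac vertical stimulus position as a fraction of the
#'   domain height. The default (0.75) places the site so that only one
#'   oblique penetration point falls inside the tissue, selecting a single
#'   wavebreak whose drift is upward; 0.25 gives the mirror-image rotor.
#' @param delay inter-stimulus delay (ms).
#' @param radius stimulus disc radius (mm). The default (2 mm) is the
#'   smallest disc that reliably captures as an S2 source at 10 mM
#'   extracellular potassium; see the methods vignette.
#' @param iso_strip_width isotropic-strip width (mm; 8 for the pinned
#'   variant, 0 for none).
#' @param conditions optionally override the full [cell_conditions()];
#'   by default normal conductances with the given `Ko`.
#' @return a `reentry_protocol`.
#' @export
reentry_protocol <- function(AR = 2.0, Ko = 10, domain = c(64, 32),
                             h = 0.25, stim_offset = 6, stim_y_frac = 0.75,
                             delay = 500, radius = 2, iso_strip_width = 0,
                             conditions = NULL) {
  if (delay <= 0) abort("`delay` must be positive")
  if (stim_offset <= 0) abort("the stimulus must lie inside the transverse region")
  structure(list(AR = AR, Ko = Ko, domain = domain, h = h,
                 stim_offset = stim_offset, stim_y_frac = stim_y_frac,
                 delay = delay, radius = radius,
                 iso_strip_width = iso_strip_width,
                 conditions = conditions %||% cell_conditions(Ko = Ko)),
            class = "reentry_protocol")
}

#' Run a 2D reentry-induction experiment
#'
#' Integrates the 2D sheet under the S1S2 protocol with the 2D preset
#' (dt = 0.02 ms, h = 0.25 mm) and records whole-field frames for tip
#' tracking. The record covers `post_s2` ms after the second stimulus.
#'
#' @param protocol a [reentry_protocol()].
#' @param post_s2 simulated time after S2 (ms; at least 3000 for drift
#'   assessment).
#' @param dt time step (ms).
#' @param frame_stride frame sampling interval (ms).
#' @return a `space_time_record` with frames.
#' @export
run_reentry <- function(protocol, post_s2 = 3000, dt = 0.02,
                        frame_stride = 5) {
  p <- protocol
  geom <- tissue_geometry(p$domain[1], p$domain[2], h = p$h,
                          border_x = p$domain[1] / 2,
                          iso_strip_width = p$iso_strip_width)
  cmap <- build_conductivity(geom, p$AR)
  nodes <- stim_disc(geom, geom$border_x - p$stim_offset,
                     p$domain[2] * p$stim_y_frac, p$radius)
  stimuli <- list(list(time = 0, nodes = nodes),
                  list(time = p$delay, nodes = nodes))
  cfg <- simulation_config(duration = p$delay + post_s2, dt = dt,
                           record_stride = 1, frame_stride = frame_stride)
  run_tissue(geom, cmap, p$conditions, stimuli, cfg, lazy = TRUE)
}

#' Detect and track a reentrant wave
#'
#' A record is classified as sustained when the reference node (domain
#' centre by default) re-activates at least `min_rotations` times after the
#' last stimulus. The rotation period is the median inter-activation
#' interval there. The core is located per frame as the wavefront free end:
#' the point where the V = -40 mV isoline meets the dV/dt = 0 isoline (a
#' phase-singularity proxy); the trajectory is smoothed with a 10 ms
#' running-mean window.
#'
#' @param record a `space_time_record` with frames.
#' @param threshold isoline voltage (mV).
#' @param min_rotations re-activations required for `sustained`.
#' @return a `reentry_report`: list with `sustained`, `period`,
#'   `trajectory` (tibble `time`, `x`, `y`), `outcome` in
#'   sustained/annihilated-at-boundary/stabilized/none.
#' @export
detect_and_track <- function(record, threshold = -40, min_rotations = 2) {
  if (is.null(record$frames)) abort("record has no frames; rerun with `frame_stride > 0`")
  geom <- record$geometry
  ft <- record$frame_times
  last_stim <- max(purrr::map_dbl(record$stimuli, "time"))

  # per-node re-activation counts after the last stimulus: sustained iff
  # any node re-activates at least `min_rotations` times
  post <- which(ft > last_stim + 50)
  up <- record$frames[, post[-1], drop = FALSE] >= -20 &
        record$frames[, post[-length(post)], drop = FALSE] < -20
  counts <- rowSums(up)
  sustained <- any(counts >= min_rotations)
  ref <- which.max(counts)
  acts <- activation_times(record$frames[ref, post],
                           threshold = -20, refractory = 50,
                           times = ft[post])
  period <- if (length(acts) >= 2) median(diff(acts)) else NA_real_

  traj <- track_tip(record, threshold)
  outcome <- if (!sustained && nrow(traj) == 0) "none"
  else if (!sustained) "annihilated-at-boundary"
  else if (nrow(traj) > 0 && terminal_gone(record)) "annihilated-at-boundary"
  else if (geom$iso_strip_width > 0 && nrow(traj) > 0 &&
           confined_to_strip(traj, geom)) "stabilized"
  else "sustained"

  structure(list(sustained = sustained, period = period, trajectory = traj,
                 outcome = outcome, activations = acts),
            class = "reentry_report")
}

# tip = sign change of both (V - threshold) and dV/dt inside a grid cell
track_tip <- function(record, threshold = -40) {
  geom <- record$geometry
  nx <- geom$nx; ny <- geom$ny; h <- geom$h
  ft <- record$frame_times
  fr <- record$frames
  last_stim <- max(purrr::map_dbl(record$stimuli, "time"))
  out <- list()
  prev <- c(NA_real_, NA_real_)
  for (k in 2:length(ft)) {
    if (ft[k] <= last_stim + 20) next
    V <- matrix(fr[, k], nx, ny)
    D <- V - matrix(fr[, k - 1], nx, ny)          # dV/dt sign proxy
    f <- V - threshold
    # 2x2 cells where both fields change sign
    sf <- sign_change_cells(f)
    sd <- sign_change_cells(D)
    hit <- which(sf & sd, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    xs <- (hit[, 1] - 0.5) * h
    ys <- (hit[, 2] - 0.5) * h
    if (!is.na(prev[1]) && nrow(hit) > 1) {
      i <- which.min((xs - prev[1])^2 + (ys - prev[2])^2)
    } else {
      i <- which.min((xs - geom$border_x)^2 + (ys - geom$height / 2)^2)
    }
    prev <- c(xs[i], ys[i])
    out[[length(out) + 1]] <- tibble(time = ft[k], x = xs[i], y = ys[i])
  }
  traj <- dplyr::bind_rows(out)
  if (nrow(traj) >= 3) {
    w <- max(1L, round(10 / stats::median(diff(ft))))
    traj$y <- stats::filter(traj$y, rep(1 / w, w), sides = 2)
    traj$x <- stats::filter(traj$x, rep(1 / w, w), sides = 2)
    traj <- traj[stats::complete.cases(traj), ]
  }
  traj
}

sign_change_cells <- function(M) {
  a <- M[-nrow(M), -ncol(M)]; b <- M[-1, -ncol(M)]
  c_ <- M[-nrow(M), -1]; d <- M[-1, -1]
  mx <- pmax(a, b, c_, d); mn <- pmin(a, b, c_, d)
  mx > 0 & mn < 0
}

# did activity die out by the end of the record?
terminal_gone <- function(record) {
  lastV <- record$frames[, ncol(record$frames)]
  max(lastV) < -40
}

confined_to_strip <- function(traj, geom, margin = 5) {
  half <- geom$iso_strip_width / 2 + margin
  tail_traj <- tail(traj, max(3, nrow(traj) %/% 3))
  all(abs(tail_traj$x - geom$border_x) <= half)
}

#' @export
print.reentry_report <- function(x, ...) {
  cat(sprintf("<reentry_report> %s; sustained = %s", x$outcome, x$sustained))
  if (!is.na(x$period)) cat(sprintf(", period = %.0f ms", x$period))
  cat(sprintf("; %d tracked tip positions\n", nrow(x$trajectory)))
  invisible(x)
}

#' @export
autoplot.reentry_report <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$time)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "time (ms)",
                  title = "reentry core trajectory") +
    ggplot2::theme_minimal()
}
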