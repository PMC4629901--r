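#' Pacing protocol
#'
#' Stimulus schedule for periodic pacing. For target periods shorter than
#' the ramp threshold (the 2.7 Hz period, ~370 ms) the schedule first ramps
#' down from the threshold in 5 ms-per-cycle decrements before holding at
#' the target; beats delivered during the ramp are excluded from analysis,
#' as are the first `n_ignore` beats at the held period.
#'
#' @param period target basic cycle length (ms).
#' @param n_stimuli number of held-period stimuli (ramp beats are extra).
#' @param n_ignore held-period beats excluded from analysis.
#' @param ramp_threshold period (ms) below which the ramp engages.
#' @param ramp_step per-cycle period decrement (ms).
#' @return a `pacing_protocol`.
#' @export
pacing_protocol <- function(period, n_stimuli = 7, n_ignore = 3,
                            ramp_threshold = 1000 / 2.7, ramp_step = 5) {
  if (period <= 0) abort("`period` must be positive")
  if (n_ignore < 0) abort("`n_ignore` must be >= 0")
  structure(list(period = period, n_stimuli = n_stimuli, n_ignore = n_ignore,
                 ramp_threshold = ramp_threshold, ramp_step = ramp_step),
            class = "pacing_protocol")
}

#' Stimulus times of a pacing protocol
#'
#' @param protocol a [pacing_protocol()].
#' @return numeric stimulus times (ms) with attribute `first_held`, the
#'   index of the first stimulus at the held (target) period.
#' @export
protocol_times <- function(protocol) {
  p <- protocol
  intervals <- numeric(0)
  if (p$period < p$ramp_threshold) {
    ramp <- seq(p$ramp_threshold, p$period, by = -p$ramp_step)
    ramp <- ramp[ramp > p$period]
    intervals <- ramp
  }
  times <- cumsum(c(0, intervals, rep(p$period, p$n_stimuli - 1)))
  first_held <- length(intervals) + 1L
  structure(times, first_held = first_held)
}

#' Detect activation times in a voltage trace
#'
#' Upward threshold crossings, debounced by a refractory window.
#'
#' @param trace tibble with `time` and `V` (uniformly sampled), or a numeric
#'   V vector with `times` supplied.
#' @param threshold crossing threshold (mV).
#' @param refractory minimum spacing between detections (ms).
#' @param times sample times if `trace` is a bare vector.
#' @return numeric vector of activation times (possibly empty).
#' @examples
#' activation_times(tibble::tibble(time = 0:10, V = c(-80, -80, 10, 10, -80,
#'   -80, -80, 10, 10, -80, -80)), refractory = 3)
#' @export
activation_times <- function(trace, threshold = -20, refractory = 50,
                             times = NULL) {
  if (is.data.frame(trace)) {
    v <- trace$V; tt <- trace$time
  } else {
    v <- trace; tt <- times %||% (seq_along(trace) - 1)
  }
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  out <- numeric(0)
  last <- -Inf
  for (i in up) {
    if (tt[i] - last > refractory) {
      out <- c(out, tt[i])
      last <- tt[i]
    }
  }
  out
}

#' Action potential duration at 90% repolarisation
#'
#' Duration from activation until V recovers to
#' `V_rest + 0.1 (V_peak - V_rest)`, with `V_rest` the pre-stimulus voltage
#' and `V_peak` the maximum of the action potential.
#'
#' @param trace tibble with `time` and `V` covering one full AP.
#' @param activation_time activation (or stimulus) time; defaults to the
#'   first threshold crossing.
#' @return APD90 in ms, or `NA` with attribute `incomplete = TRUE` when the
#'   trace ends before 90% repolarisation.
#' @export
apd90 <- function(trace, activation_time = NULL) {
  v <- trace$V; tt <- trace$time
  if (is.null(activation_time)) {
    act <- activation_times(trace)
    if (length(act) == 0) return(structure(NA_real_, incomplete = TRUE))
    activation_time <- act[1]
  }
  pre <- which(tt < activation_time)
  v_rest <- if (length(pre) > 0) v[max(pre)] else v[1]
  post <- which(tt >= activation_time)
  v_peak <- max(v[post])
  v90 <- v_rest + 0.1 * (v_peak - v_rest)
  ipk <- post[which.max(v[post])]
  rec <- which(v < v90 & seq_along(v) > ipk)
  if (length(rec) == 0) return(structure(NA_real_, incomplete = TRUE))
  tt[rec[1]] - activation_time
}

# --- single-cell pacing -----------------------------------------------------

#' Pace a single cell and record V(t)
#'
#' @param conditions a [cell_conditions()] object.
#' @param protocol a [pacing_protocol()].
#' @param state initial state; defaults to [equilibrate()].
#' @param record_stride sampling interval (ms).
#' @param tail_ms extra time simulated after the last stimulus.
#' @param dt integration step (ms).
#' @return tibble with `time` and `V`; attribute `stim_times`.
#' @export
pace_cell <- function(conditions, protocol, state = NULL,
                      record_stride = 0.5, tail_ms = NULL, dt = 0.005) {
  if (is.null(state)) state <- equilibrate(conditions)
  times <- protocol_times(protocol)
  tail_ms <- tail_ms %||% max(600, protocol$period + 100)
  dur <- max(times) + tail_ms
  stims <- lapply(times, function(t) list(time = t, nodes = 0L))
  r <- tp06_run_cpp(matrix(as.numeric(state), ncol = 1), 1L, 1L,
                    numeric(0), numeric(0), 1.0, dt, dur,
                    cond_cvec(conditions), stims, integer(0), -20, 50,
                    0L, record_stride, 0, 0L, 0, 0, 0L, 0L,
                    TRUE, 0L, FALSE, 1e-6)
  structure(tibble(time = r$trace_times, V = r$traces[, 1]),
            stim_times = as.numeric(times),
            first_held = attr(times, "first_held"))
}

#' APD restitution curve
#'
#' For each pacing period, paces a single cell with the full protocol
#' (ramp rule below the 2.7 Hz threshold, first `n_ignore` held beats
#' discarded) and reports the mean APD90 of the analyzed beats. Beats that
#' fail to capture (cell-level 2:1 block at very short periods) yield a
#' missing value flagged in `n_measured`.
#'
#' @param conditions a [cell_conditions()] object.
#' @param periods pacing periods (ms).
#' @param n_beats held-period beats per period.
#' @param n_ignore discarded held beats.
#' @return tibble with `period`, `apd90`, `n_measured`.
#' @export
restitution_curve <- function(conditions, periods, n_beats = 7,
                              n_ignore = 3) {
  state <- equilibrate(conditions)
  purrr::map_dfr(periods, function(p) {
    prot <- pacing_protocol(p, n_stimuli = n_beats, n_ignore = n_ignore)
    tr <- pace_cell(conditions, prot, state = state)
    st <- attr(tr, "stim_times")
    analyzed <- st[seq_along(st) >= attr(tr, "first_held") + n_ignore]
    apds <- purrr::map_dbl(seq_along(analyzed), function(k) {
      t0 <- analyzed[k]
      t1 <- if (k < length(analyzed)) analyzed[k + 1] else max(tr$time)
      seg <- tr[tr$time >= t0 - 5 & tr$time <= t1, ]
      # capture check: the beat must actually depolarise
      if (max(seg$V) < 0) return(NA_real_)
      apd90(seg, activation_time = t0)
    })
    tibble(period = p, apd90 = mean(apds, na.rm = TRUE),
           n_measured = sum(!is.na(apds)))
  })
}

# --- conduction classification ---------------------------------------------

# match proximal/distal activations to analyzed stimuli
match_conduction <- function(prox, dist, stim_times, n_ignore, window) {
  analyzed <- stim_times[seq_along(stim_times) > n_ignore]
  purrr::map_dfr(seq_along(analyzed), function(k) {
    sk <- analyzed[k]
    p <- prox[prox > sk & prox <= sk + window]
    pt <- if (length(p) > 0) p[1] else NA_real_
    d <- if (!is.na(pt)) dist[dist > pt & dist <= pt + window] else numeric(0)
    dt_ <- if (length(d) > 0) d[1] else NA_real_
    tibble(stimulus = which(stim_times == sk), stim_time = sk,
           proximal_t = pt, distal_t = dt_,
           conducted = !is.na(dt_))
  })
}

#' Classify conduction across the border
#'
#' Per analyzed stimulus the wave is conducted iff the distal probe (10 mm
#' past the border) activates within one pacing period of the proximal
#' activation (10 mm before the border). The overall pattern is `1:1` when
#' every analyzed wave conducts, `full block` when none does, and `n:m`
#' (stimuli : conducted) otherwise. Border-crossing delay is reported per
#' conducted wave as the proximal-to-distal lag minus a reference transit
#' time; by default the reference is the same 20 mm transit in an unbroken
#' transverse-only cable of the same AR, so the delay isolates the border
#' effect (`delay_reference = "none"` skips the extra reference run).
#'
#' @param record a `space_time_record` from a border cable run.
#' @param n_ignore stimuli excluded from analysis.
#' @param window conduction window (ms); defaults to the pacing period, or
#'   500 ms for a single pulse.
#' @param delay_reference `"uniform"` or `"none"`.
#' @return a tibble (one row per analyzed stimulus) with attributes
#'   `pattern` and `ratio`.
#' @export
classify_conduction <- function(record, n_ignore = 0, window = NULL,
                                delay_reference = c("uniform", "none")) {
  delay_reference <- match.arg(delay_reference)
  stim_times <- purrr::map_dbl(record$stimuli, "time")
  period <- if (length(stim_times) > 1) min(diff(sort(stim_times))) else NA
  window <- window %||% (if (is.na(period)) 500 else period)
  out <- match_conduction(record$probe_activations$proximal,
                          record$probe_activations$distal,
                          sort(stim_times), n_ignore, window)
  ref <- NA_real_
  if (delay_reference == "uniform" && any(out$conducted)) {
    ref <- uniform_transit_reference(record)
    out$delay <- ifelse(out$conducted, out$distal_t - out$proximal_t - ref,
                        NA_real_)
  } else {
    out$delay <- NA_real_
  }
  n <- nrow(out); m <- sum(out$conducted)
  pattern <- if (n == 0) "none" else if (m == n) "1:1"
             else if (m == 0) "full block"
             else sprintf("%d:%d", n, m)
  structure(out, pattern = pattern, ratio = c(n, m),
            transit_reference = ref, class = c("conduction_report",
                                               class(out)))
}

# transit time over the probe span in an unbroken transverse cable
uniform_transit_reference <- function(record) {
  geom <- record$geometry
  cmap <- record$conductivity
  sperp <- attr(cmap, "sigma_perp")
  g2 <- cable_geometry(length = geom$width, h = geom$h,
                       border_x = geom$width - geom$h)  # border pushed aside
  cm2 <- build_conductivity(g2, AR = 1, sigma_par = sperp)
  probes <- probe_nodes(geom)[1:2]
  r <- tp06_run_cpp(matrix(as.numeric(equilibrate(record$conditions)),
                           ncol = 1),
                    g2$nx, 1L, as.vector(cm2$sigx), numeric(0),
                    g2$h, record$config$dt, 500,
                    cond_cvec(record$conditions),
                    list(list(time = 0, nodes = stim_left_edge(g2))),
                    as.integer(probes), -20, 50, integer(0), 0, 0,
                    1L, 500, 0, 0L, 0L, TRUE, 0L, FALSE, 1e-6, TRUE)
  a1 <- r$probe_activations[[1]]; a2 <- r$probe_activations[[2]]
  if (length(a1) == 0 || length(a2) == 0) return(NA_real_)
  a2[1] - a1[1]
}

#' @export
print.conduction_report <- function(x, ...) {
  cat(sprintf("<conduction_report> pattern %s (%d analyzed, %d conducted)\n",
              attr(x, "pattern"), attr(x, "ratio")[1], attr(x, "ratio")[2]))
  NextMethod()
}

# --- border trial runner ----------------------------------------------------

# One two-region cable trial; the workhorse of all searches.
# Returns "conducted"/"blocked" plus the raw activation times.
border_trial <- function(conditions, AR, period = NULL, n_stimuli = 1,
                         n_ignore = 3, n_analyzed = 4, state = NULL,
                         geom = cable_geometry(), sigma_par = 0.154,
                         dt = 0.005, window = 500, use_lut = TRUE) {
  if (is.null(state)) state <- equilibrate(conditions)
  cmap <- build_conductivity(geom, AR, sigma_par)
  check_stability(geom, cmap, dt)
  probes <- probe_nodes(geom)
  single <- is.null(period) || n_stimuli == 1
  if (single) {
    stim_times <- 0
    dur <- 3 * window + 300
    es_code <- 1L; esw <- window; esp <- 0; ni <- 0L; na <- 1L
  } else {
    # full pacing protocol: ramp rule engages below the 2.7 Hz period,
    # ramp beats are ignored on top of n_ignore
    stim_times <- protocol_times(pacing_protocol(period,
                                                 n_stimuli = n_stimuli))
    n_ignore <- n_ignore + attr(stim_times, "first_held") - 1L
    dur <- max(stim_times) + 2 * period + 300
    es_code <- 2L; esw <- period
    esp <- period; ni <- as.integer(n_ignore); na <- as.integer(n_analyzed)
  }
  stims <- lapply(stim_times, function(t)
    list(time = t, nodes = stim_left_edge(geom)))
  r <- tp06_run_cpp(matrix(as.numeric(state), ncol = 1), geom$nx, 1L,
                    as.vector(cmap$sigx), numeric(0), geom$h, dt, dur,
                    cond_cvec(conditions), stims,
                    as.integer(probes), -20, 50, integer(0), 0, 0,
                    es_code, esw, esp, ni, na,
                    use_lut, 0L, FALSE, 1e-6, TRUE)
  if (r$status == -1)
    abort(sprintf("numerical instability at step %d, node %d",
                  r$bad_step, r$bad_node))
  prox <- r$probe_activations[[1]]; dist <- r$probe_activations[[2]]
  if (single) {
    # block window measured from the proximal activation (robust to slow
    # conduction under hyperkalemia); no proximal wave counts as blocked
    outcome <- if (length(prox) > 0 && length(dist) > 0 &&
                   dist[1] > prox[1] && dist[1] <= prox[1] + window)
      "conducted" else "blocked"
  } else {
    mc <- match_conduction(prox, dist, stim_times, n_ignore, period)
    mc <- head(mc, n_analyzed)
    outcome <- if (all(mc$conducted)) "conducted" else "blocked"
  }
  list(outcome = outcome, prox = prox, dist = dist, t_end = r$t_end)
}

# generic bisection on a monotone conducted->blocked transition
bisect_threshold <- function(trial_fn, bracket, tol, what = "AR",
                             check_bracket = TRUE) {
  lo <- bracket[1]; hi <- bracket[2]
  history <- list()
  note <- function(x, out) history[[length(history) + 1]] <<-
      tibble(value = x, outcome = out)
  if (check_bracket) {
    o_lo <- trial_fn(lo); note(lo, o_lo)
    o_hi <- trial_fn(hi); note(hi, o_hi)
    if (o_lo != "conducted" || o_hi != "blocked")
      abort(sprintf(
        "no conducted/blocked sign change in the %s bracket [%g, %g]: lower endpoint %s, upper endpoint %s",
        what, lo, hi, o_lo, o_hi))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    o <- trial_fn(mid); note(mid, o)
    if (o == "conducted") lo <- mid else hi <- mid
  }
  list(value = (lo + hi) / 2, lower = lo, upper = hi,
       history = dplyr::bind_rows(history))
}

#' Critical anisotropy ratio for a single travelling pulse
#'
#' Bisects the anisotropy ratio on the two-region cable with one stimulus:
#' below the critical AR the pulse crosses the border (distal probe
#' activates within the decision window), above it the pulse is blocked.
#'
#' @param conditions a [cell_conditions()] object.
#' @param tol bisection tolerance on AR (0.01 production, 0.05 for quick
#'   runs; values below 0.005 are rejected).
#' @param bracket initial AR bracket; endpoints are verified.
#' @param geom,sigma_par,dt,window cable setup (64 mm, h = 0.125 mm,
#'   sigma_par = 0.154 mm^2/ms, dt = 0.005 ms, 500 ms window by default).
#' @return list with `ar1`, the bracketing `lower`/`upper`, and a `history`
#'   tibble of every trial.
#' @examples
#' \donttest{
#' critical_ar_single_pulse(cell_conditions(), tol = 0.05)$ar1  # ~3.7
#' }
#' @export
critical_ar_single_pulse <- function(conditions, tol = 0.01,
                                     bracket = c(1.5, 8),
                                     geom = cable_geometry(),
                                     sigma_par = 0.154, dt = 0.005,
                                     window = 500) {
  if (tol < 0.005) abort("`tol` below 0.005 is not supported")
  state <- equilibrate(conditions)
  res <- bisect_threshold(function(ar)
    border_trial(conditions, ar, state = state, geom = geom,
                 sigma_par = sigma_par, dt = dt, window = window)$outcome,
    bracket, tol)
  list(ar1 = res$value, lower = res$lower, upper = res$upper,
       history = res$history)
}

#' Critical anisotropy ratio under periodic pacing
#'
#' As [critical_ar_single_pulse()] but pacing at fixed frequency with the
#' full train (default 3 ignored + 4 analyzed beats); a trial is blocked as
#' soon as any analyzed beat fails to conduct across the border.
#'
#' @param conditions a [cell_conditions()] object.
#' @param f pacing frequency (Hz), in \[0.5, 3.3\].
#' @param tol,bracket,geom,sigma_par,dt as in [critical_ar_single_pulse()].
#' @param n_ignore,n_analyzed pacing-train composition.
#' @return list with `ar`, `lower`, `upper`, `history`.
#' @export
critical_ar_at_frequency <- function(conditions, f, tol = 0.01,
                                     bracket = c(1.5, 8),
                                     n_ignore = 3, n_analyzed = 4,
                                     geom = cable_geometry(),
                                     sigma_par = 0.154, dt = 0.005) {
  if (f < 0.5 || f > 3.3) abort("`f` must be within [0.5, 3.3] Hz")
  period <- 1000 / f
  state <- equilibrate(conditions)
  res <- bisect_threshold(function(ar)
    border_trial(conditions, ar, period = period,
                 n_stimuli = n_ignore + n_analyzed,
                 n_ignore = n_ignore, n_analyzed = n_analyzed,
                 state = state, geom = geom, sigma_par = sigma_par,
                 dt = dt)$outcome,
    bracket, tol)
  list(ar = res$value, lower = res$lower, upper = res$upper,
       history = res$history)
}

#' Lowest pacing frequency that produces block at a fixed AR
#'
#' Scans pacing frequency on a regular grid and returns the lowest
#' frequency at which any analyzed beat fails to cross the border. Because
#' block is monotone in frequency (faster pacing always blocks more
#' easily), the default search bisects on the grid and verifies that the
#' next-lower frequency conducts, which returns the same answer as a full
#' upward scan at a fraction of the cost; `search = "scan"` performs the
#' literal upward scan.
#'
#' @param conditions a [cell_conditions()] object.
#' @param AR fixed anisotropy ratio.
#' @param f_range frequency range (Hz).
#' @param resolution frequency grid step (Hz).
#' @param n_ignore,n_analyzed pacing-train composition.
#' @param search `"bisect"` or `"scan"`.
#' @param .trial internal: replacement outcome function (used by tests to
#'   exercise the search logic without simulations).
#' @param geom,sigma_par,dt cable setup.
#' @return list with `f_block` (Hz; `NA` when no tested frequency blocks),
#'   `f_pass` (largest tested conducting frequency below it) and `history`.
#' @export
critical_block_frequency <- function(conditions, AR, f_range = c(0.5, 3.3),
                                     resolution = 0.1, n_ignore = 3,
                                     n_analyzed = 4,
                                     search = c("bisect", "scan"),
                                     geom = cable_geometry(),
                                     sigma_par = 0.154, dt = 0.005,
                                     .trial = NULL) {
  search <- match.arg(search)
  grid <- seq(f_range[1], f_range[2], by = resolution)
  if (is.null(.trial)) {
    state <- equilibrate(conditions)
    trial <- function(f)
      border_trial(conditions, AR, period = 1000 / f,
                   n_stimuli = n_ignore + n_analyzed, n_ignore = n_ignore,
                   n_analyzed = n_analyzed, state = state, geom = geom,
                   sigma_par = sigma_par, dt = dt)$outcome
  } else trial <- .trial   # injectable outcome function (tests)
  history <- list()
  note <- function(f, out) history[[length(history) + 1]] <<-
      tibble(f = f, outcome = out)
  outcome_at <- function(f) { o <- trial(f); note(f, o); o }

  if (search == "scan") {
    for (f in grid) {
      if (outcome_at(f) == "blocked")
        return(list(f_block = f, f_pass = if (f > grid[1]) f - resolution else NA,
                    history = dplyr::bind_rows(history)))
    }
    return(list(f_block = NA_real_, f_pass = grid[length(grid)],
                history = dplyr::bind_rows(history)))
  }
  # grid bisection under monotonicity. The lower endpoint (the longest,
  # slowest-paced run) is only evaluated if the bracket never moves off it:
  # whenever some midpoint conducts, that midpoint becomes the verified
  # conducting bound.
  lo <- 1L; hi <- length(grid)
  lo_verified <- FALSE
  if (outcome_at(grid[hi]) == "conducted")
    return(list(f_block = NA_real_, f_pass = grid[hi],
                history = dplyr::bind_rows(history)))
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (outcome_at(grid[mid]) == "blocked") hi <- mid
    else { lo <- mid; lo_verified <- TRUE }
  }
  if (!lo_verified && outcome_at(grid[lo]) == "blocked")
    return(list(f_block = grid[lo], f_pass = NA_real_,
                history = dplyr::bind_rows(history)))
  list(f_block = grid[hi], f_pass = grid[lo],
       history = dplyr::bind_rows(history))
}

#' Critical pacing period bracket at a fixed AR
#'
#' Finds the pair (T_pass, T_block) bracketing the critical period:
#' conduction is 1:1 for all periods >= T_pass and blocked for all periods
#' <= T_block. Periods are searched coarse-to-fine down to `resolution`
#' (5 ms) using the full pacing protocol.
#'
#' @param conditions a [cell_conditions()] object.
#' @param AR anisotropy ratio (must be below the single-pulse critical AR,
#'   otherwise every period blocks).
#' @param period_range search range (ms).
#' @param resolution final period resolution (ms).
#' @param n_ignore,n_analyzed pacing-train composition.
#' @param geom,sigma_par,dt cable setup.
#' @param .trial internal: replacement outcome function (tests only).
#' @return list with `T_pass`, `T_block` (`NA` when all periods conduct)
#'   and `history`.
#' @export
critical_period_at_ar <- function(conditions, AR,
                                  period_range = c(250, 2000),
                                  resolution = 5, n_ignore = 3,
                                  n_analyzed = 4, geom = cable_geometry(),
                                  sigma_par = 0.154, dt = 0.005,
                                  .trial = NULL) {
  if (is.null(.trial)) {
    state <- equilibrate(conditions)
    trial <- function(p)
      border_trial(conditions, AR, period = p,
                   n_stimuli = n_ignore + n_analyzed, n_ignore = n_ignore,
                   n_analyzed = n_analyzed, state = state, geom = geom,
                   sigma_par = sigma_par, dt = dt)$outcome
  } else trial <- .trial   # injectable outcome function (tests)
  history <- list()
  note <- function(p, out) history[[length(history) + 1]] <<-
      tibble(period = p, outcome = out)
  outcome_at <- function(p) { o <- trial(p); note(p, o); o }

  hi <- period_range[2]; lo <- period_range[1]
  if (outcome_at(hi) == "blocked")
    abort(sprintf("AR = %g blocks even at T = %g ms (AR above the single-pulse critical value?)",
                  AR, hi))
  if (outcome_at(lo) == "conducted")
    return(list(T_pass = lo, T_block = NA_real_,
                history = dplyr::bind_rows(history)))
  while (hi - lo > resolution) {
    mid <- resolution * round((lo + hi) / 2 / resolution)
    if (mid <= lo || mid >= hi) break
    if (outcome_at(mid) == "conducted") hi <- mid else lo <- mid
  }
  list(T_pass = hi, T_block = lo, history = dplyr::bind_rows(history))
}

#' Assemble a critical-period curve over several ARs
#'
#' @param conditions a [cell_conditions()] object.
#' @param ars anisotropy ratios (each below the single-pulse critical AR).
#' @param ... passed to [critical_period_at_ar()].
#' @return tibble with `AR`, `T_pass`, `T_block` sorted by AR.
#' @export
critical_curve <- function(conditions, ars, ...) {
  out <- purrr::map_dfr(sort(ars), function(a) {
    cp <- critical_period_at_ar(conditions, a, ...)
    tibble(AR = a, T_pass = cp$T_pass, T_block = cp$T_block)
  })
  out
}
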