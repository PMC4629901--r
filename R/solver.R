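#' Simulation configuration
#'
#' Time step, recording cadence and duration for the explicit monodomain
#' integrator. Supported production presets for (dt, h) are
#' (0.005 ms, 0.125 mm) for 1D, (0.02 ms, 0.25 mm) for 2D and
#' (0.0008 ms, 0.05 mm) for grid-refinement checks; other pairs are allowed
#' provided they satisfy the explicit-scheme stability bound, which is
#' enforced against the conductivity map at run time
#' (`dt <= 0.9 h^2 / (4 sigma_max)`).
#'
#' @param duration simulated time (ms).
#' @param dt time step (ms).
#' @param record_stride sampling interval (ms) for site traces (0 disables).
#' @param frame_stride sampling interval (ms) for whole-field frames
#'   (0 disables; frames are needed for space-time plots and tip tracking).
#' @param record_sites optional integer vector of extra node indices to
#'   record densely (the border probes are always added).
#' @return a `simulation_config`.
#' @export
simulation_config <- function(duration, dt = 0.005, record_stride = 1,
                              frame_stride = 0, record_sites = NULL) {
  if (duration <= 0 || dt <= 0) abort("`duration` and `dt` must be positive")
  structure(list(duration = duration, dt = dt,
                 record_stride = record_stride, frame_stride = frame_stride,
                 record_sites = record_sites),
            class = "simulation_config")
}

check_stability <- function(geom, cmap, dt) {
  smax <- max(attr(cmap, "sigma_par"), attr(cmap, "sigma_perp"))
  bound <- 0.9 * geom$h^2 / (4 * smax)
  if (dt > bound)
    abort(sprintf(paste("unstable configuration: dt = %g ms exceeds the",
                        "explicit bound %.4g ms for h = %g mm, sigma_max = %g"),
                  dt, bound, geom$h, smax))
  invisible(TRUE)
}

#' Stimulus site helpers
#'
#' `stim_left_edge()` returns the nodes of a rectangle `width_px` nodes wide
#' along the left border of the domain (the plane-wave stimulus).
#' `stim_disc()` returns the nodes of a disc (radius in mm) around a point,
#' the 2D point stimulus. A stimulus sets V to 50 mV at those nodes for one
#' step and leaves every other state variable untouched.
#'
#' @param geom a [tissue_geometry()].
#' @param width_px width of the edge rectangle in nodes.
#' @return 0-based node indices.
#' @export
stim_left_edge <- function(geom, width_px = 6) {
  ix <- 0:(width_px - 1)
  as.integer(outer(ix, (0:(geom$ny - 1)) * geom$nx, `+`))
}

#' @rdname stim_left_edge
#' @param x,y centre of the disc (mm).
#' @param radius disc radius (mm).
#' @export
stim_disc <- function(geom, x, y, radius = 1) {
  rm <- region_map(geom)
  sel <- (rm$x - x)^2 + (rm$y - y)^2 <= radius^2
  if (!any(sel)) abort("empty stimulus region")
  as.integer(rm$iy[sel] * geom$nx + rm$ix[sel])
}

#' Apply a voltage-reset stimulus to a field
#'
#' Sets V to 50 mV at the given nodes. This is the literal stimulus model of
#' the simulator (no current injection, no duration); exposed mostly for
#' testing, since [run_tissue()] applies stimuli internally at the protocol
#' times.
#'
#' @param V_field numeric vector or matrix of membrane potentials.
#' @param nodes 0-based node indices.
#' @return the updated field.
#' @export
apply_stimulus <- function(V_field, nodes) {
  if (length(nodes) == 0) abort("empty stimulus region")
  if (any(nodes < 0 | nodes >= length(V_field)))
    abort("stimulus region outside the grid")
  V_field[nodes + 1] <- 50
  V_field
}

#' Discrete diffusion term
#'
#' The flux-difference form of div(sigma grad V) on the grid: fluxes are
#' evaluated at half-integer nodes and boundary fluxes are zero (Neumann).
#' Summed over all nodes the term telescopes to zero.
#'
#' @param V_field matrix (nx x ny) or vector (cable) of potentials.
#' @param cmap a [build_conductivity()] map.
#' @param h grid spacing (mm).
#' @return field of the same shape (mV/ms).
#' @export
diffusion_term <- function(V_field, cmap, h) {
  V <- if (is.matrix(V_field)) V_field else matrix(V_field, ncol = 1)
  if (nrow(V) != nrow(cmap$sigx) + 1 ||
      (ncol(V) > 1 && ncol(cmap$sigy) != ncol(V) - 1) ||
      ncol(V) != ncol(cmap$sigx))
    abort("shape mismatch between V_field and conductivity map")
  out <- diffusion_term_cpp(V, as.vector(cmap$sigx), as.vector(cmap$sigy), h)
  if (is.matrix(V_field)) out else as.vector(out)
}

#' Run a monodomain tissue simulation
#'
#' Integrates the monodomain equation with the TP06 reaction term using a
#' single unsplit explicit update per step: the half-node flux differences
#' and the ionic current enter one forward-Euler step, exactly as in the
#' printed scheme. Stimuli (voltage resets) are applied at the protocol
#' times. Two probe sites 10 mm proximal/distal of the border are always
#' monitored for threshold crossings.
#'
#' @param geom a [tissue_geometry()].
#' @param cmap a [build_conductivity()] map for `geom`.
#' @param conditions a [cell_conditions()] object.
#' @param stimuli list of `list(time =, nodes =)` stimulus events (0-based
#'   node indices), e.g. from [stim_left_edge()] and a pacing schedule.
#' @param config a [simulation_config()].
#' @param init_state initial `cell_state` broadcast to every node; defaults
#'   to [equilibrate()] under `conditions`.
#' @param gates gate integration mode, see [step_cell()].
#' @param use_lut use the tabulated-rate fast path (`FALSE` evaluates every
#'   rate exactly; several-fold slower, for validation).
#' @param early_stop `"none"`, `"single"` (stop once the distal probe
#'   activates or the block window elapses) or `"paced"` (stop once every
#'   analyzed beat is classified); used by the search protocols.
#' @param es list of early-stop parameters (`window`, `period`, `n_ignore`,
#'   `n_analyzed`).
#' @param lazy freeze quiescent nodes ahead of the wavefront until the
#'   diffusive foot reaches them (safe only when `init_state` is an
#'   equilibrated resting state, where the frozen residual is < 1e-5 pA/pF).
#' @return a `space_time_record`.
#' @export
run_tissue <- function(geom, cmap, conditions, stimuli, config,
                       init_state = NULL,
                       gates = c("rush_larsen", "euler"), use_lut = TRUE,
                       early_stop = c("none", "single", "paced"),
                       es = list(), lazy = FALSE) {
  gates <- match.arg(gates)
  early_stop <- match.arg(early_stop)
  stopifnot(inherits(cmap, "conductivity_map"))
  check_stability(geom, cmap, config$dt)
  if (is.null(init_state)) init_state <- equilibrate(conditions)
  init_state <- validate_cell_state(init_state, strict_v = FALSE)

  probes <- probe_nodes(geom)
  sites <- unique(c(probes, config$record_sites))
  esd <- list(window = 500, period = 0, n_ignore = 0, n_analyzed = 0)
  esd[names(es)] <- es
  es_code <- match(early_stop, c("none", "single", "paced")) - 1L

  r <- tp06_run_cpp(matrix(as.numeric(init_state), ncol = 1),
                    geom$nx, geom$ny,
                    as.vector(cmap$sigx), as.vector(cmap$sigy),
                    geom$h, config$dt, config$duration,
                    cond_cvec(conditions), stimuli,
                    as.integer(probes), -20, 50,
                    as.integer(sites), config$record_stride,
                    config$frame_stride,
                    es_code, esd$window, esd$period,
                    as.integer(esd$n_ignore), as.integer(esd$n_analyzed),
                    use_lut, if (gates == "rush_larsen") 0L else 1L,
                    FALSE, 1e-6, lazy)
  if (r$status == -1)
    abort(sprintf("numerical instability at step %d, node %d (non-finite or out-of-range V)",
                  r$bad_step, r$bad_node))
  new_space_time_record(r, geom, cmap, conditions, stimuli, config, sites)
}

# probe sites: 10 mm and 1.25 mm on each side of the border (row 0)
probe_nodes <- function(geom) {
  xs <- geom$border_x + c(-10, 10, -1.25, 1.25)
  xs <- pmin(pmax(xs, 0), geom$width - geom$h)
  iy <- if (geom$ny > 1) floor(geom$ny / 2) else 0
  unique(node_index(geom, xs, iy * geom$h))
}

new_space_time_record <- function(r, geom, cmap, conditions, stimuli,
                                  config, sites) {
  traces <- NULL
  if (length(r$trace_times) > 0 && length(sites) > 0) {
    traces <- tibble(
      time = rep(r$trace_times, times = length(sites)),
      node = rep(sites, each = length(r$trace_times)),
      V = as.vector(r$traces))
  }
  frames <- NULL
  if (r$n_frames > 0)
    frames <- r$frames[, seq_len(r$n_frames), drop = FALSE]
  structure(
    list(status = c("completed", "all_conducted", "blocked",
                    "distal_activated", "window_elapsed")[r$status + 1],
         t_end = r$t_end,
         traces = traces,
         frames = frames, frame_times = r$frame_times[seq_len(r$n_frames %||% 0)],
         probe_activations = setNames(
           r$probe_activations[seq_along(probe_nodes(geom))],
           c("proximal", "distal", "near_left", "near_right")[seq_along(probe_nodes(geom))]),
         final_state = r$final_state,
         geometry = geom, conductivity = cmap, conditions = conditions,
         stimuli = stimuli, config = config),
    class = "space_time_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.space_time_record <- function(x, ...) {
  cat(sprintf("<space_time_record> %s after %g ms (%d x %d grid)\n",
              x$status, x$t_end, x$geometry$nx, x$geometry$ny))
  pa <- x$probe_activations
  cat(sprintf("  probe activations: proximal %d, distal %d\n",
              length(pa$proximal), length(pa$distal)))
  invisible(x)
}

#' Extract the dense voltage trace at one recorded site
#'
#' @param record a `space_time_record`.
#' @param node 0-based node index (must have been recorded).
#' @return tibble with `time` and `V`.
#' @export
site_trace <- function(record, node) {
  if (is.null(record$traces) || !node %in% record$traces$node)
    abort(sprintf("node %d was not recorded", node))
  record$traces[record$traces$node == node, c("time", "V")]
}
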