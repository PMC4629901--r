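#' Toy excitable cable
#'
#' A two-variable cubic excitable kernel (activator u, recovery w) on a 1D
#' cable, used as a fast stand-in for the ionic model when testing protocol
#' machinery: it has a stable resting state at u = 0, supports a
#' propagating pulse, and that pulse is blocked by a sufficiently large
#' abrupt drop-to-jump in the coupling coefficient. Parameters are frozen;
#' their only contract is this qualitative behaviour. Units are
#' dimensionless model units.
#'
#' @param nx number of nodes.
#' @param sig per-link coupling coefficients (length `nx - 1`), e.g. with a
#'   jump at the midpoint.
#' @param stim_times stimulus times (u set to 1 at `stim_nodes`).
#' @param stim_nodes 0-based stimulated nodes.
#' @param probe_nodes 0-based probe nodes (threshold 0.5 crossings).
#' @param duration,dt,h integration setup.
#' @param record_sites,record_stride optional dense u traces.
#' @return list with final fields `u`, `w`, `probe_activations` and traces.
#' @export
toy_run <- function(nx = 400, sig = rep(1, nx - 1), stim_times = 0,
                    stim_nodes = 0:4, probe_nodes = integer(0),
                    duration = 400, dt = 0.05, h = 0.5,
                    record_sites = integer(0), record_stride = 0) {
  toy_run_cpp(as.integer(nx), sig, h, dt, duration,
              as.numeric(stim_times), as.integer(stim_nodes),
              as.integer(probe_nodes), 0.5, 30,
              as.integer(record_sites), record_stride,
              8, 0.15, 0.005, 2.5)
}

#' Canonical toy tissue cases
#'
#' Ready-made fast test cases with known outcomes:
#' \describe{
#'   \item{`passive_gaussian`}{a Gaussian pulse in a passive uniform medium
#'     (no reaction term); ships the closed-form heat-kernel solution and
#'     its variance growth 2*sigma*t.}
#'   \item{`toy_pulse`}{a uniform toy cable where every stimulus conducts
#'     1:1 to the distal probe.}
#'   \item{`toy_two_region`}{a toy cable with a 20x coupling jump at the
#'     midpoint that fully blocks the pulse (the same current-to-load
#'     mismatch exercised by the ionic model, at negligible cost).}
#' }
#'
#' @param kind case name.
#' @return list with the case setup, a `run()` closure and the `expected`
#'   outcome description.
#' @export
toy_tissue_case <- function(kind = c("passive_gaussian", "toy_pulse",
                                     "toy_two_region")) {
  kind <- match.arg(kind)
  switch(kind,
    passive_gaussian = {
      nx <- 201; h <- 0.5; sigma <- 0.2; s0 <- 2
      x <- (0:(nx - 1)) * h
      x0 <- x[(nx + 1) / 2]
      V0 <- exp(-(x - x0)^2 / (2 * s0^2))
      solution <- function(t) {
        s2 <- s0^2 + 2 * sigma * t
        s0 / sqrt(s2) * exp(-(x - x0)^2 / (2 * s2))
      }
      list(kind = kind, x = x, V0 = V0, sigma = sigma, h = h,
           solution = solution,
           run = function(duration, dt = 0.1, frame_stride = 0)
             passive_run_cpp(matrix(V0, ncol = 1), rep(sigma, nx - 1),
                             numeric(0), h, dt, duration, frame_stride),
           expected = "matches the heat kernel; variance grows as 2 sigma t")
    },
    toy_pulse = {
      nx <- 400
      list(kind = kind, nx = nx,
           run = function(stim_times = 0)
             toy_run(nx = nx, stim_times = stim_times,
                     duration = max(stim_times) + 400,
                     probe_nodes = c(100L, 300L)),
           expected = "1:1 conduction to the distal probe")
    },
    toy_two_region = {
      nx <- 400
      sig <- c(rep(0.05, 199), rep(1, 200))   # 20x coupling jump at midpoint
      list(kind = kind, nx = nx, sig = sig,
           run = function(stim_times = 0)
             toy_run(nx = nx, sig = sig, stim_times = stim_times,
                     probe_nodes = c(100L, 300L)),
           expected = "full block of the toy pulse at the jump")
    })
}

#' Build (or load) a library of equilibrated steady states
#'
#' Equilibrates each condition once and persists the result to a directory
#' of plain-text state files plus a CSV manifest recording convergence
#' metadata; repeated calls load from the store instead of recomputing.
#'
#' @param conditions_list non-empty list of [cell_conditions()].
#' @param dir store directory (created if needed); `NULL` keeps the library
#'   in memory only.
#' @param duration equilibration time (s).
#' @return tibble manifest with one row per condition (`key`, `file`,
#'   `V_rest`, `converged`, `oscillating`) and attribute `states`, a named
#'   list of `cell_state` objects.
#' @export
make_steady_state_library <- function(conditions_list, dir = NULL,
                                      duration = 50) {
  if (length(conditions_list) == 0) abort("`conditions_list` must be non-empty")
  rows <- list(); states <- list()
  for (cond in conditions_list) {
    key <- cond_key(cond, duration)
    file <- if (!is.null(dir)) file.path(dir, paste0(key, ".txt")) else NA
    if (!is.null(dir) && file.exists(file)) {
      st <- read_cell_state(file)
      manifest <- read.csv(file.path(dir, "manifest.csv"))
      meta <- manifest[manifest$key == key, ]
      attr(st, "converged") <- meta$converged[1]
      attr(st, "oscillating") <- meta$oscillating[1]
    } else {
      st <- equilibrate(cond, duration = duration)
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        write_cell_state(st, file)
      }
    }
    states[[key]] <- st
    rows[[key]] <- tibble(key = key, file = as.character(file),
                          V_rest = st[["V"]],
                          converged = isTRUE(attr(st, "converged")),
                          oscillating = isTRUE(attr(st, "oscillating")))
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  structure(manifest, states = states)
}
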