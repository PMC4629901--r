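#' Compute the twelve TP06 membrane currents
#'
#' Evaluates every membrane current of the TP06 epicardial model at the
#' given state, with reversal potentials recomputed from the instantaneous
#' intracellular concentrations (Nernst for K, Na and Ca; the mixed K/Na
#' potential for the slow delayed rectifier). The phase-conditional
#' inward-rectifier rule of `conditions` is applied using `dvdt_sign`, the
#' sign of dV/dt supplied by the caller (ties count as repolarisation).
#'
#' @param state a `cell_state`.
#' @param conditions a [cell_conditions()] object.
#' @param dvdt_sign -1, 0 or +1.
#' @return one-row tibble with columns `I_Na`, `I_K1`, `I_to`, `I_Kr`,
#'   `I_Ks`, `I_CaL`, `I_NaCa`, `I_NaK`, `I_pCa`, `I_pK`, `I_bCa`, `I_bNa`
#'   and their sum `I_ion` (pA/pF).
#' @examples
#' st <- tp06_initial_state()
#' compute_currents(st, cell_conditions())
#' @export
compute_currents <- function(state, conditions = cell_conditions(),
                             dvdt_sign = 0) {
  state <- validate_cell_state(state, strict_v = FALSE)
  stopifnot(dvdt_sign %in% c(-1, 0, 1))
  out <- tp06_currents_cpp(as.numeric(state), cond_cvec(conditions),
                           as.integer(dvdt_sign))
  as_tibble(as.list(out))
}

#' Advance a single cell by explicit time steps
#'
#' Forward-Euler update of V and the intracellular concentrations; gating
#' variables advance either by Rush-Larsen exponential steps towards their
#' voltage-dependent steady states (default; unconditionally stable for the
#' gate subsystem) or by plain forward Euler (`gates = "euler"`) for
#' scheme-fidelity comparisons.
#'
#' @param state a `cell_state`.
#' @param conditions a [cell_conditions()] object.
#' @param dt time step (ms); must be positive and at most 0.02 ms.
#' @param n_steps number of steps to take.
#' @param gates `"rush_larsen"` or `"euler"`.
#' @return the advanced `cell_state`.
#' @export
step_cell <- function(state, conditions = cell_conditions(), dt = 0.005,
                      n_steps = 1, gates = c("rush_larsen", "euler")) {
  gates <- match.arg(gates)
  if (!is.numeric(dt) || dt <= 0 || dt > 0.02)
    abort("`dt` must be in (0, 0.02] ms")
  state <- validate_cell_state(state, strict_v = FALSE)
  r <- tp06_run_cpp(matrix(as.numeric(state), ncol = 1), 1L, 1L,
                    numeric(0), numeric(0), 1.0, dt, dt * n_steps,
                    cond_cvec(conditions), list(), integer(0), -20, 50,
                    integer(0), 0, 0, 0L, 0, 0, 0L, 0L,
                    FALSE, if (gates == "rush_larsen") 0L else 1L,
                    FALSE, 1e-6)
  new_cell_state(r$final_state[, 1])
}

.equilibrium_cache <- new.env(parent = emptyenv())

#' Equilibrate a cell to its quiescent steady state
#'
#' Integrates a single unstimulated cell for `duration` seconds (50 s by
#' default, the reference protocol) and returns the final state, which is
#' broadcast across the tissue as the initial condition of every simulation.
#'
#' Two diagnostics are attached. `converged` reports whether the per-ms
#' relative change of every state variable stayed below `tol` over the final
#' second; the quiescent TP06 calcium stores drain on a timescale of minutes,
#' so this strict criterion is typically still `FALSE` at 50 s even though
#' the membrane variables are fully settled. `oscillating` reports
#' spontaneous activity (peak-to-peak V above 1 mV over the final two
#' seconds), the regime reached when the inward-rectifier conductance falls
#' below roughly 10% of normal: such a state is flagged but still returned.
#'
#' @param conditions a [cell_conditions()] object.
#' @param duration equilibration time in seconds (>= 10 s for production).
#' @param dt integration step (ms).
#' @param tol per-ms relative-change tolerance for `converged`.
#' @param cache reuse previously computed states for identical inputs.
#' @return a `cell_state` with attributes `converged` and `oscillating`.
#' @examples
#' \donttest{
#' st <- equilibrate(cell_conditions(), duration = 50)
#' st[["V"]]            # about -86.5 mV
#' }
#' @export
equilibrate <- function(conditions = cell_conditions(), duration = 50,
                        dt = 0.005, tol = 1e-6, cache = TRUE) {
  if (duration < 10)
    warn("equilibration under 10 s is for testing only; production runs use >= 10 s")
  key <- cond_key(conditions, duration, dt, tol)
  if (cache && !is.null(.equilibrium_cache[[key]]))
    return(.equilibrium_cache[[key]])
  r <- tp06_run_cpp(matrix(as.numeric(tp06_initial_state()), ncol = 1),
                    1L, 1L, numeric(0), numeric(0), 1.0, dt, duration * 1000,
                    cond_cvec(conditions), list(), integer(0), -20, 50,
                    0L, 5, 0, 0L, 0, 0, 0L, 0L, TRUE, 0L, TRUE, tol)
  st <- new_cell_state(r$final_state[, 1])
  vtail <- r$traces[r$trace_times >= duration * 1000 - 2000, 1]
  osc <- diff(range(vtail)) > 1
  attr(st, "converged") <- r$converged && !osc
  attr(st, "oscillating") <- osc
  if (osc)
    warn("no quiescent steady state: spontaneous activity persists (state returned)")
  if (cache) .equilibrium_cache[[key]] <- st
  st
}
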