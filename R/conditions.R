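#' Define an electrophysiological condition
#'
#' A condition bundles everything that distinguishes one simulated
#' "experiment" from another at the cell level: maximal-conductance scale
#' factors for the five channels studied (fast sodium, L-type calcium, rapid
#' and slow delayed rectifiers, inward rectifier), the extracellular
#' potassium concentration, and an optional phase-conditional rule that
#' applies a different inward-rectifier conductance only during a chosen
#' phase of the action potential.
#'
#' Phase rules (used to dissect when I_K1 matters):
#' \describe{
#'   \item{`"always"`}{no phase gating; `g_K1` applies throughout.}
#'   \item{`"front_only"`}{`ik1_factor` applies while dV/dt > 0.}
#'   \item{`"tail_only"`}{`ik1_factor` applies while dV/dt <= 0.}
#'   \item{`"subthreshold_front"`}{`ik1_factor` applies while dV/dt > 0 and
#'     V < -50 mV (before sodium-channel activation).}
#'   \item{`"suprathreshold_front"`}{`ik1_factor` applies while dV/dt > 0 and
#'     V > -50 mV.}
#' }
#' When a phase rule other than `"always"` is active, `g_K1` is the scale
#' used outside the rule's phase (normally 1).
#'
#' @param g_Na,g_CaL,g_Kr,g_Ks,g_K1 conductance scale factors in (0, 1].
#' @param Ko extracellular potassium (mM); 5.4 is normokalemia. Values in
#'   [5.4, 20] are the supported hyperkalemia scan range.
#' @param ik1_rule one of the phase rules above.
#' @param ik1_factor inward-rectifier scale applied when the rule's phase
#'   condition holds (ignored for `"always"`).
#' @param Cm membrane capacitance per unit area (uF/mm^2 scale factor of the
#'   TP06 formulation; enters the intracellular concentration balances).
#' @return an object of class `cell_conditions`.
#' @examples
#' cell_conditions()                       # normal epicardial TP06
#' cell_conditions(g_K1 = 0.25)            # 25% inward rectifier
#' cell_conditions(Ko = 10)                # hyperkalemia
#' cell_conditions(ik1_rule = "front_only", ik1_factor = 0.25)
#' @export
cell_conditions <- function(g_Na = 1, g_CaL = 1, g_Kr = 1, g_Ks = 1,
                            g_K1 = 1, Ko = 5.4,
                            ik1_rule = c("always", "front_only", "tail_only",
                                         "subthreshold_front",
                                         "suprathreshold_front"),
                            ik1_factor = 1, Cm = 0.185) {
  ik1_rule <- match.arg(ik1_rule)
  sc <- c(g_Na = g_Na, g_CaL = g_CaL, g_Kr = g_Kr, g_Ks = g_Ks, g_K1 = g_K1)
  for (nm in names(sc)) {
    v <- sc[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0 || v > 1)
      abort(sprintf("`%s` must be a single value in (0, 1], got %s",
                    nm, format(v)))
  }
  if (!is.numeric(Ko) || length(Ko) != 1 || Ko <= 0)
    abort("`Ko` must be a positive concentration (mM)")
  if (Ko < 5.4 || Ko > 20)
    warn(sprintf("Ko = %g mM is outside the supported scan range [5.4, 20]",
                 Ko))
  if (ik1_factor <= 0 || ik1_factor > 1)
    abort("`ik1_factor` must be in (0, 1]")
  structure(
    list(g_Na = g_Na, g_CaL = g_CaL, g_Kr = g_Kr, g_Ks = g_Ks, g_K1 = g_K1,
         Ko = Ko, ik1_rule = ik1_rule, ik1_factor = ik1_factor, Cm = Cm),
    class = "cell_conditions")
}

#' @export
print.cell_conditions <- function(x, ...) {
  cat("<cell_conditions>\n")
  sc <- unlist(x[c("g_Na", "g_CaL", "g_Kr", "g_Ks", "g_K1")])
  mod <- sc[sc != 1]
  cat("  scales:", if (length(mod) == 0) "all 1 (normal)" else
    paste(names(mod), "=", format(mod), collapse = ", "), "\n")
  cat("  Ko:", x$Ko, "mM\n")
  if (x$ik1_rule != "always")
    cat("  I_K1 rule:", x$ik1_rule, "-> factor", x$ik1_factor, "\n")
  invisible(x)
}

#' @export
as_tibble.cell_conditions <- function(x, ...) {
  tibble::tibble(g_Na = x$g_Na, g_CaL = x$g_CaL, g_Kr = x$g_Kr,
                 g_Ks = x$g_Ks, g_K1 = x$g_K1, Ko = x$Ko,
                 ik1_rule = x$ik1_rule, ik1_factor = x$ik1_factor)
}

ik1_rule_codes <- c(always = 0L, front_only = 1L, tail_only = 2L,
                    subthreshold_front = 3L, suprathreshold_front = 4L)

# named numeric vector consumed by the compiled kernel
cond_cvec <- function(cond) {
  stopifnot(inherits(cond, "cell_conditions"))
  c(g_Na = cond$g_Na, g_CaL = cond$g_CaL, g_Kr = cond$g_Kr, g_Ks = cond$g_Ks,
    g_K1 = cond$g_K1, Ko = cond$Ko, Cm = cond$Cm,
    ik1_factor = cond$ik1_factor,
    ik1_rule = as.numeric(ik1_rule_codes[[cond$ik1_rule]]))
}

cond_key <- function(cond, ...) {
  digest::digest(list(unclass(cond), ...))
}
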