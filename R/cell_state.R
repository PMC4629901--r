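#' TP06 cell state
#'
#' The full membrane/ionic state of one TP06 epicardial cell: membrane
#' potential `V` (mV), twelve gating variables in \[0, 1\], the dynamic
#' intracellular concentrations (mM) and the ryanodine-receptor adaptation
#' variable `R_bar`.
#'
#' `tp06_initial_state()` returns the conventional pre-equilibration starting
#' point; production simulations start from [equilibrate()]'s output instead.
#'
#' @return named numeric vector of class `cell_state` with 19 entries.
#' @seealso [equilibrate()], [validate_cell_state()]
#' @export
tp06_initial_state <- function() {
  new_cell_state(c(
    V = -86.2, m = 0, h = 0.75, j = 0.75, d = 0, f = 1, f2 = 1, fCass = 1,
    r = 0, s = 1, xr1 = 0, xr2 = 1, xs = 0,
    Na_i = 7.67, K_i = 138.3, Ca_i = 0.00007, Ca_sr = 1.3, Ca_ss = 0.00007,
    R_bar = 1))
}

state_names <- c("V", "m", "h", "j", "d", "f", "f2", "fCass", "r", "s",
                 "xr1", "xr2", "xs", "Na_i", "K_i", "Ca_i", "Ca_sr", "Ca_ss",
                 "R_bar")
gate_names <- c("m", "h", "j", "d", "f", "f2", "fCass", "r", "s",
                "xr1", "xr2", "xs")
conc_names <- c("Na_i", "K_i", "Ca_i", "Ca_sr", "Ca_ss")

new_cell_state <- function(x) {
  stopifnot(is.numeric(x), length(x) == 19)
  names(x) <- state_names
  class(x) <- "cell_state"
  x
}

#' Validate a cell state
#'
#' Checks the state invariants: all values finite, gates within \[0, 1\],
#' concentrations strictly positive, and V inside the physiologically
#' meaningful window.
#'
#' @param state a `cell_state` (or named numeric vector with the same names).
#' @param strict_v if `TRUE`, require V in \[-100, 60\] mV.
#' @return the state, invisibly; aborts with the name of the offending
#'   variable otherwise.
#' @export
validate_cell_state <- function(state, strict_v = TRUE) {
  if (!all(state_names %in% names(state)))
    abort(paste("cell state is missing:",
                paste(setdiff(state_names, names(state)), collapse = ", ")))
  state <- state[state_names]
  bad <- names(state)[!is.finite(state)]
  if (length(bad) > 0)
    abort(paste("non-finite state value in:", paste(bad, collapse = ", ")))
  g <- state[gate_names]
  bad <- gate_names[g < 0 | g > 1]
  if (length(bad) > 0)
    abort(paste("gate outside [0, 1]:", paste(bad, collapse = ", ")))
  cc <- state[conc_names]
  bad <- conc_names[cc <= 0]
  if (length(bad) > 0)
    abort(paste("non-positive concentration:", paste(bad, collapse = ", ")))
  if (strict_v && (state[["V"]] < -100 || state[["V"]] > 60))
    abort(sprintf("V = %.2f mV outside [-100, 60]", state[["V"]]))
  invisible(new_cell_state(unname(state)))
}

#' @export
print.cell_state <- function(x, ...) {
  cat("<cell_state> V =", format(x[["V"]], digits = 5), "mV\n")
  print(unclass(round(x, 6)))
  invisible(x)
}

#' Read or write a cell state as plain text
#'
#' Flat `name value` text serialization used by the fixture store.
#'
#' @param state a `cell_state`.
#' @param path file path.
#' @return `read_cell_state()` returns a `cell_state`;
#'   `write_cell_state()` returns `path` invisibly.
#' @export
write_cell_state <- function(state, path) {
  state <- validate_cell_state(state, strict_v = FALSE)
  writeLines(sprintf("%s %.17g", state_names, as.numeric(state)), path)
  invisible(path)
}

#' @rdname write_cell_state
#' @export
read_cell_state <- function(path) {
  tab <- read.table(path, col.names = c("name", "value"))
  x <- setNames(tab$value, tab$name)
  validate_cell_state(x, strict_v = FALSE)
}
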