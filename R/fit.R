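#' Critical-period curve parameters
#'
#' The dependence of the critical pacing period on the anisotropy ratio is
#' summarised by the closed form
#' \deqn{T(AR) = a + b \, AR^c / (AR_1 - AR)^d}
#' where `AR1` is the single-pulse critical anisotropy ratio (the vertical
#' asymptote), `a` the short-period (high-frequency) refractory asymptote in
#' ms, and `b`, `c`, `d` free shape parameters.
#'
#' @param ar1 single-pulse critical anisotropy ratio (> 1).
#' @param a refractory asymptote (ms, > 0).
#' @param b,c,d free parameters (`d > 0`).
#' @return object of class `fit_parameters`.
#' @examples
#' fit_parameters(ar1 = 3.72, a = 307, b = 0.0014, c = 9.09, d = 0.333)
#' @export
fit_parameters <- function(ar1, a, b, c, d) {
  if (ar1 <= 1) abort("`ar1` must exceed 1")
  if (a <= 0) abort("`a` must be positive (ms)")
  if (d <= 0) abort("`d` must be positive")
  structure(list(ar1 = ar1, a = a, b = b, c = c, d = d),
            class = "fit_parameters")
}

#' @export
print.fit_parameters <- function(x, ...) {
  cat(sprintf("<fit_parameters> AR1 = %g, a = %g ms, b = %g, c = %g, d = %g\n",
              x$ar1, x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Evaluate the critical-period curve T(AR)
#'
#' @param fit a [fit_parameters()] object.
#' @param AR anisotropy ratios, each strictly below `fit$ar1` (the curve has
#'   a vertical asymptote there).
#' @return critical periods (ms).
#' @examples
#' p <- fit_parameters(3.72, 307, 0.0014, 9.09, 0.333)
#' evaluate_T(p, 3.0)
#' @export
evaluate_T <- function(fit, AR) {
  stopifnot(inherits(fit, "fit_parameters"))
  if (any(AR >= fit$ar1))
    abort(sprintf("T(AR) is defined only for AR < AR1 = %g", fit$ar1))
  fit$a + fit$b * AR^fit$c / (fit$ar1 - AR)^fit$d
}

#' Fit the critical-period curve to measured brackets
#'
#' Least-squares fit of the free parameters (b, c, d) on the log-period
#' scale to the bracket midpoints `(T_pass + T_block)/2`, holding `ar1`
#' (measured independently by single-pulse bisection) and `a` (the
#' refractory asymptote) fixed. Starting values come from the linear
#' regression of `log(T - a)` on `log(AR)` and `log(ar1 - AR)`, refined
#' with Levenberg-Marquardt on `log(T)`.
#'
#' @param points tibble with columns `AR`, `T_pass`, `T_block` (a
#'   [critical_curve()] result); rows with missing brackets are dropped.
#' @param ar1 fixed single-pulse critical AR.
#' @param a fixed refractory asymptote (ms).
#' @return a `tar_fit` object; see [tidy.tar_fit()], [glance.tar_fit()].
#' @export
fit_T_curve <- function(points, ar1, a) {
  pts <- points[stats::complete.cases(points[c("AR", "T_pass", "T_block")]), ]
  if (nrow(pts) < 3) abort("need at least 3 complete (AR, T_pass, T_block) points")
  if (any(pts$AR >= ar1)) abort("all points must have AR < ar1")
  Tm <- (pts$T_pass + pts$T_block) / 2
  if (any(Tm <= a))
    abort("bracket midpoints must exceed the refractory asymptote `a`")
  # linearised start: log(T - a) = log b + c log AR - d log(ar1 - AR)
  lf <- lm(log(Tm - a) ~ log(pts$AR) + log(ar1 - pts$AR))
  start <- list(lb = unname(coef(lf)[1]), c = unname(coef(lf)[2]),
                d = -unname(coef(lf)[3]))
  dat <- data.frame(AR = pts$AR, logT = log(Tm))
  fit <- minpack.lm::nlsLM(
    logT ~ log(a + exp(lb) * AR^c / (ar1 - AR)^d),
    data = dat, start = start,
    lower = c(lb = -30, c = -10, d = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  pars <- fit_parameters(ar1 = ar1, a = a, b = unname(exp(cf["lb"])),
                         c = unname(cf["c"]), d = unname(cf["d"]))
  structure(list(parameters = pars, points = pts, midpoints = Tm,
                 nls = fit),
            class = "tar_fit")
}

#' @export
print.tar_fit <- function(x, ...) {
  cat("<tar_fit> critical-period curve fit\n")
  print(x$parameters)
  cat(sprintf("  %d points, RMS log-period residual %.4g\n",
              nrow(x$points), sqrt(mean(stats::resid(x$nls)^2))))
  invisible(x)
}

#' Tidy the fitted critical-period curve
#'
#' @param x a `tar_fit`.
#' @param ... unused.
#' @return one row per parameter with `term`, `estimate` and whether the
#'   parameter was `fixed` during fitting.
#' @export
tidy.tar_fit <- function(x, ...) {
  p <- x$parameters
  tibble(term = c("ar1", "a", "b", "c", "d"),
         estimate = c(p$ar1, p$a, p$b, p$c, p$d),
         fixed = c(TRUE, TRUE, FALSE, FALSE, FALSE))
}

#' @rdname tidy.tar_fit
#' @export
glance.tar_fit <- function(x, ...) {
  tibble(nobs = nrow(x$points),
         sigma_log = sqrt(mean(stats::resid(x$nls)^2)),
         ar1 = x$parameters$ar1, a = x$parameters$a)
}

#' @export
predict.tar_fit <- function(object, AR, ...) evaluate_T(object$parameters, AR)

#' @export
autoplot.tar_fit <- function(object, n = 200, ...) {
  p <- object$parameters
  grid <- tibble(AR = seq(min(object$points$AR) * 0.9,
                          p$ar1 - 1e-3, length.out = n))
  grid <- grid[grid$AR < p$ar1, ]
  grid$T <- evaluate_T(p, grid$AR)
  pts <- object$points
  pts$T_mid <- object$midpoints
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$AR)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$T)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$T_block,
                                        ymax = .data$T_pass), width = 0.02) +
    ggplot2::geom_point(ggplot2::aes(y = .data$T_mid)) +
    ggplot2::geom_vline(xintercept = p$ar1, linetype = "dashed") +
    ggplot2::labs(x = "anisotropy ratio", y = "critical period (ms)") +
    ggplot2::theme_minimal()
}
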