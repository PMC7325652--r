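#' Relative total error of cell-count estimates
#'
#' RTE at an expected level is the root-mean-square error of the estimates
#' divided by the expected number of input malignant cells (equivalently,
#' `sqrt(bias^2 + variance) / expected`). An unbiased Poisson counter at
#' expectation lambda has RTE `1/sqrt(lambda)`.
#'
#' @param estimates cell-count estimates.
#' @param expected expected malignant cells: a scalar, or a vector parallel to
#'   `estimates` defining levels.
#' @return a data frame with one row per expected level: `expected_cells`,
#'   `rte`, `n`.
#' @export
relative_total_error <- function(estimates, expected) {
  if (any(expected <= 0)) stop_invalid("expected must be > 0")
  if (length(expected) == 1) expected <- rep(expected, length(estimates))
  if (length(expected) != length(estimates))
    stop_invalid("expected must be scalar or parallel to estimates")
  levels <- sort(unique(expected))
  out <- data.frame(expected_cells = levels,
                    rte = vapply(levels, function(l) {
                      e <- estimates[expected == l]
                      sqrt(mean((e - l)^2)) / l
                    }, numeric(1)),
                    n = vapply(levels, function(l) sum(expected == l),
                               numeric(1)))
  rownames(out) <- NULL
  out
}

#' Sadler precision-profile fit
#'
#' Fits the flexible three-parameter variance-function model
#' `y = (beta1 + beta2 * x)^J` by nonlinear least squares, multi-started over
#' a grid of exponents J with linearised starting values for beta1 and beta2
#' at each J. `y` is typically the relative total error (or a variance) at
#' expected cell input `x`.
#'
#' @param x expected malignant-cell inputs (>= 4 distinct levels).
#' @param y precision statistic at each x (RTE by default usage; a raw
#'   variance works equally).
#' @param j_grid starting values for the exponent J.
#' @return an object of class `sadler_fit` with `coefficients` (beta1, beta2,
#'   J), `fitted`, `residual_norm`, `data`, and the underlying `nls` object.
#' @export
fit_sadler <- function(x, y, j_grid = setdiff(seq(-2, 2, by = 0.5), 0)) {
  if (length(unique(x)) < 4)
    stop_invalid("need >= 4 distinct x levels to fit the precision profile")
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  best <- NULL
  for (j0 in j_grid) {
    # linearised start: y^(1/j0) ~ b1 + b2 x (requires y > 0)
    st <- tryCatch({
      z <- y^(1 / j0)
      cf <- stats::coef(stats::lm(z ~ x))
      list(b1 = cf[[1]], b2 = cf[[2]], J = j0)
    }, error = function(e) list(b1 = 0.1, b2 = 1, J = j0))
    if (!all(is.finite(unlist(st)))) st <- list(b1 = 0.1, b2 = 1, J = j0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ (b1 + b2 * x)^J, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Sadler precision-profile fit failed from every start")
  cf <- stats::coef(best$fit)
  structure(list(coefficients = cf,
                 fitted = stats::fitted(best$fit),
                 residual_norm = sqrt(best$rss),
                 data = data.frame(x = x, y = y),
                 nls_fit = best$fit),
            class = "sadler_fit")
}

#' @export
coef.sadler_fit <- function(object, ...) object$coefficients

#' @export
print.sadler_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Sadler precision profile: y = (b1 + b2*x)^J\n")
  cat(sprintf("  b1 = %.6g, b2 = %.6g, J = %.6g  (residual norm %.3g)\n",
              cf[["b1"]], cf[["b2"]], cf[["J"]], x$residual_norm))
  invisible(x)
}

#' Predicted precision statistic at new inputs
#'
#' @param object a `sadler_fit`.
#' @param newdata numeric vector of expected cell inputs.
#' @param ... unused.
#' @return predicted y values.
#' @export
predict.sadler_fit <- function(object, newdata, ...) {
  cf <- object$coefficients
  (cf[["b1"]] + cf[["b2"]] * newdata)^cf[["J"]]
}

#' @export
plot.sadler_fit <- function(x, threshold = NULL, ...) {
  plot(x$data$x, x$data$y, log = "x", xlab = "expected malignant cells",
       ylab = "precision statistic", pch = 19, ...)
  xs <- exp(seq(log(min(x$data$x)), log(max(x$data$x)), length.out = 200))
  graphics::lines(xs, predict(x, xs))
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2, col = 2)
  invisible(x)
}

#' Limit of quantitation from a precision profile
#'
#' Solves the fitted Sadler curve for the input at which it reaches the
#' relative-total-error threshold (default 70%), by bisection over the fitted
#' data range.
#'
#' @param fit a [fit_sadler()] object.
#' @param threshold relative total error defining the LoQ.
#' @return expected malignant cells at the threshold (the LoQ).
#' @export
loq <- function(fit, threshold = 0.70) {
  rng <- range(fit$data$x)
  f <- function(z) predict(fit, z) - threshold
  if (f(rng[1]) * f(rng[2]) > 0) {
    cond <- structure(class = c("mrdseq_out_of_range", "error", "condition"),
                      list(message = sprintf(
                        "fitted precision profile does not cross %.2f on [%.3g, %.3g]",
                        threshold, rng[1], rng[2]), call = sys.call()))
    stop(cond)
  }
  stats::uniroot(f, rng, tol = 1e-10)$root
}
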