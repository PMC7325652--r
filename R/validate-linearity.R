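#' Polynomial-method linearity assessment
#'
#' Implements the polynomial linearity procedure: fit first- (linear),
#' second- (quadratic), and third-order (cubic) polynomials to the observed
#' vs expected frequencies; if no nonlinear coefficient is significant at
#' `alpha`, linearity holds over the full range. Otherwise the best-fitting
#' higher-order model is compared with the linear fit at each tested
#' frequency; if every deviation is within `tol` (default 5%) the result is
#' acceptably linear; otherwise the extreme frequency with the larger
#' deviation is dropped and the procedure repeats on the reduced range.
#'
#' Regression is performed on log10-transformed frequencies (both axes span
#' orders of magnitude) and the percent deviation is evaluated on the
#' back-transformed scale. Observed zeros cannot be log-transformed and are
#' dropped (their count is reported).
#'
#' @param observed measured frequencies (or cell counts), with replicates.
#' @param expected expected frequencies, parallel to `observed`
#'   (>= 4 distinct levels).
#' @param alpha significance level for the nonlinear coefficients.
#' @param tol maximum tolerated fractional deviation of the polynomial from
#'   the linear fit (0.05 = 5%).
#' @param min_levels smallest number of levels the range may be reduced to.
#' @return an object of class `linearity_report`.
#' @export
assess_linearity <- function(observed, expected, alpha = 0.05, tol = 0.05,
                             min_levels = 4) {
  if (length(observed) != length(expected))
    stop_invalid("observed and expected must have equal length")
  keep <- observed > 0 & expected > 0
  n_dropped_zero <- sum(!keep)
  lx <- log10(expected[keep])
  ly <- log10(observed[keep])
  if (length(unique(lx)) < 4) {
    cond <- structure(
      class = c("mrdseq_insufficient_design", "error", "condition"),
      list(message = "linearity assessment needs >= 4 distinct expected frequencies",
           call = sys.call()))
    stop(cond)
  }

  all_levels <- sort(unique(lx))
  levels_in <- all_levels
  dropped <- numeric()
  verdict <- NA_character_
  chosen_order <- 1L
  deviations <- NULL
  lin_fit <- NULL

  repeat {
    sel <- lx %in% levels_in
    x <- lx[sel]; y <- ly[sel]
    nlev <- length(levels_in)
    lin_fit <- stats::lm(y ~ x)
    fits <- list(lin_fit)
    max_order <- min(3L, nlev - 1L)
    for (k in 2:max_order) fits[[k]] <- stats::lm(y ~ poly(x, k, raw = TRUE))

    # significance of the nonlinear coefficients (NaN p from a saturated or
    # zero-residual fit counts as not significant)
    pvals <- unlist(lapply(fits[-1], function(f) {
      cf <- suppressWarnings(stats::coef(summary(f)))
      cf[-(1:2), "Pr(>|t|)"]
    }))
    signif_nl <- any(!is.na(pvals) & !is.nan(pvals) & pvals < alpha)

    if (!signif_nl) {
      verdict <- "linear"
      chosen_order <- 1L
      deviations <- data.frame(expected = 10^levels_in,
                               deviation_pct = rep(0, nlev))
      break
    }
    # best-fitting higher-order model
    aics <- vapply(fits[-1], stats::AIC, numeric(1))
    best_k <- which.min(aics) + 1L
    chosen_order <- best_k
    poly_fit <- fits[[best_k]]
    pred_lin <- stats::predict(lin_fit,
                               newdata = data.frame(x = levels_in))
    pred_poly <- stats::predict(poly_fit,
                                newdata = data.frame(x = levels_in))
    dev_pct <- 100 * (10^(pred_poly - pred_lin) - 1)
    deviations <- data.frame(expected = 10^levels_in, deviation_pct = dev_pct)
    if (all(abs(dev_pct) <= 100 * tol)) {
      verdict <- "linear"
      break
    }
    if (nlev <= min_levels) {
      verdict <- "nonlinear"
      break
    }
    # reduce the range: drop the extreme level with the larger deviation
    if (abs(dev_pct[1]) >= abs(dev_pct[nlev])) {
      dropped <- c(dropped, 10^levels_in[1])
      levels_in <- levels_in[-1]
    } else {
      dropped <- c(dropped, 10^levels_in[nlev])
      levels_in <- levels_in[-nlev]
    }
  }

  cf <- stats::coef(lin_fit)
  structure(list(verdict = verdict,
                 chosen_order = chosen_order,
                 slope = cf[[2]], intercept = cf[[1]],
                 accepted_range = range(10^levels_in),
                 deviations = deviations,
                 dropped_levels = dropped,
                 range_reduced = length(dropped) > 0,
                 n_dropped_zero = n_dropped_zero,
                 alpha = alpha, tol = tol,
                 linear_fit = lin_fit),
            class = "linearity_report")
}

#' @export
print.linearity_report <- function(x, ...) {
  cat(sprintf("Linearity (polynomial method): verdict %s\n", x$verdict))
  cat(sprintf("  linear fit (log10 scale): slope %.4f, intercept %.4f\n",
              x$slope, x$intercept))
  cat(sprintf("  accepted range: %.4g to %.4g", x$accepted_range[1],
              x$accepted_range[2]))
  if (x$range_reduced)
    cat(sprintf("  (%d level(s) dropped)", length(x$dropped_levels)))
  cat("\n")
  if (x$n_dropped_zero > 0)
    cat(sprintf("  %d zero observation(s) excluded from the log fit\n",
                x$n_dropped_zero))
  invisible(x)
}

#' @export
coef.linearity_report <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}
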