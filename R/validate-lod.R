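#' Probit limit of detection
#'
#' Models the probability of MRD detection as a function of expected
#' malignant-cell input with a maximum-likelihood probit regression on
#' log10(dose) (a linear dose scale is available as an option). The LoD is
#' the dose at which the fitted curve reaches the target detection
#' probability (default 95%). The confidence interval comes from a
#' nonparametric bootstrap stratified by dose level: detection outcomes are
#' resampled with replacement within each dose and the fit repeated.
#'
#' @param doses expected malignant cells per sample.
#' @param detections logical (or 0/1) detection outcome per sample.
#' @param target detection probability defining the LoD.
#' @param dose_scale `"log10"` (default) or `"linear"`.
#' @param n_boot bootstrap replicates for the CI (0 skips the CI).
#' @param conf_level CI level.
#' @param seed seed for the bootstrap.
#' @return an object of class `probit_lod` with elements `coefficients`,
#'   `lod`, `ci`, `target`, `data`, `glm_fit`.
#' @export
fit_probit <- function(doses, detections, target = 0.95,
                       dose_scale = c("log10", "linear"),
                       n_boot = 2000, conf_level = 0.95, seed = 1L) {
  dose_scale <- match.arg(dose_scale)
  detections <- as.logical(detections)
  if (length(doses) != length(detections))
    stop_invalid("doses and detections must have equal length")
  if (length(unique(doses)) < 2)
    stop_invalid("need at least 2 dose levels")
  if (all(detections) || !any(detections)) {
    cond <- structure(class = c("mrdseq_separation", "error", "condition"),
                      list(message = "complete separation: all outcomes identical; the probit curve is not identifiable",
                           call = sys.call()))
    stop(cond)
  }
  # aggregate to dose-level binomial counts: identical fit, cheap refits
  agg <- stats::aggregate(cbind(k = detections, n = 1) ~ doses, FUN = sum)
  xf <- function(d) if (dose_scale == "log10") log10(d) else d
  fit_one <- function(k, n) {
    f <- suppressWarnings(stats::glm(cbind(k, n - k) ~ xf(agg$doses),
                                     family = stats::binomial("probit")))
    a <- stats::coef(f)[[1]]; b <- stats::coef(f)[[2]]
    if (!is.finite(b) || b <= 0) return(list(fit = f, lod = NA_real_))
    q <- (stats::qnorm(target) - a) / b
    list(fit = f, lod = if (dose_scale == "log10") 10^q else q)
  }
  main <- fit_one(agg$k, agg$n)
  ci <- c(lower = NA_real_, upper = NA_real_)
  boot_lods <- NULL
  if (n_boot > 0) {
    set.seed(derive_seed(seed, "probit-boot"))
    boot_lods <- vapply(seq_len(n_boot), function(b) {
      kb <- stats::rbinom(nrow(agg), agg$n, agg$k / agg$n)
      tryCatch(fit_one(kb, agg$n)$lod, error = function(e) NA_real_)
    }, numeric(1))
    probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
    ci <- stats::quantile(boot_lods, probs, na.rm = TRUE, names = FALSE)
    names(ci) <- c("lower", "upper")
  }
  structure(list(coefficients = stats::coef(main$fit),
                 lod = main$lod, ci = ci, target = target,
                 dose_scale = dose_scale, conf_level = conf_level,
                 n_boot = n_boot, data = agg, glm_fit = main$fit,
                 boot_lods = boot_lods),
            class = "probit_lod")
}

#' @export
print.probit_lod <- function(x, ...) {
  cat(sprintf("Probit limit of detection (%.0f%% detection, %s dose scale)\n",
              100 * x$target, x$dose_scale))
  cat(sprintf("  LoD: %.4g cells", x$lod))
  if (!is.na(x$ci[["lower"]]))
    cat(sprintf("  (%.0f%% CI %.4g-%.4g, %d bootstrap reps)",
                100 * x$conf_level, x$ci[["lower"]], x$ci[["upper"]], x$n_boot))
  cat("\n")
  invisible(x)
}

#' @export
coef.probit_lod <- function(object, ...) object$coefficients

#' Predicted detection probability at a dose
#'
#' @param object a `probit_lod` fit.
#' @param newdata numeric vector of doses (expected malignant cells).
#' @param ... unused.
#' @return detection probabilities.
#' @export
predict.probit_lod <- function(object, newdata, ...) {
  x <- if (object$dose_scale == "log10") log10(newdata) else newdata
  stats::pnorm(object$coefficients[[1]] + object$coefficients[[2]] * x)
}

#' @export
plot.probit_lod <- function(x, ...) {
  d <- x$data
  plot(d$doses, d$k / d$n, log = if (x$dose_scale == "log10") "x" else "",
       xlab = "expected malignant cells", ylab = "detection probability",
       ylim = c(0, 1), pch = 19, ...)
  xs <- exp(seq(log(min(d$doses)), log(max(d$doses)), length.out = 200))
  graphics::lines(xs, predict(x, xs))
  graphics::abline(h = x$target, lty = 2)
  graphics::abline(v = x$lod, lty = 2)
  invisible(x)
}
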