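#' Nested-bootstrap relative bias
#'
#' Estimates the relative bias of MRD cell-count measurements against their
#' expected values, per stratum (e.g. disease indication x input cancer
#' cells), with percentile confidence intervals from a nested bootstrap that
#' respects the hierarchy of the data: samples are resampled with replacement
#' within each stratum, then replicate measurements are resampled with
#' replacement within each drawn sample.
#'
#' @param data a data frame with columns `stratum`, `sample`, `observed`,
#'   `expected` (one row per replicate measurement).
#' @param n_boot bootstrap replicates (default 10,000).
#' @param conf_level CI level.
#' @param seed integer seed.
#' @return an object of class `bias_report`: one row per stratum with
#'   `relative_bias` (mean of per-replicate `(observed - expected)/expected`),
#'   percentile CI bounds, and a `degenerate` flag for single-sample strata.
#' @export
bootstrap_bias <- function(data, n_boot = 10000, conf_level = 0.95,
                           seed = 1L) {
  need <- c("stratum", "sample", "observed", "expected")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop_invalid("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(data$expected <= 0)) stop_invalid("expected must be > 0")
  data$rel <- (data$observed - data$expected) / data$expected
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  strata <- unique(data$stratum)
  rows <- list()
  set.seed(derive_seed(seed, "bias-boot"))
  for (s in strata) {
    d <- data[data$stratum == s, , drop = FALSE]
    by_sample <- split(d$rel, d$sample)
    k <- length(by_sample)
    point <- mean(d$rel)
    sizes <- lengths(by_sample)
    if (length(unique(sizes)) == 1 && k > 1) {
      # balanced fast path: fully vectorised double resampling
      r <- sizes[[1]]
      vals <- matrix(unlist(by_sample), nrow = r)
      samp <- sample.int(k, k * n_boot, replace = TRUE)
      ridx <- sample.int(r, r * k * n_boot, replace = TRUE)
      drawn <- vals[cbind(ridx, rep(samp, each = r))]
      boots <- colMeans(matrix(drawn, nrow = r * k))
    } else {
      boots <- vapply(seq_len(n_boot), function(b) {
        chosen <- sample.int(k, k, replace = TRUE)
        mean(unlist(lapply(by_sample[chosen], function(v) {
          v[sample.int(length(v), length(v), replace = TRUE)]
        })))
      }, numeric(1))
    }
    ci <- stats::quantile(boots, probs, names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = s, n_samples = k, n_replicates = nrow(d),
      relative_bias = point, ci_lower = ci[1], ci_upper = ci[2],
      degenerate = k < 2, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_boot = n_boot, conf_level = conf_level,
            class = c("bias_report", "data.frame"))
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("Nested-bootstrap relative bias (%d replicates, %.0f%% percentile CI)\n",
              attr(x, "n_boot"), 100 * attr(x, "conf_level")))
  tab <- as.data.frame(x)
  tab$relative_bias <- sprintf("%+.1f%%", 100 * tab$relative_bias)
  tab$ci_lower <- sprintf("%+.1f%%", 100 * tab$ci_lower)
  tab$ci_upper <- sprintf("%+.1f%%", 100 * tab$ci_upper)
  print(tab, row.names = FALSE)
  if (any(x$degenerate))
    cat("  note: strata with a single sample have degenerate CIs\n")
  invisible(x)
}
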