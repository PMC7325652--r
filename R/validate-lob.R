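#' Nonparametric limit of blank
#'
#' The LoB is the empirical 95th percentile (more generally, the
#' `1 - alpha` quantile) of MRD measurements among all tracked sequences in
#' all analyte-free samples, computed with the CLSI-style nonparametric rank
#' rule: rank position `0.5 + (1 - alpha) * n` with linear interpolation
#' between order statistics. Reported per DNA-input level when a grouping is
#' supplied, and overall.
#'
#' @param blank_values MRD frequencies (or template counts) observed in blank
#'   samples, one value per tracked sequence per sample.
#' @param alpha type I error rate (default 0.05, i.e. the 95th percentile).
#' @param group optional grouping vector (e.g. DNA input level) parallel to
#'   `blank_values`.
#' @return an object of class `lob_estimate` with the overall `value` and a
#'   `by_group` data frame.
#' @export
estimate_lob <- function(blank_values, alpha = 0.05, group = NULL) {
  if (length(blank_values) == 0)
    stop_missing_data("no blank measurements supplied")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  pct <- function(v) {
    s <- sort(v)
    n <- length(s)
    r <- 0.5 + (1 - alpha) * n
    if (r <= 1) return(s[1])
    if (r >= n) return(s[n])
    i <- floor(r)
    s[i] + (r - i) * (s[i + 1] - s[i])
  }
  by_group <- NULL
  if (!is.null(group)) {
    if (length(group) != length(blank_values))
      stop_invalid("group must be parallel to blank_values")
    vals <- tapply(blank_values, group, pct)
    by_group <- data.frame(group = names(vals), lob = as.numeric(vals),
                           n = as.integer(table(group)[names(vals)]),
                           stringsAsFactors = FALSE)
    rownames(by_group) <- NULL
  }
  structure(list(value = pct(blank_values), alpha = alpha,
                 n = length(blank_values), by_group = by_group),
            class = "lob_estimate")
}

#' @export
print.lob_estimate <- function(x, ...) {
  cat(sprintf("Limit of blank (%.0fth percentile of %d blank measurements): %.4g\n",
              100 * (1 - x$alpha), x$n, x$value))
  if (!is.null(x$by_group)) {
    cat("  by DNA input level:\n")
    print(x$by_group, row.names = FALSE)
  }
  invisible(x)
}
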