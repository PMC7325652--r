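#' Total nucleated cells in a sample
#'
#' Quantified from amplicons of genomic regions that are diploid in normal
#' gDNA: `reference_templates / 2`. When reference counts are absent, falls
#' back to the DNA-mass conversion `round(dna_mass_pg / pg_per_diploid_cell)`.
#'
#' @param sample a `contrived_sample` (or any list with `reference_templates`
#'   and/or `dna_mass_pg`).
#' @param const [assay_constants()].
#' @return total nucleated cell count.
#' @export
total_nucleated_cells <- function(sample, const = assay_constants()) {
  if (!is.null(sample$reference_templates) &&
      !is.na(sample$reference_templates)) {
    return(sample$reference_templates / 2)
  }
  if (!is.null(sample$dna_mass_pg) && !is.na(sample$dna_mass_pg)) {
    return(cells_from_mass(sample$dna_mass_pg, const))
  }
  stop_missing_data("sample carries neither reference templates nor DNA mass")
}

#' Match sample sequences against a tracking profile
#'
#' An observed sequence is assigned to a tracked sequence iff it has the same
#' length and Hamming distance <= N (that sequence's mismatch budget). Each
#' observed sequence matches at most one tracked sequence: the nearest, with
#' ties broken toward the lowest-index tracked sequence (recorded in the
#' `tie` column). When the sample carries no read records, its per-sequence
#' template counts are used directly as exact (mismatch-0) matches.
#'
#' @param sample a `contrived_sample`.
#' @param profile a `tracking_profile` (non-empty).
#' @return a data frame of alignment records: `tracked_index`,
#'   `tracked_sequence`, `observed_sequence`, `length`, `mismatches`,
#'   `allowed`, `abundance`, `tie`.
#' @export
match_tracked <- function(sample, profile) {
  tr <- profile$tracked
  if (is.null(tr) || nrow(tr) == 0) stop_missing_data("empty tracking profile")
  obs <- sample$reads
  if (is.null(obs)) {
    tt <- sample$tracked
    idx <- match(tt$sequence, tr$sequence)
    keep <- !is.na(idx) & tt$templates > 0
    return(data.frame(tracked_index = idx[keep],
                      tracked_sequence = tt$sequence[keep],
                      observed_sequence = tt$sequence[keep],
                      length = nchar(tt$sequence[keep]),
                      mismatches = rep(0L, sum(keep)),
                      allowed = tr$allowed_mutations[idx[keep]],
                      abundance = tt$templates[keep],
                      tie = rep(FALSE, sum(keep)),
                      stringsAsFactors = FALSE))
  }
  records <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    d <- vapply(tr$sequence, hamming, numeric(1), b = obs$sequence[i])
    ok <- which(d <= tr$allowed_mutations)
    if (length(ok) == 0) next
    best <- ok[d[ok] == min(d[ok])]
    j <- best[1]
    records[[i]] <- data.frame(tracked_index = j,
                               tracked_sequence = tr$sequence[j],
                               observed_sequence = obs$sequence[i],
                               length = nchar(tr$sequence[j]),
                               mismatches = as.integer(d[j]),
                               allowed = tr$allowed_mutations[j],
                               abundance = obs$abundance[i],
                               tie = length(best) > 1,
                               stringsAsFactors = FALSE)
  }
  records <- records[!vapply(records, is.null, logical(1))]
  if (length(records) == 0) {
    return(data.frame(tracked_index = integer(), tracked_sequence = character(),
                      observed_sequence = character(), length = integer(),
                      mismatches = integer(), allowed = integer(),
                      abundance = numeric(), tie = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Consensus malignant-cell count across tracked sequences
#'
#' Each tracked rearrangement independently samples one gDNA template per
#' malignant cell, so each per-sequence template count is an unbiased estimate
#' of the malignant-cell number; the consensus combines them. The default is
#' the unweighted mean over all tracked sequences, zero counts included.
#'
#' @param per_sequence_cells numeric vector of per-sequence cell estimates
#'   (one entry per tracked sequence).
#' @param method `"mean"` (default), `"weighted"` (abundance-weighted mean,
#'   i.e. total templates over sequences carrying them, which reduces to the
#'   mean here), or `"max"`.
#' @return consensus malignant-cell count.
#' @export
consensus_malignant_cells <- function(per_sequence_cells,
                                      method = c("mean", "weighted", "max")) {
  if (length(per_sequence_cells) == 0)
    stop_missing_data("no tracked sequences to form a consensus")
  method <- match.arg(method)
  switch(method,
         mean = mean(per_sequence_cells),
         weighted = if (sum(per_sequence_cells) == 0) 0 else
           sum(per_sequence_cells^2) / sum(per_sequence_cells),
         max = max(per_sequence_cells))
}

#' MRD frequency
#'
#' @param consensus_cells consensus malignant-cell count.
#' @param total_cells total nucleated cells.
#' @return `consensus_cells / total_cells`; exactly 0 when the consensus is 0.
#' @export
mrd_frequency <- function(consensus_cells, total_cells) {
  if (total_cells <= 0) stop_invalid("total_cells must be > 0")
  if (consensus_cells == 0) return(0)
  consensus_cells / total_cells
}

#' Quantify MRD in a sample against a tracking profile
#'
#' Runs sequence matching, forms per-sequence cell estimates (summed template
#' abundance per tracked sequence), the consensus malignant-cell count, total
#' nucleated cells, and the MRD frequency. A sample is called detected iff any
#' tracked sequence carries at least one template.
#'
#' @param sample a `contrived_sample`.
#' @param profile a `tracking_profile`.
#' @param const [assay_constants()].
#' @param consensus consensus method, see [consensus_malignant_cells()].
#' @return an object of class `mrd_result`.
#' @export
mrd_quantify <- function(sample, profile, const = assay_constants(),
                         consensus = "mean") {
  records <- match_tracked(sample, profile)
  per_seq <- numeric(nrow(profile$tracked))
  names(per_seq) <- profile$tracked$sequence
  if (nrow(records)) {
    sums <- tapply(records$abundance, records$tracked_index, sum)
    per_seq[as.integer(names(sums))] <- as.numeric(sums)
  }
  cons <- consensus_malignant_cells(per_seq, method = consensus)
  total <- total_nucleated_cells(sample, const)
  structure(list(sample_id = sample$sample_id,
                 per_sequence_cells = per_seq,
                 consensus_malignant_cells = cons,
                 total_nucleated_cells = total,
                 mrd_frequency = mrd_frequency(cons, total),
                 detected = any(per_seq >= 1),
                 records = records),
            class = "mrd_result")
}

#' @export
print.mrd_result <- function(x, ...) {
  cat(sprintf("MRD result for '%s':\n", x$sample_id %||% "<sample>"))
  cat(sprintf("  consensus malignant cells: %.4g\n",
              x$consensus_malignant_cells))
  cat(sprintf("  total nucleated cells    : %.7g\n", x$total_nucleated_cells))
  cat(sprintf("  MRD frequency            : %.3e (%s%%)\n", x$mrd_frequency,
              format(100 * x$mrd_frequency, digits = 3)))
  cat(sprintf("  detected                 : %s\n", x$detected))
  invisible(x)
}

#' As a data frame: one row per MRD result
#'
#' @param x an `mrd_result`.
#' @param ... unused.
#' @return a one-row data frame.
#' @export
as.data.frame.mrd_result <- function(x, ...) {
  data.frame(sample_id = x$sample_id %||% NA_character_,
             consensus_malignant_cells = x$consensus_malignant_cells,
             total_nucleated_cells = x$total_nucleated_cells,
             mrd_frequency = x$mrd_frequency,
             detected = x$detected,
             stringsAsFactors = FALSE)
}

#' Overall percent agreement between tracked and observed sequences
#'
#' For alignment records with `mismatches <= allowed`, sums abundance-weighted
#' positive agreement `(length - mismatches) * abundance` and negative
#' agreement `mismatches * abundance` in exact integer arithmetic, and reports
#' `OPA = 100 * PA / (PA + NA)` with a Wilson 95% confidence interval on the
#' disagreement proportion, plus the Phred restatement of the disagreement
#' rate.
#'
#' @param records a data frame with columns `length`, `mismatches`, `allowed`,
#'   `abundance` (e.g. from [match_tracked()]).
#' @param conf_level confidence level for the interval.
#' @return an object of class `opa_report`.
#' @export
compute_opa <- function(records, conf_level = 0.95) {
  r <- records[records$mismatches <= records$allowed, , drop = FALSE]
  pa <- sum((r$length - r$mismatches) * r$abundance)
  na_ <- sum(r$mismatches * r$abundance)
  n <- pa + na_
  if (n == 0) stop_missing_data("no nucleotides assessed: OPA undefined")
  rate <- na_ / n
  # Wilson interval on the disagreement proportion
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  centre <- (rate + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(rate * (1 - rate) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  lo_rate <- max(0, centre - half)
  hi_rate <- min(1, centre + half)
  structure(list(nucleotides_assessed = n,
                 positive_agreement = pa,
                 negative_agreement = na_,
                 opa = 100 * pa / n,
                 disagreement_rate = rate,
                 phred = phred_score(rate),
                 ci = c(lower = 100 * (1 - hi_rate),
                        upper = 100 * (1 - lo_rate)),
                 conf_level = conf_level),
            class = "opa_report")
}

#' @export
print.opa_report <- function(x, digits = 6, ...) {
  cat("Sequence agreement (OPA):\n")
  cat(sprintf("  nucleotides assessed: %s\n",
              format(x$nucleotides_assessed, big.mark = ",")))
  cat(sprintf("  OPA: %.*f%%  (%.0f%% CI %.*f-%.*f)\n", digits, x$opa,
              100 * x$conf_level, digits, x$ci[["lower"]], digits,
              x$ci[["upper"]]))
  cat(sprintf("  disagreement rate: %.3g  (Phred %.1f)\n",
              x$disagreement_rate, x$phred))
  invisible(x)
}

#' Phred quality score of a disagreement rate
#'
#' The standard scaling `-10 * log10(rate)`: a disagreement rate of
#' 3.5 per 100,000 nucleotides corresponds to a Phred score near 44.5.
#'
#' @param rate disagreement rate in \[0, 1\].
#' @param cap score returned for a rate of exactly 0.
#' @return Phred score.
#' @export
phred_score <- function(rate, cap = 60) {
  if (any(rate < 0 | rate > 1)) stop_invalid("rate must lie in [0, 1]")
  ifelse(rate == 0, cap, -10 * log10(rate))
}
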