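#' Assay constants
#'
#' Fixed physical and statistical constants of the MRD assay. A human diploid
#' genome weighs 6.53 pg, so DNA mass converts to cell equivalents as
#' `mass_pg / 6.53`; the limit of detection is defined at 95% detection
#' probability, the limit of quantitation at 70% relative total error, and
#' the limit of blank at the 95th percentile of blank measurements.
#'
#' @param pg_per_diploid_cell DNA mass of one diploid cell, in picograms.
#' @param detection_target detection probability defining the LoD.
#' @param rte_threshold relative total error defining the LoQ.
#' @param lob_alpha type I error rate defining the LoB percentile.
#' @return an object of class `assay_constants`.
#' @export
#' @examples
#' const <- assay_constants()
#' cells_from_mass(2e7, const)  # 20 ug of DNA -> 3,062,787 cell equivalents
assay_constants <- function(pg_per_diploid_cell = 6.53,
                            detection_target = 0.95,
                            rte_threshold = 0.70,
                            lob_alpha = 0.05) {
  if (pg_per_diploid_cell <= 0)
    stop_invalid("pg_per_diploid_cell must be > 0")
  for (p in c(detection_target, rte_threshold, lob_alpha)) {
    if (p <= 0 || p >= 1) stop_invalid("probabilities must lie in (0, 1)")
  }
  structure(list(pg_per_diploid_cell = pg_per_diploid_cell,
                 detection_target = detection_target,
                 rte_threshold = rte_threshold,
                 lob_alpha = lob_alpha),
            class = "assay_constants")
}

#' Convert a DNA mass to diploid cell equivalents
#'
#' @param dna_mass_pg DNA mass in picograms.
#' @param const an [assay_constants()] object.
#' @param round round to the nearest whole cell (the convention used when
#'   reporting total nucleated cells).
#' @return number of diploid cell equivalents.
#' @export
cells_from_mass <- function(dna_mass_pg, const = assay_constants(),
                            round = TRUE) {
  if (any(dna_mass_pg <= 0)) stop_invalid("dna_mass_pg must be > 0")
  x <- dna_mass_pg / const$pg_per_diploid_cell
  if (round) base::round(x) else x
}

#' @export
print.assay_constants <- function(x, ...) {
  cat("Assay constants:\n")
  cat(sprintf("  pg per diploid cell : %.2f\n", x$pg_per_diploid_cell))
  cat(sprintf("  LoD detection target: %.2f\n", x$detection_target))
  cat(sprintf("  LoQ RTE threshold   : %.2f\n", x$rte_threshold))
  cat(sprintf("  LoB alpha           : %.2f\n", x$lob_alpha))
  invisible(x)
}
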