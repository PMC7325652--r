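# Readers and writers. Tables are tab-separated (sequence fields make CSV
# quoting ambiguous); machine reports are JSON; repertoires and clone
# sequences are FASTA with key=value metadata in the header.

SHEET_COLUMNS <- c("sample_id", "dna_mass_pg", "expected_malignant_cells",
                   "reference_templates", "sequence", "locus", "templates")

#' Write contrived samples as a tab-separated sample sheet
#'
#' One row per (sample, tracked sequence). Columns: `sample_id`,
#' `dna_mass_pg`, `expected_malignant_cells`, `reference_templates`,
#' `sequence`, `locus`, `templates`.
#'
#' @param samples a list of `contrived_sample` objects (or a single one).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  if (inherits(samples, "contrived_sample")) samples <- list(samples)
  rows <- lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id,
               dna_mass_pg = s$dna_mass_pg,
               expected_malignant_cells = s$expected_malignant_cells,
               reference_templates = s$reference_templates,
               sequence = s$tracked$sequence,
               locus = s$tracked$locus,
               templates = s$tracked$templates,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet back into contrived samples
#'
#' Validates the schema and reports malformed rows with their line numbers
#' (line 1 is the header).
#'
#' @param path a TSV written by [write_sample_sheet()] (or hand-built with the
#'   same columns).
#' @return a list of `contrived_sample` objects.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(SHEET_COLUMNS, names(tab))
  if (length(missing_cols)) {
    cond <- structure(class = c("mrdseq_schema", "error", "condition"),
                      list(message = paste0("sample sheet lacks required column(s): ",
                                            paste(missing_cols, collapse = ", ")),
                           call = sys.call()))
    stop(cond)
  }
  if (nrow(tab) == 0) {
    warning("sample sheet is empty (header only)", call. = FALSE)
    return(list())
  }
  bad <- which(tab$templates < 0 | tab$dna_mass_pg <= 0 |
                 tab$expected_malignant_cells < 0)
  if (length(bad)) {
    cond <- structure(class = c("mrdseq_schema", "error", "condition"),
                      list(message = paste0("invalid values at line(s): ",
                                            paste(bad + 1, collapse = ", ")),
                           call = sys.call()))
    stop(cond)
  }
  lapply(split(tab, factor(tab$sample_id, levels = unique(tab$sample_id))),
         function(g) {
           structure(list(sample_id = g$sample_id[1],
                          patient_id = NA_character_,
                          dna_mass_pg = g$dna_mass_pg[1],
                          expected_malignant_cells =
                            g$expected_malignant_cells[1],
                          tracked = data.frame(sequence = g$sequence,
                                               locus = g$locus,
                                               templates = g$templates,
                                               stringsAsFactors = FALSE),
                          reference_templates = g$reference_templates[1],
                          background = NULL, reads = NULL),
                     class = "contrived_sample")
         })
}

#' Write a repertoire (or clone sequences) as FASTA
#'
#' Headers carry `key=value` metadata: locus and relative frequency for
#' repertoire clones.
#'
#' @param repertoire a `healthy_repertoire` or `malignant_clone`.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(repertoire, path) {
  if (inherits(repertoire, "malignant_clone")) {
    seqs <- repertoire$sequences$sequence
    names(seqs) <- sprintf("%s_seq%d locus=%s", repertoire$patient_id,
                           seq_along(seqs), repertoire$sequences$locus)
  } else {
    cl <- repertoire$clones
    seqs <- cl$sequence
    names(seqs) <- sprintf("%s_clone%06d locus=%s frequency=%.6g",
                           repertoire$donor_id, seq_along(seqs), cl$locus,
                           cl$frequency)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA repertoire written by [write_fasta()]
#'
#' @param path FASTA path.
#' @return a `healthy_repertoire`.
#' @export
read_fasta_repertoire <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  get_kv <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    sub(paste0(key, "="), "", m)
  }
  clones <- data.frame(locus = get_kv("locus"),
                       sequence = as.character(ss),
                       frequency = as.numeric(get_kv("frequency")),
                       stringsAsFactors = FALSE)
  donor <- sub("_clone.*", "", sub(" .*", "", hdr[1]))
  structure(list(clones = clones, donor_id = donor),
            class = "healthy_repertoire")
}

#' Write a tracking profile as JSON
#'
#' Serialises the tracked sequences (with mismatch budgets and uniqueness
#' scores) and, when present, the per-candidate criterion audit trail.
#'
#' @param profile a `tracking_profile`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, path) {
  jsonlite::write_json(list(patient_id = profile$patient_id,
                            tracked = profile$tracked,
                            audit = profile$audit),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a tracking profile from JSON
#'
#' @param path JSON written by [write_profile()].
#' @return a `tracking_profile`.
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(patient_id = x$patient_id,
                 tracked = as.data.frame(x$tracked),
                 audit = if (!is.null(x$audit)) as.data.frame(x$audit)),
            class = "tracking_profile")
}

# Coerce each report object to plain lists/frames for JSON.
report_data <- function(x) UseMethod("report_data")

#' @export
report_data.default <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  x[!vapply(x, function(e) is.function(e) || inherits(e, c("lm", "glm", "nls", "merMod")),
            logical(1))]
}

#' @export
report_data.probit_lod <- function(x) {
  list(lod = x$lod, ci = as.list(x$ci), target = x$target,
       dose_scale = x$dose_scale, coefficients = as.list(x$coefficients),
       n_boot = x$n_boot)
}

#' @export
report_data.sadler_fit <- function(x) {
  list(coefficients = as.list(x$coefficients),
       residual_norm = x$residual_norm, data = x$data)
}

#' @export
report_data.lob_estimate <- function(x) {
  list(value = x$value, alpha = x$alpha, n = x$n, by_group = x$by_group)
}

#' @export
report_data.linearity_report <- function(x) {
  list(verdict = x$verdict, chosen_order = x$chosen_order, slope = x$slope,
       intercept = x$intercept, accepted_range = x$accepted_range,
       deviations = x$deviations, dropped_levels = x$dropped_levels,
       range_reduced = x$range_reduced, n_dropped_zero = x$n_dropped_zero)
}

#' @export
report_data.opa_report <- function(x) {
  list(nucleotides_assessed = x$nucleotides_assessed,
       positive_agreement = x$positive_agreement,
       negative_agreement = x$negative_agreement,
       opa = x$opa, disagreement_rate = x$disagreement_rate,
       phred = x$phred, ci = as.list(x$ci))
}

#' Write validation reports to a directory
#'
#' Writes one JSON machine report per named result, a combined
#' `summary_limits.tsv` (LoD / LoQ / LoB with CIs) and, when a
#' variance-component table is present, `precision_cv.tsv` with abundance
#' columns in ascending order. Re-serialisation is idempotent. Missing
#' results are marked explicitly in the summary.
#'
#' @param results named list of fit objects (`lod`, `loq`, `lob`,
#'   `precision`, `linearity`, `bias`, `opa` — any subset).
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (nm in names(results)) {
    p <- file.path(dir, paste0(nm, ".json"))
    jsonlite::write_json(report_data(results[[nm]]), p, auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    written <- c(written, p)
  }
  fmt <- function(v) if (is.null(v) || length(v) == 0 || is.na(v)) "no data"
                     else format(v, digits = 6)
  lod <- results$lod; sad <- results$loq; lob <- results$lob
  lim <- data.frame(
    quantity = c("LoD (cells)", "LoD 95% CI lower", "LoD 95% CI upper",
                 "LoQ (cells)", "LoB"),
    value = c(fmt(lod$lod), fmt(lod$ci[["lower"]]), fmt(lod$ci[["upper"]]),
              fmt(if (!is.null(sad)) attr(sad, "loq") %||% results$loq_value),
              fmt(lob$value)),
    stringsAsFactors = FALSE)
  p <- file.path(dir, "summary_limits.tsv")
  utils::write.table(lim, p, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, p)
  if (!is.null(results$precision)) {
    tab <- as.data.frame(results$precision)
    tab <- tab[order(tab$expected_cells), ]
    p <- file.path(dir, "precision_cv.tsv")
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
  }
  invisible(written)
}
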