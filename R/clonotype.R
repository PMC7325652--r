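#' Trackability criteria
#'
#' The five conditions a candidate clonotype must satisfy before it is
#' accepted for MRD tracking: it must comprise at least `min_locus_share` of
#' all sequences at its locus and at least `min_cell_fraction` of all
#' nucleated cells; be well separated from the background repertoire (no more
#' than `max_near_neighbors` other less-abundant same-locus sequences with
#' frequencies within a factor of `neighbor_ratio`); be supported by at least
#' `min_templates` gDNA templates; and be sufficiently unique
#' (`uniqueness_score >= min_uniqueness`).
#'
#' @param min_locus_share minimum share of same-locus sequences (default 3%).
#' @param min_cell_fraction minimum fraction of all nucleated cells (0.2%).
#' @param max_near_neighbors maximum tolerated near neighbors (5).
#' @param neighbor_ratio frequency ratio defining "near" (10).
#' @param min_templates minimum supporting gDNA templates (40).
#' @param min_uniqueness minimum uniqueness score (see [uniqueness_score()]).
#' @return an object of class `trackability_criteria`.
#' @export
trackability_criteria <- function(min_locus_share = 0.03,
                                  min_cell_fraction = 0.002,
                                  max_near_neighbors = 5,
                                  neighbor_ratio = 10,
                                  min_templates = 40,
                                  min_uniqueness = 3) {
  if (min_locus_share <= 0 || min_cell_fraction <= 0 || min_templates <= 0 ||
      min_uniqueness <= 0)
    stop_invalid("all thresholds must be positive")
  if (neighbor_ratio <= 1) stop_invalid("neighbor_ratio must exceed 1")
  structure(list(min_locus_share = min_locus_share,
                 min_cell_fraction = min_cell_fraction,
                 max_near_neighbors = max_near_neighbors,
                 neighbor_ratio = neighbor_ratio,
                 min_templates = min_templates,
                 min_uniqueness = min_uniqueness),
            class = "trackability_criteria")
}

#' Uniqueness database of previously observed Ig rearrangements
#'
#' A map from sequence to the number of unrelated repertoires it has been
#' observed in, out of `total_repertoires`. Sequences absent from the map have
#' incidence 0.
#'
#' @param incidence named integer vector (names are sequences).
#' @param total_repertoires number of repertoires the database summarises.
#' @return an object of class `uniqueness_db`.
#' @export
uniqueness_db <- function(incidence = integer(), total_repertoires = 1e6) {
  if (total_repertoires < 1) stop_invalid("total_repertoires must be >= 1")
  if (any(incidence < 0)) stop_invalid("incidences must be >= 0")
  structure(list(incidence = incidence,
                 total_repertoires = total_repertoires),
            class = "uniqueness_db")
}

#' Build a uniqueness database around simulated clones
#'
#' Plants each clone's sequences at the incidence implied by its uniqueness
#' tier (`unique` = absent, `intermediate` ~ 1 in 10^4 repertoires, `common` ~
#' 1 in 100), optionally alongside background repertoire sequences at low
#' incidence.
#'
#' @param clones list of [gen_malignant_clone()] objects (or a single one).
#' @param total_repertoires database size.
#' @param background optional [gen_healthy_repertoire()]; its sequences are
#'   entered with incidence 1.
#' @return a [uniqueness_db()].
#' @export
build_uniqueness_db <- function(clones, total_repertoires = 1e6,
                                background = NULL) {
  if (inherits(clones, "malignant_clone")) clones <- list(clones)
  inc <- integer()
  for (cl in clones) {
    inc[cl$sequences$sequence] <- cl$db_incidence
  }
  if (!is.null(background)) {
    bg <- setdiff(background$clones$sequence, names(inc))
    inc[bg] <- 1L
  }
  uniqueness_db(inc, total_repertoires)
}

#' Uniqueness score of a clonotype sequence
#'
#' An add-one smoothed negative log incidence rate:
#' `-log10((incidence + 1) / (total_repertoires + 1))`. A sequence never seen
#' in a database of 10^6 repertoires scores 6; a sequence seen in every
#' repertoire scores 0. Higher is more unique.
#'
#' @param sequence character vector of sequences.
#' @param db a [uniqueness_db()].
#' @return numeric score(s).
#' @export
uniqueness_score <- function(sequence, db) {
  inc <- unname(db$incidence[sequence])
  inc[is.na(inc)] <- 0L
  -log10((inc + 1) / (db$total_repertoires + 1))
}

#' Allowed Hamming mismatches for a tracked sequence
#'
#' Tracking tolerates somatic hypermutation: more unique (higher-complexity)
#' sequences are allowed more mismatched nucleotides, because a mutated match
#' is still unlikely to be a coincidental healthy clone. The budget is tiered
#' on the uniqueness score: below the first threshold no mismatches are
#' allowed; above it, `N = min(cap, floor(length * fraction))` with the
#' fraction rising tier by tier.
#'
#' @param sequence the tracked sequence (its length scales the budget).
#' @param score uniqueness score from [uniqueness_score()].
#' @param tiers score thresholds (ascending) opening each tier.
#' @param fractions mismatch fraction of sequence length per tier.
#' @param cap hard cap on N.
#' @return integer mismatch budget N.
#' @export
allowed_mutations <- function(sequence, score,
                              tiers = c(2, 3.5, 5),
                              fractions = c(1 / 45, 2 / 45, 1 / 15),
                              cap = 3L) {
  if (!nzchar(sequence)) stop_invalid("sequence must be non-empty")
  stopifnot(length(tiers) == length(fractions))
  tier <- findInterval(score, tiers)
  if (tier == 0) return(0L)
  as.integer(min(cap, floor(nchar(sequence) * fractions[tier])))
}

#' Call candidate clonotypes in an identification sample
#'
#' Collapses the sample's template table (tracked spike-ins plus background
#' repertoire, or read records when only those are present) into one candidate
#' per distinct sequence, with its share of same-locus templates and its
#' fraction of total nucleated cells.
#'
#' @param id_sample a `contrived_sample`.
#' @param const [assay_constants()].
#' @return a data frame of class `candidate_clonotypes`: one row per distinct
#'   sequence with `sequence`, `locus`, `templates`, `locus_share`,
#'   `cell_fraction`.
#' @export
call_candidates <- function(id_sample, const = assay_constants()) {
  tabs <- list()
  if (!is.null(id_sample$tracked) && nrow(id_sample$tracked) > 0) {
    t0 <- id_sample$tracked
    tabs[[1]] <- t0[t0$templates > 0, c("sequence", "locus", "templates")]
  }
  if (!is.null(id_sample$background) && nrow(id_sample$background) > 0) {
    tabs[[length(tabs) + 1L]] <-
      id_sample$background[, c("sequence", "locus", "templates")]
  }
  if (length(tabs) == 0 && !is.null(id_sample$reads)) {
    r <- id_sample$reads
    tabs[[1]] <- data.frame(sequence = r$sequence, locus = r$locus,
                            templates = r$abundance, stringsAsFactors = FALSE)
  }
  if (length(tabs) == 0) {
    return(structure(data.frame(sequence = character(), locus = character(),
                                templates = integer(), locus_share = numeric(),
                                cell_fraction = numeric()),
                     class = c("candidate_clonotypes", "data.frame")))
  }
  tab <- do.call(rbind, tabs)
  agg <- stats::aggregate(templates ~ sequence + locus, data = tab, FUN = sum)
  locus_tot <- tapply(agg$templates, agg$locus, sum)
  cells <- total_nucleated_cells(id_sample, const = const)
  agg$locus_share <- agg$templates / as.numeric(locus_tot[agg$locus])
  agg$cell_fraction <- agg$templates / cells
  agg <- agg[order(-agg$templates), ]
  rownames(agg) <- NULL
  structure(agg, class = c("candidate_clonotypes", "data.frame"))
}

#' Select trackable clonotypes from candidates
#'
#' Applies the five trackability criteria (see [trackability_criteria()]) to
#' each candidate and assembles a tracking profile from those that pass all
#' of them. Ties in the separation comparison are broken toward rejection
#' (a neighbor at exactly `1/neighbor_ratio` of the candidate's frequency
#' counts as near). An empty profile is a legitimate outcome.
#'
#' @param candidates a `candidate_clonotypes` data frame.
#' @param criteria [trackability_criteria()].
#' @param db [uniqueness_db()].
#' @param patient_id identifier stored on the profile.
#' @return an object of class `tracking_profile` with elements `tracked`
#'   (data frame: `sequence`, `locus`, `allowed_mutations`,
#'   `uniqueness_score`) and `audit` (per-candidate criterion flags and the
#'   named criteria that failed).
#' @export
select_trackable <- function(candidates, criteria = trackability_criteria(),
                             db, patient_id = "patient1") {
  n <- nrow(candidates)
  score <- if (n) uniqueness_score(candidates$sequence, db) else numeric()
  pass_share <- candidates$locus_share >= criteria$min_locus_share
  pass_cells <- candidates$cell_fraction >= criteria$min_cell_fraction
  pass_templates <- candidates$templates >= criteria$min_templates
  pass_unique <- score >= criteria$min_uniqueness
  pass_separation <- logical(n)
  for (i in seq_len(n)) {
    same <- candidates$locus == candidates$locus[i]
    near <- same &
      candidates$locus_share < candidates$locus_share[i] &
      candidates$locus_share >= candidates$locus_share[i] / criteria$neighbor_ratio
    pass_separation[i] <- sum(near) <= criteria$max_near_neighbors
  }
  flags <- data.frame(locus_share = pass_share, cell_fraction = pass_cells,
                      separation = pass_separation, templates = pass_templates,
                      uniqueness = pass_unique)
  failed <- apply(flags, 1, function(f) paste(names(flags)[!f], collapse = ","))
  audit <- cbind(candidates, uniqueness_score = score, flags,
                 failed_criteria = failed, stringsAsFactors = FALSE)
  ok <- which(rowSums(flags) == ncol(flags))
  tracked <- data.frame(sequence = candidates$sequence[ok],
                        locus = candidates$locus[ok],
                        uniqueness_score = score[ok],
                        stringsAsFactors = FALSE)
  tracked$allowed_mutations <- vapply(seq_len(nrow(tracked)), function(i) {
    allowed_mutations(tracked$sequence[i], tracked$uniqueness_score[i])
  }, integer(1))
  structure(list(patient_id = patient_id, tracked = tracked, audit = audit),
            class = "tracking_profile")
}

#' Construct a tracking profile directly from a malignant clone
#'
#' Convenience constructor used when the identification stage is bypassed
#' (e.g. pure tracking simulations): every clone sequence is tracked with the
#' given mismatch budget.
#'
#' @param clone a [gen_malignant_clone()] object.
#' @param allowed_mutations mismatch budget N applied to every sequence.
#' @param uniqueness_score score recorded on every sequence.
#' @return a `tracking_profile`.
#' @export
tracking_profile <- function(clone, allowed_mutations = 0L,
                             uniqueness_score = 6) {
  tracked <- data.frame(sequence = clone$sequences$sequence,
                        locus = clone$sequences$locus,
                        uniqueness_score = uniqueness_score,
                        allowed_mutations = as.integer(allowed_mutations),
                        stringsAsFactors = FALSE)
  structure(list(patient_id = clone$patient_id, tracked = tracked,
                 audit = NULL),
            class = "tracking_profile")
}

#' @export
print.tracking_profile <- function(x, ...) {
  cat(sprintf("Tracking profile for %s: %d tracked sequence(s)\n",
              x$patient_id, nrow(x$tracked)))
  if (nrow(x$tracked)) {
    print(x$tracked[, c("locus", "uniqueness_score", "allowed_mutations")])
  }
  if (!is.null(x$audit)) {
    rej <- x$audit[x$audit$failed_criteria != "", ]
    if (nrow(rej))
      cat(sprintf("  %d candidate(s) rejected (criteria: %s)\n", nrow(rej),
                  paste(unique(rej$failed_criteria), collapse = "; ")))
  }
  invisible(x)
}
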