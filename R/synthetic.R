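#' Sequencing / assay noise model
#'
#' @param per_base_error_rate probability that any given nucleotide of a read
#'   is mis-called (substitutions only).
#' @param extra_cv multiplicative lognormal assay noise applied to template
#'   counts, expressed as a coefficient of variation. 0 disables it, leaving
#'   pure Poisson sampling.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(per_base_error_rate = 0, extra_cv = 0) {
  if (per_base_error_rate < 0 || per_base_error_rate >= 1)
    stop_invalid("per_base_error_rate must lie in [0, 1)")
  if (extra_cv < 0) stop_invalid("extra_cv must be >= 0")
  structure(list(per_base_error_rate = per_base_error_rate,
                 extra_cv = extra_cv),
            class = "noise_model")
}

#' Generate a healthy polyclonal B-cell repertoire
#'
#' Clone frequencies follow a power law in rank (`f_r` proportional to
#' `r^-power_exponent`, normalised to sum to 1); sequences are i.i.d. random
#' nucleotide strings and loci are assigned at random with the given weights.
#' The defaults (2000 clones, exponent 0.5) give a top clone near 1% of the
#' repertoire, typical of a polyclonal marrow with no dominant expansion.
#'
#' @param n_clones number of clones.
#' @param locus_weights named non-negative weights over the five tracked loci,
#'   summing to 1.
#' @param seed integer seed; the same seed reproduces the repertoire exactly.
#' @param power_exponent rank-frequency power-law exponent.
#' @param seq_length nucleotide length of the CDR3-like sequences.
#' @param donor_id identifier stored with the repertoire.
#' @return an object of class `healthy_repertoire`: a list with a `clones`
#'   data frame (`locus`, `sequence`, `frequency`) and `donor_id`.
#' @export
gen_healthy_repertoire <- function(n_clones,
                                   locus_weights = c("IGH" = 0.45,
                                                     "IGK" = 0.30,
                                                     "IGL" = 0.15,
                                                     "BCL1-IGH" = 0.05,
                                                     "BCL2-IGH" = 0.05),
                                   seed = 1L,
                                   power_exponent = 0.5,
                                   seq_length = 45,
                                   donor_id = "donor1") {
  if (n_clones < 1) stop_invalid("n_clones must be >= 1")
  if (any(locus_weights < 0) || sum(locus_weights) <= 0)
    stop_invalid("locus_weights must be non-negative with positive sum")
  locus_weights <- locus_weights / sum(locus_weights)
  set.seed(derive_seed(seed, "repertoire", donor_id))
  freq <- (seq_len(n_clones))^(-power_exponent)
  freq <- freq / sum(freq)
  clones <- data.frame(
    locus = sample(names(locus_weights), n_clones, replace = TRUE,
                   prob = locus_weights),
    sequence = random_sequences(n_clones, seq_length),
    frequency = freq,
    stringsAsFactors = FALSE
  )
  structure(list(clones = clones, donor_id = donor_id),
            class = "healthy_repertoire")
}

#' Generate a malignant clone with 1-5 trackable rearrangements
#'
#' Each rearrangement is carried at one genomic copy per malignant cell. The
#' uniqueness tier sets the incidence the clone's sequences will be given when
#' a uniqueness database is built around them ([build_uniqueness_db()]):
#' `unique` sequences are absent from the database, `intermediate` ones occur
#' at roughly 1 in 10^4 repertoires, and `common` ones at 1 in 100 — common
#' sequences score below the default tracking cutoff and are rejected.
#'
#' @param k_sequences number of trackable rearrangements (1-5).
#' @param uniqueness_tier one of `"unique"`, `"intermediate"`, `"common"`.
#' @param seed integer seed.
#' @param seq_length nucleotide length of each rearrangement.
#' @param patient_id identifier.
#' @return an object of class `malignant_clone`.
#' @export
gen_malignant_clone <- function(k_sequences,
                                uniqueness_tier = c("unique", "intermediate",
                                                    "common"),
                                seed = 1L,
                                seq_length = 45,
                                patient_id = "patient1") {
  if (k_sequences < 1 || k_sequences > 5)
    stop_invalid("k_sequences must be between 1 and 5")
  uniqueness_tier <- match.arg(uniqueness_tier)
  set.seed(derive_seed(seed, "clone", patient_id))
  loci <- c("IGH", "IGK", "IGL", "BCL1-IGH", "BCL2-IGH")[seq_len(k_sequences)]
  repeat {
    seqs <- random_sequences(k_sequences, seq_length)
    if (!anyDuplicated(seqs)) break
  }
  db_incidence <- switch(uniqueness_tier,
                         unique = 0L, intermediate = 99L, common = 9999L)
  structure(list(patient_id = patient_id,
                 sequences = data.frame(locus = loci, sequence = seqs,
                                        copies_per_cell = 1L,
                                        stringsAsFactors = FALSE),
                 uniqueness_tier = uniqueness_tier,
                 db_incidence = db_incidence),
            class = "malignant_clone")
}

# Reads for one tracked sequence: n templates, substitution errors injected at
# per-base rate e. Error-free templates collapse into a single record; each
# mutated template is materialised individually (cheap: expected count ~ n*L*e).
sequence_reads <- function(seq, locus, n, e) {
  if (n == 0) return(NULL)
  L <- nchar(seq)
  if (e == 0) {
    return(data.frame(sequence = seq, locus = locus, abundance = n,
                      stringsAsFactors = FALSE))
  }
  p_mut <- 1 - (1 - e)^L
  m <- stats::rbinom(1, n, p_mut)
  out <- if (n - m > 0) {
    data.frame(sequence = seq, locus = locus, abundance = n - m,
               stringsAsFactors = FALSE)
  }
  if (m > 0) {
    # number of errors per mutated template ~ Binomial(L, e) conditioned >= 1
    kprob <- stats::dbinom(seq_len(L), L, e)
    ks <- sample.int(L, m, replace = TRUE, prob = kprob)
    mut <- vapply(ks, function(k) mutate_sequence(seq, k), character(1))
    tab <- table(mut)
    out <- rbind(out, data.frame(sequence = names(tab), locus = locus,
                                 abundance = as.integer(tab),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Contrive an MRD dilution sample
#'
#' Emulates spiking malignant gDNA into a healthy diluent at a prescribed DNA
#' mass and expected malignant-cell number. Each tracked rearrangement's
#' template count is drawn independently as Poisson(`expected_cells`) (one
#' genome copy per rearrangement per cell), then perturbed by multiplicative
#' lognormal noise with CV `noise$extra_cv` and re-rounded. Reference
#' (diploid-region) templates are `2 * round(dna_mass_pg / pg_per_cell)`
#' before noise. When the noise model carries a per-base error rate (or
#' `with_reads = TRUE`), read records with injected substitutions are
#' attached.
#'
#' RNG streams are derived per (sample, sequence), so generating a subset of a
#' study leaves the remaining samples' draws unchanged.
#'
#' @param clone a [gen_malignant_clone()] object.
#' @param background optional [gen_healthy_repertoire()]; when supplied, the
#'   non-malignant cell equivalents are distributed over its clones
#'   (independent Poisson per clone) so that identification-stage candidate
#'   calling sees a realistic background.
#' @param dna_mass_pg total DNA mass of the sample in picograms.
#' @param expected_cells ground-truth expected number of malignant cells.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param sample_id identifier; defaults to a deterministic name.
#' @param const [assay_constants()].
#' @param with_reads force generation of read records.
#' @return an object of class `contrived_sample`.
#' @export
contrive_sample <- function(clone, background = NULL, dna_mass_pg,
                            expected_cells, noise = noise_model(),
                            seed = 1L, sample_id = NULL,
                            const = assay_constants(),
                            with_reads = noise$per_base_error_rate > 0) {
  if (expected_cells < 0) stop_invalid("expected_cells must be >= 0")
  if (dna_mass_pg <= 0) stop_invalid("dna_mass_pg must be > 0")
  sample_id <- sample_id %||%
    sprintf("%s_m%g_c%g", clone$patient_id, dna_mass_pg, expected_cells)

  seqs <- clone$sequences
  templates <- integer(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    set.seed(derive_seed(seed, sample_id, seqs$sequence[i]))
    n <- stats::rpois(1, expected_cells)
    if (noise$extra_cv > 0) n <- max(0L, round(n * rlnorm_cv(1, noise$extra_cv)))
    templates[i] <- n
  }
  tracked <- data.frame(sequence = seqs$sequence, locus = seqs$locus,
                        templates = templates, stringsAsFactors = FALSE)

  ref <- 2 * round(dna_mass_pg / const$pg_per_diploid_cell)
  if (noise$extra_cv > 0) {
    set.seed(derive_seed(seed, sample_id, "reference"))
    ref <- max(0, round(ref * rlnorm_cv(1, noise$extra_cv)))
  }

  bg <- NULL
  if (!is.null(background)) {
    set.seed(derive_seed(seed, sample_id, "background"))
    bg_cells <- max(0, dna_mass_pg / const$pg_per_diploid_cell - expected_cells)
    counts <- stats::rpois(nrow(background$clones),
                           background$clones$frequency * bg_cells)
    keep <- counts > 0
    bg <- data.frame(sequence = background$clones$sequence[keep],
                     locus = background$clones$locus[keep],
                     templates = counts[keep], stringsAsFactors = FALSE)
  }

  reads <- NULL
  if (with_reads) {
    set.seed(derive_seed(seed, sample_id, "reads"))
    parts <- lapply(seq_len(nrow(tracked)), function(i) {
      sequence_reads(tracked$sequence[i], tracked$locus[i],
                     tracked$templates[i], noise$per_base_error_rate)
    })
    if (!is.null(bg) && nrow(bg) > 0) {
      parts <- c(parts, list(data.frame(sequence = bg$sequence,
                                        locus = bg$locus,
                                        abundance = bg$templates,
                                        stringsAsFactors = FALSE)))
    }
    parts <- parts[!vapply(parts, is.null, logical(1))]
    reads <- if (length(parts)) do.call(rbind, parts)
  }

  structure(list(sample_id = sample_id,
                 patient_id = clone$patient_id,
                 dna_mass_pg = dna_mass_pg,
                 expected_malignant_cells = expected_cells,
                 tracked = tracked,
                 reference_templates = ref,
                 background = bg,
                 reads = reads),
            class = "contrived_sample")
}

#' @export
print.contrived_sample <- function(x, ...) {
  cat(sprintf("Contrived sample '%s': %.3g pg DNA, %.4g expected malignant cells\n",
              x$sample_id, x$dna_mass_pg, x$expected_malignant_cells))
  cat(sprintf("  tracked sequences: %d (templates: %s)\n",
              nrow(x$tracked), paste(x$tracked$templates, collapse = ", ")))
  cat(sprintf("  reference templates: %d; background clones: %d; reads: %s\n",
              x$reference_templates,
              if (is.null(x$background)) 0L else nrow(x$background),
              if (is.null(x$reads)) "none" else nrow(x$reads)))
  invisible(x)
}

#' Generate a factorial precision-study grid
#'
#' Emulates a main-effects screening design over operator sets, instrument
#' sets, reagent lots, days, and runs within day. Each replicate measurement
#' is a Poisson draw at its expected cell input multiplied by lognormal level
#' effects drawn once per factor level (shared across all strata), then
#' rounded. Factor levels are assigned by randomly permuting balanced level
#' vectors within each abundance x DNA-input cell, so every level of every
#' factor appears at every abundance.
#'
#' @param abundances expected malignant-cell inputs (the default set spans the
#'   study's dilution levels).
#' @param dna_inputs total DNA masses (pg).
#' @param factor_cvs named CVs of the multiplicative level effects for
#'   `operator_set`, `instrument_set`, `reagent_lot`, `day`, `run_within_day`.
#'   Missing names default to 0.
#' @param n_replicates replicates per abundance x DNA-input cell (>= 21 so
#'   every day level is represented).
#' @param seed integer seed.
#' @return a `validation_grid`: a data frame with factor columns and a
#'   `measurement` column, plus attributes recording the injected effects.
#' @export
gen_validation_grid <- function(abundances = c(2.14, 6.13, 21.44, 61.26,
                                               214.46, 612.56),
                                dna_inputs = c(5e5, 2e6, 2e7),
                                factor_cvs = c(),
                                n_replicates = 42,
                                seed = 1L) {
  if (length(abundances) == 0) stop_invalid("abundances must be non-empty")
  if (any(unlist(factor_cvs) < 0)) stop_invalid("factor CVs must be >= 0")
  n_levels <- c(operator_set = 3L, instrument_set = 2L, reagent_lot = 4L,
                day = 21L, run_within_day = 10L)
  if (n_replicates < max(n_levels))
    stop_invalid("n_replicates must cover every factor level (>= 21)")
  cvs <- stats::setNames(rep(0, length(n_levels)), names(n_levels))
  if (length(factor_cvs)) {
    unknown <- setdiff(names(factor_cvs), names(n_levels))
    if (length(unknown))
      stop_invalid("unknown factor(s): ", paste(unknown, collapse = ", "))
    cvs[names(factor_cvs)] <- unlist(factor_cvs)
  }

  set.seed(derive_seed(seed, "grid", "effects"))
  effects <- lapply(names(n_levels), function(f) rlnorm_cv(n_levels[[f]], cvs[[f]]))
  names(effects) <- names(n_levels)

  rows <- list()
  for (a in abundances) {
    for (d in dna_inputs) {
      set.seed(derive_seed(seed, "grid", a, d))
      lev <- lapply(names(n_levels), function(f) {
        sample(rep_len(seq_len(n_levels[[f]]), n_replicates))
      })
      names(lev) <- names(n_levels)
      lambda <- stats::rpois(n_replicates, a)
      eff <- Reduce(`*`, lapply(names(n_levels),
                                function(f) effects[[f]][lev[[f]]]))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("grid_a%g_d%g_r%d", a, d, seq_len(n_replicates)),
        expected_cells = a, dna_input_pg = d,
        operator_set = factor(lev$operator_set, levels = 1:3),
        instrument_set = factor(lev$instrument_set, levels = 1:2),
        reagent_lot = factor(lev$reagent_lot, levels = 1:4),
        day = factor(lev$day, levels = 1:21),
        run_within_day = factor(lev$run_within_day, levels = 1:10),
        replicate = seq_len(n_replicates),
        measurement = round(lambda * eff),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "factor_cvs") <- cvs
  attr(out, "effects") <- effects
  class(out) <- c("validation_grid", "data.frame")
  out
}

#' Generate a blank (healthy-only) panel for limit-of-blank studies
#'
#' Blanks carry no malignant templates. With probability `collision_rate` per
#' tracked sequence per blank, a coincidentally matching healthy clone is
#' planted at a small template count (1 + Poisson(0.5)), modelling
#' intermediate-uniqueness sequence collisions.
#'
#' @param n_donors number of healthy donors.
#' @param dna_masses DNA input masses (pg), one panel per mass per donor.
#' @param profile a [tracking_profile] whose sequences are searched for.
#' @param collision_rate per-sequence collision probability in \[0, 1\].
#' @param seed integer seed.
#' @param n_replicates replicates per donor x mass.
#' @param const [assay_constants()].
#' @return a list of `contrived_sample` blanks
#'   (`expected_malignant_cells = 0`).
#' @export
gen_blank_panel <- function(n_donors = 7, dna_masses = c(5e5, 2e7, 4e7),
                            profile, collision_rate = 0, seed = 1L,
                            n_replicates = 1, const = assay_constants()) {
  if (collision_rate < 0 || collision_rate > 1)
    stop_invalid("collision_rate must lie in [0, 1]")
  seqs <- profile$tracked
  out <- list()
  for (d in seq_len(n_donors)) {
    for (m in dna_masses) {
      for (r in seq_len(n_replicates)) {
        sid <- sprintf("blank_d%d_m%g_r%d", d, m, r)
        set.seed(derive_seed(seed, sid))
        hits <- stats::runif(nrow(seqs)) < collision_rate
        counts <- ifelse(hits, 1L + stats::rpois(nrow(seqs), 0.5), 0L)
        out[[length(out) + 1L]] <- structure(list(
          sample_id = sid, patient_id = profile$patient_id,
          dna_mass_pg = m, expected_malignant_cells = 0,
          tracked = data.frame(sequence = seqs$sequence, locus = seqs$locus,
                               templates = as.integer(counts),
                               stringsAsFactors = FALSE),
          reference_templates = 2 * round(m / const$pg_per_diploid_cell),
          background = NULL, reads = NULL), class = "contrived_sample")
      }
    }
  }
  out
}
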