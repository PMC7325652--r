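#' Study configuration
#'
#' Bundles the master seed, assay constants, trackability criteria, noise
#' model, study sizes, and per-procedure toggles consumed by
#' [run_pipeline()]. Unknown toggle or size names are rejected. The
#' configuration round-trips losslessly through JSON
#' ([write_config()] / [read_config()]).
#'
#' @param seed master integer seed.
#' @param const [assay_constants()].
#' @param criteria [trackability_criteria()].
#' @param noise [noise_model()].
#' @param run named logical toggles for the six validation procedures
#'   (`lod`, `loq`, `lob`, `precision`, `linearity`, `bias`, `opa`).
#' @param sizes named study sizes: `lod_n_per_dose`, `lod_doses`,
#'   `grid_replicates`, `bias_n_boot`, `bias_strata`, `bias_samples`,
#'   `bias_replicates`, `linearity_levels`, `linearity_replicates`,
#'   `blank_donors`, `opa_templates`, `k_sequences`, `id_disease_load`.
#' @return an object of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         const = assay_constants(),
                         criteria = trackability_criteria(),
                         noise = noise_model(),
                         run = list(),
                         sizes = list()) {
  run_default <- list(lod = TRUE, loq = TRUE, lob = TRUE, precision = TRUE,
                      linearity = TRUE, bias = TRUE, opa = TRUE)
  unknown <- setdiff(names(run), names(run_default))
  if (length(unknown))
    stop_invalid("unknown toggle(s): ", paste(unknown, collapse = ", "))
  run_default[names(run)] <- run
  sizes_default <- list(
    lod_n_per_dose = 150L,
    lod_doses = c(0.5, 0.75, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5),
    grid_replicates = 42L,
    bias_n_boot = 2000L,
    bias_strata = c(10, 30, 100, 300),
    bias_samples = 20L,
    bias_replicates = 2L,
    linearity_levels = c(2, 2.5, 3, 9.2, 30.6, 91.9, 306.3, 918.8,
                         3062.8, 9188.4, 30627.9),
    linearity_replicates = 8L,
    blank_donors = 7L,
    opa_templates = 200000L,
    opa_error_rate = 3.5e-5,
    k_sequences = 2L,
    id_disease_load = 0.10)
  unknown <- setdiff(names(sizes), names(sizes_default))
  if (length(unknown))
    stop_invalid("unknown size(s): ", paste(unknown, collapse = ", "))
  sizes_default[names(sizes)] <- sizes
  structure(list(seed = as.integer(seed), const = const, criteria = criteria,
                 noise = noise, run = run_default, sizes = sizes_default),
            class = "study_config")
}

#' Write / read a study configuration as JSON
#'
#' @param config a [study_config()].
#' @param path JSON path.
#' @return `write_config` the path invisibly; `read_config` a `study_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(list(seed = config$seed,
                            const = unclass(config$const),
                            criteria = unclass(config$criteria),
                            noise = unclass(config$noise),
                            run = config$run,
                            sizes = config$sizes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  study_config(seed = x$seed,
               const = do.call(assay_constants, as.list(x$const)),
               criteria = do.call(trackability_criteria, as.list(x$criteria)),
               noise = do.call(noise_model, as.list(x$noise)),
               run = as.list(x$run),
               sizes = as.list(x$sizes))
}

log_event <- function(log, stage, event, detail = "") {
  rbind(log, data.frame(time = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
                        stage = stage, event = event, detail = detail,
                        stringsAsFactors = FALSE))
}

#' Run the full simulate - identify - track - validate pipeline
#'
#' Generates a synthetic study under the configuration's seed, identifies a
#' tracking profile from a high-burden ID sample, tracks the profile across
#' contrived dilution samples, and runs whichever of the six validation
#' procedures are toggled on. The same configuration and seed reproduce all
#' outputs exactly.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; reports are written there with
#'   [write_reports()].
#' @return a list with `results` (named fit objects), `profile`, `log`
#'   (a data frame of stage events), and `files` (paths written, if any).
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL) {
  seed <- config$seed
  sz <- config$sizes
  const <- config$const
  log <- data.frame(time = character(), stage = character(),
                    event = character(), detail = character(),
                    stringsAsFactors = FALSE)
  results <- list()
  stage <- function(name, expr) {
    log <<- log_event(log, name, "start")
    val <- tryCatch(expr, error = function(e) {
      log <<- log_event(log, name, "error", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log <<- log_event(log, name, "end")
    val
  }

  # -- simulate + identify ---------------------------------------------------
  repertoire <- stage("simulate", {
    gen_healthy_repertoire(n_clones = 2000, seed = seed)
  })
  clone <- gen_malignant_clone(sz$k_sequences, "unique", seed = seed)
  db <- build_uniqueness_db(clone, background = repertoire)

  profile <- stage("identify", {
    id_cells <- cells_from_mass(5e5, const, round = FALSE)
    id_sample <- contrive_sample(clone, repertoire, dna_mass_pg = 5e5,
                                 expected_cells = sz$id_disease_load * id_cells,
                                 seed = derive_seed(seed, "id"),
                                 sample_id = "id_sample", const = const)
    candidates <- call_candidates(id_sample, const)
    prof <- select_trackable(candidates, config$criteria, db,
                             patient_id = clone$patient_id)
    log <- log_event(log, "identify", "counts",
                     sprintf("%d candidates, %d tracked", nrow(candidates),
                             nrow(prof$tracked)))
    if (nrow(prof$tracked) == 0) stop("no trackable clonotype identified")
    prof
  })

  # -- track: dilution series used by LoD/LoQ --------------------------------
  dilution <- NULL
  if (config$run$lod || config$run$loq) {
    dilution <- stage("track", {
      simulate_dilution_series(clone, profile, doses = sz$lod_doses,
                               n_per_dose = sz$lod_n_per_dose,
                               noise = config$noise,
                               seed = derive_seed(seed, "lod"), const = const)
    })
  }

  if (config$run$lod) {
    results$lod <- stage("validate-lod", {
      fit_probit(dilution$dose, dilution$detected,
                 target = const$detection_target, n_boot = 500,
                 seed = derive_seed(seed, "lodci"))
    })
  }
  if (config$run$loq) {
    results$loq <- stage("validate-loq", {
      rte <- relative_total_error(dilution$consensus, dilution$dose)
      fit <- fit_sadler(rte$expected_cells, rte$rte)
      attr(fit, "loq") <- tryCatch(loq(fit, const$rte_threshold),
                                   error = function(e) NA_real_)
      attr(fit, "rte") <- rte
      fit
    })
  }
  if (config$run$lob) {
    results$lob <- stage("validate-lob", {
      blanks <- gen_blank_panel(sz$blank_donors, dna_masses = c(5e5, 2e7, 4e7),
                                profile = profile, collision_rate = 0,
                                seed = derive_seed(seed, "lob"), const = const)
      freqs <- unlist(lapply(blanks, function(b) {
        b$tracked$templates / total_nucleated_cells(b, const)
      }))
      masses <- rep(vapply(blanks, `[[`, numeric(1), "dna_mass_pg"),
                    each = nrow(profile$tracked))
      estimate_lob(freqs, alpha = const$lob_alpha, group = masses)
    })
  }
  if (config$run$precision) {
    results$precision <- stage("validate-precision", {
      grid <- gen_validation_grid(n_replicates = sz$grid_replicates,
                                  seed = derive_seed(seed, "grid"))
      variance_components(grid, method = "moments")
    })
  }
  if (config$run$linearity) {
    results$linearity <- stage("validate-linearity", {
      set.seed(derive_seed(seed, "linearity"))
      expected <- rep(sz$linearity_levels, each = sz$linearity_replicates)
      observed <- stats::rpois(length(expected), expected)
      assess_linearity(observed, expected)
    })
  }
  if (config$run$bias) {
    results$bias <- stage("validate-bias", {
      rows <- list()
      for (a in sz$bias_strata) {
        for (sm in seq_len(sz$bias_samples)) {
          set.seed(derive_seed(seed, "bias", a, sm))
          obs <- stats::rpois(sz$bias_replicates, a)
          rows[[length(rows) + 1L]] <- data.frame(
            stratum = sprintf("cells_%g", a),
            sample = sprintf("s%d", sm), observed = obs, expected = a,
            stringsAsFactors = FALSE)
        }
      }
      bootstrap_bias(do.call(rbind, rows), n_boot = sz$bias_n_boot,
                     seed = derive_seed(seed, "biasboot"))
    })
  }
  if (config$run$opa) {
    results$opa <- stage("validate-opa", {
      noisy <- noise_model(per_base_error_rate = sz$opa_error_rate)
      s <- contrive_sample(clone, dna_mass_pg = 2e7,
                           expected_cells = sz$opa_templates, noise = noisy,
                           seed = derive_seed(seed, "opa"),
                           sample_id = "opa_sample", const = const,
                           with_reads = TRUE)
      prof_n <- profile
      prof_n$tracked$allowed_mutations <- 3L
      compute_opa(match_tracked(s, prof_n))
    })
  }

  files <- NULL
  if (!is.null(out_dir)) {
    files <- write_reports(results, out_dir)
    log <- log_event(log, "report", "written", paste(length(files), "files"))
  }
  list(results = results, profile = profile, log = log, files = files)
}
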