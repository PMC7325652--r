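#' Simulate a tracked dilution series
#'
#' Contrives `n_per_dose` samples at each expected malignant-cell dose
#' ([contrive_sample()]), quantifies each against the profile
#' ([mrd_quantify()]), and returns one row per sample. This is the workhorse
#' behind limit-of-detection and limit-of-quantitation studies: detection
#' outcomes feed [fit_probit()], consensus cell counts feed
#' [relative_total_error()] and [fit_sadler()].
#'
#' @param clone a [gen_malignant_clone()] object.
#' @param profile tracking profile; defaults to tracking every clone sequence
#'   exactly (`N = 0`).
#' @param doses expected malignant-cell inputs.
#' @param n_per_dose samples per dose.
#' @param dna_mass_pg DNA mass of every sample (pg).
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param const [assay_constants()].
#' @return a data frame: `dose`, `replicate`, `detected`, `consensus`
#'   (consensus malignant cells), `mrd_frequency`.
#' @export
simulate_dilution_series <- function(clone, profile = tracking_profile(clone),
                                     doses, n_per_dose, dna_mass_pg = 2e7,
                                     noise = noise_model(), seed = 1L,
                                     const = assay_constants()) {
  if (n_per_dose < 1) stop_invalid("n_per_dose must be >= 1")
  n <- length(doses) * n_per_dose
  dose_col <- rep(doses, each = n_per_dose)
  rep_col <- rep(seq_len(n_per_dose), times = length(doses))
  detected <- logical(n)
  consensus <- numeric(n)
  freq <- numeric(n)
  for (i in seq_len(n)) {
    s <- contrive_sample(clone, dna_mass_pg = dna_mass_pg,
                         expected_cells = dose_col[i], noise = noise,
                         seed = seed,
                         sample_id = sprintf("dil_%g_%d", dose_col[i],
                                             rep_col[i]),
                         const = const)
    q <- mrd_quantify(s, profile, const)
    detected[i] <- q$detected
    consensus[i] <- q$consensus_malignant_cells
    freq[i] <- q$mrd_frequency
  }
  data.frame(dose = dose_col, replicate = rep_col, detected = detected,
             consensus = consensus, mrd_frequency = freq)
}
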