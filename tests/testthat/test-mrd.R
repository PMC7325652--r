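test_that("total nucleated cells come from reference amplicons, with mass fallback", {
  expect_equal(total_nucleated_cells(list(reference_templates = 10)), 5)
  expect_equal(total_nucleated_cells(list(reference_templates = NA,
                                          dna_mass_pg = 2e7)), 3062787)
  expect_equal(total_nucleated_cells(list(reference_templates = NULL,
                                          dna_mass_pg = 5e5)), 76570)
  expect_error(total_nucleated_cells(list()), class = "mrdseq_missing_data")
})

test_that("Hamming matching respects the per-sequence mismatch budget", {
  cl <- make_clone(k = 1, seed = 3)
  seq0 <- cl$sequences$sequence
  sample_with <- function(obs_seq) {
    structure(list(sample_id = "s", dna_mass_pg = 2e6,
                   expected_malignant_cells = 1,
                   tracked = NULL, reference_templates = 100,
                   background = NULL,
                   reads = data.frame(sequence = obs_seq, locus = "IGH",
                                      abundance = 7,
                                      stringsAsFactors = FALSE)),
              class = "contrived_sample")
  }
  flip <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in seq_len(k)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }

  prof0 <- tracking_profile(cl, allowed_mutations = 0L)
  rec <- match_tracked(sample_with(seq0), prof0)
  expect_equal(rec$mismatches, 0L)
  expect_equal(rec$abundance, 7)

  prof1 <- tracking_profile(cl, allowed_mutations = 1L)
  expect_equal(nrow(match_tracked(sample_with(flip(seq0, 1)), prof1)), 1)
  expect_equal(match_tracked(sample_with(flip(seq0, 1)), prof1)$mismatches, 1L)
  expect_equal(nrow(match_tracked(sample_with(flip(seq0, 2)), prof1)), 0)

  # a length mismatch is not an error, just no match
  expect_equal(nrow(match_tracked(sample_with(substr(seq0, 1, 20)), prof1)), 0)
  expect_error(match_tracked(sample_with(seq0),
                             structure(list(tracked = NULL),
                                       class = "tracking_profile")),
               class = "mrdseq_missing_data")
})

test_that("reads at per-base error 1e-3 match at >= 99.9% with N = 3", {
  cl <- make_clone(k = 1, seed = 2)
  prof <- tracking_profile(cl, allowed_mutations = 3L)
  s <- contrive_sample(cl, dna_mass_pg = 2e7, expected_cells = 20000,
                       noise = noise_model(per_base_error_rate = 1e-3),
                       seed = 8, with_reads = TRUE)
  rec <- match_tracked(s, prof)
  expect_gte(sum(rec$abundance) / s$tracked$templates, 0.999)
})

test_that("consensus malignant-cell counts average the per-sequence estimates", {
  expect_equal(consensus_malignant_cells(3), 3.0)
  expect_equal(consensus_malignant_cells(c(2, 4)), 3.0)
  expect_equal(consensus_malignant_cells(c(0, 0)), 0.0)
  expect_equal(consensus_malignant_cells(c(2, 4), method = "max"), 4)
  expect_error(consensus_malignant_cells(numeric()),
               class = "mrdseq_missing_data")
})

test_that("MRD frequency reproduces the worked dilution arithmetic", {
  # 2 cells in 20 ug of DNA: frequency 6.53e-7, printed as 0.000065%
  f <- mrd_frequency(2, cells_from_mass(2e7))
  expect_equal(f, 2 / 3062787, tolerance = 1e-12)
  expect_equal(sprintf("%.6f%%", 100 * f), "0.000065%")
  # 200 ng at 100% disease load
  expect_equal(mrd_frequency(30628, cells_from_mass(2e5)), 1, tolerance = 1e-4)
  expect_equal(mrd_frequency(0, 1000), 0)
  expect_error(mrd_frequency(1, 0), class = "mrdseq_invalid_parameter")
  # invariant to uniform scaling of both counts
  expect_equal(mrd_frequency(3, 1e5), mrd_frequency(300, 1e7))
})

test_that("OPA equals hand-computed agreement arithmetic and is rebucketing-invariant", {
  o <- compute_opa(toy_records())
  expect_equal(o$positive_agreement, 1995)
  expect_equal(o$negative_agreement, 5)
  expect_equal(o$opa, 99.75)

  clean <- data.frame(length = 45, mismatches = 0L, allowed = 3L,
                      abundance = 1000)
  expect_equal(compute_opa(clean)$opa, 100)

  # splitting a record into two abundance buckets changes nothing
  rec <- toy_records()
  split_rec <- rbind(rec, rec)
  split_rec$abundance <- split_rec$abundance / 2
  expect_equal(compute_opa(split_rec)$opa, o$opa)

  # records beyond the allowed budget are excluded
  over <- rbind(toy_records(),
                data.frame(length = 20, mismatches = 5L, allowed = 3L,
                           abundance = 50))
  expect_equal(compute_opa(over)$opa, o$opa)

  expect_error(compute_opa(clean[0, ]), class = "mrdseq_missing_data")
})

test_that("an injected per-base error rate is recovered as the disagreement rate", {
  cl <- make_clone(k = 1, seed = 2)
  prof <- tracking_profile(cl, allowed_mutations = 3L)
  e <- 3.5e-5
  s <- contrive_sample(cl, dna_mass_pg = 2e7, expected_cells = 250000,
                       noise = noise_model(per_base_error_rate = e),
                       seed = 7, with_reads = TRUE)
  o <- compute_opa(match_tracked(s, prof))
  expect_gte(o$nucleotides_assessed, 1e7)
  mc_se <- sqrt(e / o$nucleotides_assessed)
  expect_lt(abs(o$disagreement_rate - e), 3.5 * mc_se)
})

test_that("Phred restatement uses the -10 log10 convention", {
  expect_equal(round(phred_score(3.5e-5), 1), 44.6)
  expect_lt(abs(phred_score(3.5e-5) - 44.5), 0.15)
  expect_equal(round(phred_score(4.0e-5), 1), 44.0)
  expect_equal(phred_score(0.1), 10.0)
  expect_equal(phred_score(0), 60)
  expect_error(phred_score(1.5), class = "mrdseq_invalid_parameter")
  # monotone decreasing in the error rate
  rates <- 10^seq(-6, -1)
  expect_true(all(diff(phred_score(rates)) < 0))
})

test_that("end-to-end identity: no noise and N = 0 reproduce generated counts exactly", {
  cl <- make_clone(k = 3, seed = 19)
  prof <- tracking_profile(cl, allowed_mutations = 0L)
  s <- contrive_sample(cl, dna_mass_pg = 2e7, expected_cells = 50, seed = 19,
                       with_reads = TRUE)
  q <- mrd_quantify(s, prof)
  expect_equal(unname(q$per_sequence_cells[s$tracked$sequence]),
               as.numeric(s$tracked$templates))
  expect_equal(q$consensus_malignant_cells, mean(s$tracked$templates))
  expect_equal(compute_opa(q$records)$opa, 100)
  expect_true(q$detected)
})
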