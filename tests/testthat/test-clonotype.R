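test_that("uniqueness score follows the smoothed negative log incidence rate", {
  db <- uniqueness_db(total_repertoires = 1e6)
  expect_equal(uniqueness_score("AAA", db), -log10(1 / 1000001),
               tolerance = 1e-12)
  expect_equal(round(uniqueness_score("AAA", db), 3), 6.0)

  db2 <- uniqueness_db(c(AAA = 1e6), total_repertoires = 1e6)
  expect_equal(uniqueness_score("AAA", db2), 0, tolerance = 1e-12)

  # strictly decreasing in incidence
  scores <- vapply(c(0, 1, 10, 100, 1e4, 1e6), function(i) {
    uniqueness_score("S", uniqueness_db(c(S = i), 1e6))
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("allowed mutations are tiered on uniqueness and capped", {
  expect_equal(allowed_mutations(strrep("A", 45), score = 0), 0L)
  expect_equal(allowed_mutations(strrep("A", 45), score = 6), 3L)
  expect_equal(allowed_mutations(strrep("A", 45), score = 2.5), 1L)
  expect_equal(allowed_mutations(strrep("A", 45), score = 4), 2L)
  # never exceeds the cap, whatever the length
  for (len in c(30, 45, 60, 120)) {
    expect_lte(allowed_mutations(strrep("A", len), score = 10), 3L)
  }
  expect_error(allowed_mutations("", score = 6),
               class = "mrdseq_invalid_parameter")
})

test_that("candidate calling computes locus shares and cell fractions", {
  one <- structure(list(sample_id = "s", dna_mass_pg = 653,
                        expected_malignant_cells = 0,
                        tracked = data.frame(sequence = "AAAA", locus = "IGH",
                                             templates = 10L),
                        reference_templates = 200, background = NULL,
                        reads = NULL), class = "contrived_sample")
  cand <- call_candidates(one)
  expect_equal(cand$locus_share, 1.0)
  expect_equal(cand$cell_fraction, 10 / 100)

  two <- one
  two$tracked <- data.frame(sequence = c("AAAA", "CCCC"),
                            locus = c("IGH", "IGH"),
                            templates = c(60L, 40L))
  cand2 <- call_candidates(two)
  expect_equal(sort(cand2$locus_share), c(0.4, 0.6))

  empty <- one
  empty$tracked <- NULL
  expect_equal(nrow(call_candidates(empty)), 0)
})

test_that("planted sequences are recovered among candidates at 10% disease load", {
  st <- make_id_setting(seed = 11)
  ids <- make_id_sample(st, load = 0.10)
  cand <- call_candidates(ids)
  expect_true(all(st$clone$sequences$sequence %in% cand$sequence))
})

test_that("the five trackability criteria accept and reject as specified", {
  db <- uniqueness_db(total_repertoires = 1e6)
  base <- data.frame(sequence = "S1", locus = "IGH", templates = 100L,
                     locus_share = 0.5, cell_fraction = 0.01,
                     stringsAsFactors = FALSE)

  # locus share 0.029 -> rejected on the 3% rule
  low_share <- base
  low_share$locus_share <- 0.029
  prof <- select_trackable(low_share, db = db)
  expect_equal(nrow(prof$tracked), 0)
  expect_match(prof$audit$failed_criteria, "locus_share")

  # exactly 40 templates, all else passing -> accepted
  forty <- base
  forty$templates <- 40L
  expect_equal(nrow(select_trackable(forty, db = db)$tracked), 1)
  thirty_nine <- base
  thirty_nine$templates <- 39L
  expect_equal(nrow(select_trackable(thirty_nine, db = db)$tracked), 0)

  # 6 less-abundant same-locus sequences within 10x -> rejected on separation
  neighbors <- data.frame(sequence = paste0("N", 1:6), locus = "IGH",
                          templates = 50L, locus_share = 0.06,
                          cell_fraction = 0.005, stringsAsFactors = FALSE)
  crowded <- rbind(base, neighbors)
  prof2 <- select_trackable(crowded, db = db)
  expect_false("S1" %in% prof2$tracked$sequence)
  expect_match(prof2$audit$failed_criteria[prof2$audit$sequence == "S1"],
               "separation")
  # with only 5 neighbours the same candidate passes
  prof3 <- select_trackable(rbind(base, neighbors[1:5, ]), db = db)
  expect_true("S1" %in% prof3$tracked$sequence)
})

test_that("rejected candidates always name at least one failed criterion", {
  st <- make_id_setting(seed = 13)
  ids <- make_id_sample(st, load = 0.08, seed = 13)
  prof <- select_trackable(call_candidates(ids), db = st$db)
  rejected <- prof$audit[prof$audit$failed_criteria != "", ]
  accepted <- prof$audit[prof$audit$failed_criteria == "", ]
  expect_equal(nrow(accepted) + nrow(rejected), nrow(prof$audit))
  expect_equal(nrow(accepted), nrow(prof$tracked))
  expect_true(all(nchar(rejected$failed_criteria) > 0))
})

test_that("unique-tier clones at >= 5% load are fully tracked; common-tier clones are not", {
  for (seed in c(11, 29, 47)) {
    st <- make_id_setting(seed = seed)
    for (load in c(0.05, 0.10)) {
      ids <- make_id_sample(st, load = load, seed = seed)
      prof <- select_trackable(call_candidates(ids), db = st$db,
                               patient_id = st$clone$patient_id)
      expect_true(all(st$clone$sequences$sequence %in% prof$tracked$sequence),
                  info = sprintf("seed %d load %g", seed, load))
    }
  }

  stc <- make_id_setting(seed = 11, tier = "common")
  idsc <- make_id_sample(stc, load = 0.10)
  profc <- select_trackable(call_candidates(idsc), db = stc$db)
  expect_false(any(stc$clone$sequences$sequence %in% profc$tracked$sequence))
  bad <- profc$audit[profc$audit$sequence %in% stc$clone$sequences$sequence, ]
  expect_true(all(grepl("uniqueness", bad$failed_criteria)))
})

test_that("tightening any single criterion never grows the tracked set", {
  st <- make_id_setting(seed = 17)
  ids <- make_id_sample(st, load = 0.06, seed = 17)
  cand <- call_candidates(ids)
  base_crit <- trackability_criteria()
  base_set <- select_trackable(cand, base_crit, st$db)$tracked$sequence
  tighter <- list(
    trackability_criteria(min_locus_share = 0.06),
    trackability_criteria(min_cell_fraction = 0.004),
    trackability_criteria(max_near_neighbors = 2),
    trackability_criteria(neighbor_ratio = 20),
    trackability_criteria(min_templates = 80),
    trackability_criteria(min_uniqueness = 5)
  )
  for (crit in tighter) {
    tight_set <- select_trackable(cand, crit, st$db)$tracked$sequence
    expect_true(all(tight_set %in% base_set))
  }
})
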