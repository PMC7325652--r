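# Shared fixtures, built in code.

# a clone tracked exactly (N = 0) unless stated otherwise
make_clone <- function(k = 1, tier = "unique", seed = 1) {
  gen_malignant_clone(k, tier, seed = seed)
}

# a small identification setting: repertoire + clone + database
make_id_setting <- function(seed = 11, k = 3, tier = "unique",
                            n_clones = 2000) {
  repertoire <- gen_healthy_repertoire(n_clones, seed = seed)
  clone <- gen_malignant_clone(k, tier, seed = seed)
  db <- build_uniqueness_db(clone, background = repertoire)
  list(repertoire = repertoire, clone = clone, db = db)
}

# contrive an ID sample at a given disease load (fraction of nucleated cells)
make_id_sample <- function(setting, load = 0.10, dna_mass_pg = 5e5,
                           seed = 11) {
  cells <- cells_from_mass(dna_mass_pg, round = FALSE)
  contrive_sample(setting$clone, setting$repertoire, dna_mass_pg,
                  expected_cells = load * cells, seed = seed,
                  sample_id = sprintf("id_load%g", load))
}

# toy alignment records for OPA arithmetic
toy_records <- function() {
  data.frame(length = c(20, 20), mismatches = c(1L, 0L),
             allowed = c(3L, 3L), abundance = c(5, 95))
}
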