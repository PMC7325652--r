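test_that("probit LoD matches the Poisson closed forms for 1 and 2 tracked sequences", {
  doses <- c(0.5, 0.75, 1, 1.25, 1.5, 2, 2.5, 3, 3.5, 4, 5)

  # two sequences: detection if either is sampled; 1 - exp(-2*lambda) = 0.95
  cl2 <- make_clone(k = 2, seed = 3)
  sim2 <- simulate_dilution_series(cl2, doses = doses, n_per_dose = 1500,
                                   seed = 1)
  fit2 <- fit_probit(sim2$dose, sim2$detected, n_boot = 200, seed = 1)
  expect_equal(fit2$lod, -log(0.05) / 2, tolerance = 0.07)
  expect_true(fit2$ci[["lower"]] < fit2$lod && fit2$lod < fit2$ci[["upper"]])

  # one sequence at a smaller n: same machinery, wider tolerance
  cl1 <- make_clone(k = 1, seed = 3)
  sim1 <- simulate_dilution_series(cl1, doses = doses, n_per_dose = 1500,
                                   seed = 2)
  fit1 <- fit_probit(sim1$dose, sim1$detected, n_boot = 0)
  expect_equal(fit1$lod, -log(0.05), tolerance = 0.07)

  # fitted detection probability is monotone increasing in dose
  p <- predict(fit1, seq(0.5, 6, by = 0.25))
  expect_true(all(diff(p) > 0))

  expect_error(fit_probit(c(1, 2, 3), c(TRUE, TRUE, TRUE), n_boot = 0),
               class = "mrdseq_separation")
  expect_error(fit_probit(c(1, 1), c(TRUE, FALSE), n_boot = 0),
               class = "mrdseq_invalid_parameter")
})

test_that("relative total error matches its closed forms", {
  # constant estimator equal to expected
  expect_equal(relative_total_error(rep(10, 50), 10)$rte, 0)
  # pure bias: estimator = 2x expected, zero variance
  expect_equal(relative_total_error(rep(20, 50), 10)$rte, 1.0)
  # unbiased Poisson estimates: RTE ~ 1/sqrt(lambda)
  set.seed(42)
  lam <- 16
  est <- rpois(40000, lam)
  expect_equal(relative_total_error(est, lam)$rte, 1 / sqrt(lam),
               tolerance = 0.02)
  expect_error(relative_total_error(1:3, 0),
               class = "mrdseq_invalid_parameter")
})

test_that("the Sadler profile recovers generating parameters and the Poisson LoQ", {
  x <- c(1, 2, 4, 8, 16, 32, 64, 128)

  gen <- (0.3 + 0.8 * x)^(-0.7)
  fit <- fit_sadler(x, gen)
  expect_equal(unname(coef(fit)), c(0.3, 0.8, -0.7), tolerance = 1e-6)

  # pure Poisson relative total error: y = x^(-1/2); LoQ at 70% = (1/0.7)^2
  fit_pois <- fit_sadler(x, x^(-0.5))
  expect_equal(loq(fit_pois, 0.70), (1 / 0.7)^2, tolerance = 1e-4)

  # threshold not crossed on the data range
  expect_error(loq(fit_pois, 2), class = "mrdseq_out_of_range")
  expect_error(fit_sadler(c(1, 2, 3), c(1, 0.7, 0.57)),
               class = "mrdseq_invalid_parameter")
})

test_that("limit of blank follows the nonparametric rank rule", {
  expect_equal(estimate_lob(rep(0, 84))$value, 0)

  # 100 blanks, 4 non-zero: 95th percentile still below the first non-zero
  v4 <- c(rep(0, 96), rep(0.001, 4))
  expect_equal(estimate_lob(v4)$value, 0)
  # 10 non-zero at v: the rank lands inside the non-zero block
  v10 <- c(rep(0, 90), rep(0.002, 10))
  expect_equal(estimate_lob(v10)$value, 0.002)

  # permutation invariance and monotonicity in each input value
  set.seed(9)
  vals <- rexp(60)
  expect_equal(estimate_lob(vals)$value, estimate_lob(sample(vals))$value)
  bumped <- vals
  bumped[which.max(vals)] <- max(vals) * 2
  expect_gte(estimate_lob(bumped)$value, estimate_lob(vals)$value)

  grouped <- estimate_lob(c(rep(0, 50), rep(0.01, 50)),
                          group = rep(c("a", "b"), each = 50))
  expect_equal(grouped$by_group$lob, c(0, 0.01))
  expect_error(estimate_lob(numeric()), class = "mrdseq_missing_data")
})

test_that("variance components attribute no spurious effect under Poisson-only noise", {
  g <- gen_validation_grid(abundances = 612.56, dna_inputs = c(5e5, 2e6, 2e7),
                          n_replicates = 42, seed = 1)
  v <- variance_components(g, method = "moments")
  named <- c(v$operator_set_cv, v$instrument_set_cv, v$reagent_lot_cv,
             v$day_cv, v$run_within_day_cv)
  expect_true(all(named <= 3))
  # Poisson floor at 612.56 cells: 100/sqrt(612.56) = 4.04 %CV
  expect_equal(v$reproducibility_cv, 100 / sqrt(612.56), tolerance = 0.2)
  expect_equal(v$repeatability_cv, v$residual_cv)
  expect_equal(v$lot_to_lot_cv, v$reagent_lot_cv)

  vr <- variance_components(g, method = "reml")
  named_r <- c(vr$operator_set_cv, vr$instrument_set_cv, vr$reagent_lot_cv,
               vr$day_cv, vr$run_within_day_cv)
  # spurious attributions stay well below the 4% Poisson residual
  expect_true(all(named_r <= 2.5))
  expect_equal(vr$residual_cv, 100 / sqrt(612.56), tolerance = 0.25)
})

test_that("moments-mode %CV-squared components sum to the total", {
  g <- gen_validation_grid(abundances = c(61.26, 612.56), dna_inputs = 2e7,
                          factor_cvs = c(reagent_lot = 0.03, day = 0.02),
                          n_replicates = 63, seed = 4)
  v <- variance_components(g, method = "moments")
  for (i in seq_len(nrow(v))) {
    parts <- c(v$operator_set_cv[i], v$instrument_set_cv[i],
               v$reagent_lot_cv[i], v$day_cv[i], v$run_within_day_cv[i],
               v$residual_cv[i])
    expect_equal(sum(parts^2), v$reproducibility_cv[i]^2, tolerance = 1e-8)
  }
})

test_that("an injected 2% reagent-lot CV is recovered at high abundance", {
  rec <- vapply(1:10, function(s) {
    g <- gen_validation_grid(abundances = 612.56,
                             dna_inputs = c(5e5, 2e6, 2e7),
                             factor_cvs = c(reagent_lot = 0.02),
                             n_replicates = 84, seed = s)
    variance_components(g, method = "moments")$lot_to_lot_cv
  }, numeric(1))
  expect_equal(mean(rec), 2, tolerance = 0.5)
})

test_that("the Poisson residual %CV at 2.14 cells is near 68", {
  g <- gen_validation_grid(abundances = 2.14, dna_inputs = c(5e5, 2e6, 2e7),
                          n_replicates = 1700, seed = 2)
  v <- variance_components(g, method = "moments")
  expect_equal(v$residual_cv, 68, tolerance = 0.045)
})

test_that("confounded factors and missing columns are reported", {
  g <- gen_validation_grid(abundances = c(2.14, 21.44), dna_inputs = 2e7,
                          n_replicates = 42, seed = 3)
  g$reagent_lot[g$expected_cells == 2.14] <- g$reagent_lot[
    g$expected_cells == 2.14][1]
  err <- tryCatch(variance_components(g, method = "moments"),
                  error = function(e) e)
  expect_s3_class(err, "mrdseq_confounding")
  expect_match(conditionMessage(err), "reagent_lot")
  expect_error(variance_components(data.frame(x = 1)),
               class = "mrdseq_invalid_parameter")
})

test_that("linearity: proportional data pass, quadratic contamination reduces the range", {
  lv <- c(2, 2.5, 3, 9.2, 30.6, 91.9, 306.3, 918.8, 3062.8, 9188.4, 30627.9)
  expected <- rep(lv, each = 8)

  exact <- assess_linearity(expected, expected)
  expect_equal(exact$verdict, "linear")
  expect_equal(exact$slope, 1.0, tolerance = 1e-10)
  expect_equal(exact$accepted_range, range(lv))
  expect_false(exact$range_reduced)

  set.seed(4)
  quad <- assess_linearity(expected + 0.002 * expected^2, expected)
  expect_true(quad$range_reduced || quad$verdict == "nonlinear")

  # Poisson-noise dilution series: slope within the validated 0.95-1.03 band
  set.seed(11)
  noisy <- assess_linearity(rpois(length(expected), expected), expected)
  expect_equal(noisy$verdict, "linear")
  expect_gte(noisy$slope, 0.95)
  expect_lte(noisy$slope, 1.03)

  expect_error(assess_linearity(1:6, rep(c(1, 10, 100), 2)),
               class = "mrdseq_insufficient_design")
})

test_that("linearity verdict is invariant to replicate order", {
  lv <- c(2, 20, 200, 2000, 20000)
  expected <- rep(lv, each = 6)
  set.seed(5)
  observed <- rpois(length(expected), expected)
  a <- assess_linearity(observed, expected)
  perm <- sample(length(expected))
  b <- assess_linearity(observed[perm], expected[perm])
  expect_equal(a$verdict, b$verdict)
  expect_equal(a$slope, b$slope)
})

test_that("nested-bootstrap bias matches constant-shift cases and covers zero", {
  grid <- expand.grid(sample = sprintf("s%d", 1:8), replicate = 1:3)
  d0 <- data.frame(stratum = "a", sample = grid$sample,
                   observed = 50, expected = 50)
  b0 <- bootstrap_bias(d0, n_boot = 500, seed = 1)
  expect_equal(b0$relative_bias, 0)
  expect_lte(b0$ci_lower, 0)
  expect_gte(b0$ci_upper, 0)

  d25 <- transform(d0, observed = 1.25 * expected)
  b25 <- bootstrap_bias(d25, n_boot = 500, seed = 1)
  expect_equal(b25$relative_bias, 0.25)
  expect_equal(b25$ci_upper - b25$ci_lower, 0)

  one <- data.frame(stratum = "a", sample = "s1", observed = c(48, 52),
                    expected = 50)
  expect_true(bootstrap_bias(one, n_boot = 100, seed = 1)$degenerate)
  expect_error(bootstrap_bias(data.frame(stratum = 1, sample = 1,
                                         observed = 1, expected = 0)),
               class = "mrdseq_invalid_parameter")
})

test_that("bootstrap CIs cover zero bias in most unbiased simulations", {
  covered <- logical(100)
  for (r in seq_len(100)) {
    set.seed(1000 + r)
    d <- do.call(rbind, lapply(1:12, function(sm) {
      data.frame(stratum = "s", sample = sprintf("s%d", sm),
                 observed = rpois(2, 25), expected = 25)
    }))
    b <- bootstrap_bias(d, n_boot = 500, seed = r)
    covered[r] <- b$ci_lower <= 0 && 0 <= b$ci_upper
  }
  expect_gte(mean(covered), 0.93)
})
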