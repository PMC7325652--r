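#' Variance-component precision analysis
#'
#' Decomposes replicate MRD measurement variability at each expected cell
#' input into components attributable to operator set, instrument set,
#' reagent lot, day, run within day, and residual error, each reported as a
#' percent coefficient of variation (100 * sd / mean). Repeatability is the
#' residual %CV; reproducibility is the %CV of the summed components;
#' lot-to-lot variability is the reagent-lot %CV.
#'
#' Two estimators are provided. `"reml"` (default) fits a random-intercept
#' mixed model on `log(count + 0.5)` with every process factor as a random
#' effect and back-transforms each log-scale variance v to
#' `%CV = 100 * sqrt(exp(v) - 1)` (multiplicative effects model).
#' `"moments"` works on the raw count scale: each factor's component comes
#' from its one-way ANOVA mean squares `(MSB - MSW) / n0` truncated at zero,
#' and the residual is the observed total variance minus the factor sum
#' (truncated), so the %CV-squared decomposition sums to the raw total by
#' construction. The raw-scale mode is the one comparable to a Poisson floor:
#' pure Poisson counts at lambda have residual %CV `100 / sqrt(lambda)`.
#'
#' @param grid a [gen_validation_grid()] data frame (or any data frame with
#'   `expected_cells`, `measurement`, and the five factor columns).
#' @param method `"reml"` or `"moments"`.
#' @param exclude_below drop measurements with `expected_cells` below this
#'   value (used to exclude levels below the assay LoD); default keeps all.
#' @return an object of class `vca_table`: one row per abundance with per-
#'   factor %CV, residual, repeatability, reproducibility, and lot-to-lot %CV.
#' @export
variance_components <- function(grid, method = c("reml", "moments"),
                                exclude_below = 0) {
  method <- match.arg(method)
  factors <- c("operator_set", "instrument_set", "reagent_lot", "day",
               "run_within_day")
  need <- c("expected_cells", "measurement", factors)
  missing_cols <- setdiff(need, names(grid))
  if (length(missing_cols))
    stop_invalid("grid lacks column(s): ", paste(missing_cols, collapse = ", "))
  grid <- grid[grid$expected_cells >= exclude_below, , drop = FALSE]
  abundances <- sort(unique(grid$expected_cells))
  rows <- list()
  for (a in abundances) {
    g <- grid[grid$expected_cells == a, , drop = FALSE]
    for (f in factors) {
      if (length(unique(g[[f]][!is.na(g[[f]])])) < 2) {
        cond <- structure(
          class = c("mrdseq_confounding", "error", "condition"),
          list(message = sprintf(
            "factor '%s' has a single level at expected_cells = %g: confounded with abundance",
            f, a), call = sys.call()))
        stop(cond)
      }
    }
    y <- g$measurement
    mu <- mean(y)
    comp <- if (method == "moments") {
      vc_moments(y, g, factors)
    } else {
      vc_reml(y, g, factors)
    }
    cv <- if (method == "moments") {
      100 * sqrt(comp) / mu
    } else {
      100 * sqrt(exp(comp) - 1)
    }
    names(cv) <- names(comp)
    total_var_cv <- if (method == "moments") {
      100 * sqrt(sum(comp)) / mu
    } else {
      100 * sqrt(exp(sum(comp)) - 1)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      expected_cells = a, n = length(y), mean = mu,
      operator_set_cv = cv[["operator_set"]],
      instrument_set_cv = cv[["instrument_set"]],
      reagent_lot_cv = cv[["reagent_lot"]],
      day_cv = cv[["day"]],
      run_within_day_cv = cv[["run_within_day"]],
      residual_cv = cv[["residual"]],
      repeatability_cv = cv[["residual"]],
      reproducibility_cv = total_var_cv,
      lot_to_lot_cv = cv[["reagent_lot"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, method = method, class = c("vca_table", "data.frame"))
}

# Raw-scale method-of-moments components: one-way ANOVA per factor,
# (MSB - MSW)/n0 truncated at 0; residual = total variance minus factor sum.
vc_moments <- function(y, g, factors) {
  N <- length(y)
  comp <- numeric(length(factors))
  names(comp) <- factors
  for (f in factors) {
    grp <- if (f == "run_within_day") {
      interaction(g$day, g$run_within_day, drop = TRUE)
    } else {
      factor(g[[f]])
    }
    grp <- droplevels(grp)
    k <- nlevels(grp)
    m_i <- tapply(y, grp, mean)
    n_i <- as.numeric(table(grp))
    msb <- sum(n_i * (m_i - mean(y))^2) / (k - 1)
    msw <- sum((y - m_i[grp])^2) / (N - k)
    n0 <- (N - sum(n_i^2) / N) / (k - 1)
    comp[f] <- max(0, (msb - msw) / n0)
  }
  total <- stats::var(y)
  c(comp, residual = max(0, total - sum(comp)))
}

# REML components of log(count + 0.5) via lme4; returns log-scale variances.
vc_reml <- function(y, g, factors) {
  d <- g
  d$.resp <- log(y + 0.5)
  form <- stats::as.formula(paste(
    ".resp ~ (1|operator_set) + (1|instrument_set) + (1|reagent_lot) +",
    "(1|day) + (1|day:run_within_day)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = d,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(name) {
    v <- vc$vcov[vc$grp == name]
    if (length(v) == 0) 0 else v
  }
  c(operator_set = get("operator_set"),
    instrument_set = get("instrument_set"),
    reagent_lot = get("reagent_lot"),
    day = get("day"),
    run_within_day = get("day:run_within_day"),
    residual = get("Residual"))
}

#' @export
print.vca_table <- function(x, digits = 1, ...) {
  cat(sprintf("Variance-component precision analysis (%s estimator)\n",
              attr(x, "method")))
  cat("%CV attributed to each variable, by expected cell input:\n")
  tab <- as.data.frame(x)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
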