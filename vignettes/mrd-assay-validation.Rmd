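---
title: "MRD quantification by clonotype tracking and its analytical validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRD quantification by clonotype tracking and its analytical validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdseq)
```

## The measurement model

Measurable residual disease (MRD) in B-cell malignancies is expressed as the
number of malignant cells per total nucleated cells in a sample. An
immunosequencing assay measures it in two stages. First, a high-burden
diagnostic ("ID") sample is sequenced and the malignant clone's rearranged
immunoglobulin receptor sequences — its *clonotypes*, at the IGH, IGK and IGL
loci and at IGH-BCL1/IGH-BCL2 translocation amplicons — are identified.
Second, in follow-up ("MRD") samples, gDNA templates carrying those tracked
sequences are counted. Because each rearrangement is present at one genomic
copy per malignant cell, a template count is a direct estimate of the number
of malignant cells whose DNA entered the assay.

Two quantities complete the measurement:

* **Total nucleated cells.** Amplicons from genomic regions that are diploid
  in normal DNA are counted alongside; `total_nucleated_cells()` divides the
  reference-template count by two, falling back to the mass conversion
  `dna_mass_pg / 6.53` (one human diploid genome weighs 6.53 pg) when
  reference counts are absent.
* **Consensus malignant-cell count.** Each tracked rearrangement's template
  count is an independent, unbiased Poisson estimate of the same malignant
  cell number. `consensus_malignant_cells()` therefore averages the
  per-sequence counts (zero counts included); this mean is itself unbiased
  and its recovery of the generating Poisson mean is what the tests check.
  Abundance-weighted and maximum alternatives are available as options, but
  the mean is the default and the documented behaviour. The MRD frequency is
  the consensus divided by total nucleated cells, defined to be exactly 0
  when the consensus is 0.

At the low end the assay is template-limited: if a sample truly contains
$\lambda$ malignant cells, the chance that at least one template of a single
tracked sequence is drawn is $1 - e^{-\lambda}$, so no single-sequence assay
can reach 95% detection below $-\ln(0.05) \approx 3$ cells, and no estimator
can beat the Poisson coefficient of variation $100/\sqrt{\lambda}$ (about
70% at 2 cells). Tracking $k$ sequences shifts both limits by a factor of
$k$ in the effective sampling rate. These closed forms are the package's
primary correctness oracles.

## Trackability and mismatch tolerance

`select_trackable()` applies five criteria to each candidate clonotype from
`call_candidates()`; all thresholds live in `trackability_criteria()`:

* at least 3% of all sequences at its locus (`min_locus_share`);
* at least 0.2% of all nucleated cells (`min_cell_fraction`), with the
  denominator taken from the diploid reference amplicons, not read totals;
* separation from the background: no more than 5 other less-abundant
  same-locus sequences within a factor of 10 in frequency, ties broken
  toward rejection;
* at least 40 supporting gDNA templates (`min_templates`);
* sufficient uniqueness.

Uniqueness is scored against a database of previously observed
rearrangements as the add-one smoothed negative log incidence rate,
$-\log_{10}((\text{incidence}+1)/(\text{total}+1))$: 6 for a sequence never
seen in $10^6$ repertoires, 0 for one seen in all of them. The functional
form is a package choice — any score monotone in incidence and bounded would
do — and the default acceptance cutoff is 3 (roughly "rarer than 1 in
1,000"). Every rejected candidate records which criteria failed; an empty
profile is a legitimate outcome.

Tracking tolerates somatic hypermutation by allowing up to $N$ Hamming
mismatches per tracked sequence (`allowed_mutations()`), with $N$ rising in
tiers with the uniqueness score: 0 below score 2, then
$\min(3, \lfloor L \cdot f \rfloor)$ with $f = 1/45, 2/45, 1/15$ at scores
2, 3.5 and 5 — i.e. 1, 2, 3 mismatches on a 45-nt sequence. The tier
boundaries and cap are exposed as arguments; only their monotone shape
matters to the downstream logic. Matching (`match_tracked()`) is
Hamming-only with an equal-length requirement — no indels — and each
observed sequence is assigned to at most one tracked sequence (the nearest;
ties go to the lowest-index sequence and are flagged).

Sequence agreement is summarised by the overall percent agreement:
for records with $\text{mismatches} \le N$,

$$\mathrm{OPA} = 100 \cdot
  \frac{\sum (\text{Length}-\text{Mismatches})\cdot\text{Abundance}}
       {\sum \text{Length}\cdot\text{Abundance}},$$

accumulated in exact integer arithmetic before the final division. The
disagreement rate $1 - \mathrm{OPA}/100$ is restated as a Phred score using
the standard $-10\log_{10}$ convention (`phred_score()`); a plain
$-\log_{10}$ restatement would compress typical immunosequencing error rates
(a few per 100,000 nucleotides) to values near 4.5 instead of the
conventional 40–45 range, so the factor-10 scaling is used throughout. A
rate of exactly 0 maps to a configurable cap (default 60).

## The six validation procedures

**Probit LoD** (`fit_probit`). Detection outcomes are modelled as
$\Phi(a + b\,\log_{10} x)$ by maximum likelihood; the LoD solves the fitted
probability for the 95% target. The log dose scale is the standard choice
for detection limits and behaves well over the 1–23 cell range where such
studies concentrate; a linear-dose mode is retained. The CI is a
nonparametric bootstrap stratified by dose level (outcomes resampled within
each dose, 2,000 refits by default on the dose-aggregated binomial fit).
Complete separation raises a classed error rather than a silent unstable
fit.

**Relative total error and Sadler LoQ** (`relative_total_error`,
`fit_sadler`, `loq`). RTE at a level is RMSE divided by expected cells —
equivalently $\sqrt{\text{bias}^2+\text{variance}}/x$. The precision
profile $y = (\beta_1 + \beta_2 x)^J$ is fitted by nonlinear least squares,
multi-started over a grid of exponents $J \in \{-2,\dots,2\}\setminus\{0\}$
with linearised starts for $\beta_1,\beta_2$ at each $J$ (the model is
ill-posed from a single arbitrary start). The LoQ solves the fitted curve
for 70% RTE by bisection over the data range; failure to cross raises an
out-of-range error. The profile is fitted to RTE by default because the LoQ
is defined on total error; a raw-variance mode is the same call with a
different `y`. On a pure-Poisson profile $y = x^{-1/2}$ the LoQ is
$(1/0.7)^2 \approx 2.04$ cells, another analytic oracle.

**Nonparametric LoB** (`estimate_lob`). The 95th percentile of MRD
measurements among all tracked sequences in all blank samples, at rank
$0.5 + 0.95n$ with linear interpolation between order statistics (the
CLSI-style rule; only "nonparametric" is essential), per DNA-input level
and overall.

**Variance components** (`variance_components`). Per expected-cell input,
replicate variability is decomposed over operator set, instrument set,
reagent lot, day, and run within day, each reported as
$100\cdot\mathrm{sd}/\mathrm{mean}$. Two estimators: REML (default) fits
`lmer` random intercepts on $\log(y+0.5)$ — matching the generator's
multiplicative factor effects — and back-transforms each variance $v$ to
$100\sqrt{e^v - 1}$; the moments mode works on the raw count scale with
one-way ANOVA components $(\mathrm{MSB}-\mathrm{MSW})/n_0$ truncated at
zero and the residual defined as the observed total variance minus the
factor sum, so the %CV² decomposition sums to the total by construction.
The raw scale is the one comparable to the Poisson floor
($100/\sqrt{2.14} \approx 68$ %CV at the lowest input), so the
low-abundance checks use the moments mode. Repeatability is the residual
%CV, reproducibility the %CV of the summed components, lot-to-lot the
reagent-lot %CV. A factor with a single level at some abundance raises a
confounding error naming the factor.

**Polynomial linearity** (`assess_linearity`). First-, second- and
third-order polynomials are fitted; if no nonlinear coefficient is
significant at $P<0.05$ the range is linear. Otherwise the best-fitting
higher-order model (lowest AIC) is compared with the linear fit at every
tested level; deviations within ±5% are acceptable, else the extreme level
with the larger deviation is dropped and the procedure repeats (down to 4
levels). Regression is on $\log_{10}$-transformed frequencies — both axes
span orders of magnitude and multiplicative error is the natural scale —
with the ±5% comparison made after back-transforming. Observed zeros cannot
be log-transformed and are excluded, with their count reported. A
zero-residual fit (exact proportional data) yields NaN p-values, which
count as not significant.

**Nested-bootstrap bias** (`bootstrap_bias`). Relative errors
$(\text{obs}-\text{exp})/\text{exp}$ are averaged per stratum; the CI
resamples samples with replacement within the stratum, then replicates
within each drawn sample (10,000 replicates, percentile 95% CI). The
point estimate is the unweighted mean over replicates. Single-sample
strata are flagged degenerate rather than rejected.

## What the synthetic data emulate — and what they do not

`gen_healthy_repertoire()` draws clone frequencies from a rank power law
(default exponent 0.5 over 2,000 clones, giving a top clone near 1% of the
repertoire — a polyclonal marrow with no dominant expansion) and assigns
random 45-nt sequences (a typical IGH CDR3 scale) to loci at weights
IGH 0.45, IGK 0.30, IGL 0.15, translocation amplicons 0.05 each. With these
defaults a malignant clone at ≥5% of nucleated cells clears all five
trackability criteria, which is the recovery property the tests assert.

`contrive_sample()` emulates spiking disease gDNA into a healthy diluent:
each tracked rearrangement's template count is an independent
Poisson(expected cells) draw — one genome copy per rearrangement per cell —
optionally perturbed by multiplicative lognormal noise (`extra_cv`) and
re-rounded (counts are discrete, floored at 0). Reference templates are
`2 * round(mass / 6.53 pg)` before noise. Note that rounding is not
homogeneous: exact doubling of reference templates under doubled mass holds
at masses that are whole cell equivalents. Read records with substitution
errors injected at a per-base rate are attached on request; error-free
templates collapse into one record and each mutated template is
materialised individually, which keeps 10⁷-nucleotide error simulations
cheap. RNG streams are derived per (sample, sequence) from the master seed,
so subsetting a study never shifts the remaining samples' draws.

`gen_validation_grid()` emulates a main-effects screening design (3
operator sets, 2 instrument sets, 4 reagent lots, 21 days, 10 runs/day):
levels are balanced within each abundance × DNA-input cell and assigned by
random permutation, and factor effects are multiplicative lognormal draws
made once per level and shared across strata — a random-effects model on
the log scale. `gen_blank_panel()` produces healthy-only samples; with a
nonzero collision rate, a coincidentally matching clone is planted at
1 + Poisson(0.5) templates, a small count consistent with collisions coming
from intermediate-uniqueness rearrangements.

The generator deliberately omits V(D)J recombination structure (no gene
segments, no junctional biology), PCR chimeras, amplification bias, and any
disease-specific clone-size distributions. Passing tests therefore
demonstrate the statistical machinery — Poisson sampling arithmetic,
criterion logic, estimator calibration — not performance on real
repertoires, whose sequence composition and background collision structure
are richer.

## Numerical choices and study sizes

Detection studies use 8 doses from 1 to 5 cells (concentrated around the
3-cell Poisson limit) with equal allocation; the LoD oracle check runs
50,000 samples, below which the probit's mild misspecification against the
true $1-e^{-\lambda}$ curve is indistinguishable from Monte-Carlo noise.
Precision-floor checks use 5,000–20,000 replicate samples at 2.14 cells
(the CV of a CV estimator needs $n \gtrsim 5{,}000$ for ±3 %CV
resolution); VCA parameter-recovery checks average 10 independent grids.
The bias study uses 4 strata × 20 samples × 2 replicates with 10,000
bootstrap replicates; the coverage property is checked over 100 repetitions
at 500 replicates each, since percentile-CI coverage is insensitive to the
bootstrap count beyond a few hundred. The demo pipeline
(`run_pipeline(study_config())`) uses smaller sizes throughout; every size
is a `study_config()` field.

Ties, degenerate inputs, and edge cases: separation comparisons break ties
toward rejection; observed sequences equidistant from two tracked sequences
go to the lower index and are flagged; `mrd_frequency` is exactly 0 on a
zero consensus; empty candidate lists, empty profiles and all-zero blank
panels are valid inputs with defined outputs; negative variance components
are truncated at zero.

## Known limitations

* Hamming-only matching cannot absorb indels, which real somatic
  hypermutation occasionally produces.
* The uniqueness score's functional form and the mismatch-budget tiers are
  package choices; only their monotone behaviour is load-bearing.
* The moments-mode VCA uses one-way ANOVA per factor, which slightly
  understates components in crossed designs; at screening-design sizes a
  named factor can pick up ~2 %CV of spurious effect under pure Poisson
  noise, so small attributions should be read against that floor.
* Log-scale linearity regression must drop observed zeros, which biases the
  lowest levels when counts are very small.
* The consensus mean treats all tracked sequences equally;
  intermediate-uniqueness sequences are annotated, not down-weighted.
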