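---
title: "Tertile-conditional prognostic biomarker discovery with constru"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tertile-conditional prognostic biomarker discovery with constru}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(constru)
```

## The problem

Immune activity scores such as the cytolytic activity score (CYTscore, the
mean log2 expression of *GZMA* and *PRF1*) predict overall survival in some
tumor cohorts and not in others, and often only in a subset of patients.
`constru` implements a scan that asks, for every gene of an expression
matrix, whether the *relative expression state* of that gene — low,
intermediate or high — conditions the score's prognostic power. Genes whose
tertiles reproducibly gate the score-survival association across
independent cohorts are then assembled into a stratification signature
(STRATsig) whose population tertiles define patient subgroups in which the
score is, or is not, informative.

## The scan

For each gene $g$ of a cohort with survival follow-up:

1. Samples are sorted by the gene's expression and split into tertiles
   T1 (lowest) < T2 < T3 (highest). The sample at 0-based sorted rank $r$
   of $n$ receives tertile $\lfloor 3r/n \rfloor$; ties are broken by the
   original sample index, so group sizes differ by at most one and the
   assignment is deterministic.
2. Within each tertile a multivariable Cox proportional-hazards model of
   overall survival on the continuous score is fitted, adjusted for patient
   age (continuous), FIGO stage (low = I/II, high = III/IV, missing as an
   explicit third level) and surgical debulking status (optimal,
   suboptimal, missing as a third level). The score's hazard ratio
   $HR_t$ and two-sided Wald p-value $P_t$ are recorded per tertile.
3. The whole-cohort interaction model
   $\text{score} + g + \text{score}\times g$ is fitted and the interaction
   term's HR and p-value recorded. It is reported for comparison only and
   never used for gene selection.
4. The Pearson correlation $r(g, \text{score})$ is recorded.

Genes whose T1 and T3 fits both converge receive a **parity score**

$$\Pi_g \;=\; \frac{-\log_{10} P_{T1}}{HR_{T1}} \;-\;
  \frac{-\log_{10} P_{T3}}{HR_{T3}},$$

a signed contrast of significance and effect size between the gene's lower
and upper tertiles. Large positive $\Pi_g$ marks *LowerT*-type genes (the
score-survival association concentrates where the gene is low); large
negative $\Pi_g$ marks *UpperT*-type genes. P-values are clamped at
$10^{-300}$ before the log transform.

Because a gene correlated with the score makes a poor stratifier — its
tertiles compress the score's distribution — genes with
$|r| > 0.15$ are filtered after the scan. Parity scores of the surviving
genes are mapped to percentile ranks ($100\,r/(n-1)$ with 0-based average
ranks for ties), which makes rankings comparable across cohorts with
different gene universes.

Candidate selection intersects two (or more) independent training cohorts:
UpperT candidates sit at or below the cutoff percentile (2, 4 or 6; default
4) in *every* cohort, LowerT candidates at or above 100 minus the cutoff. A
gene qualifying for both sets across discordant cohorts is excluded from
both. STRATsig is the mean log2 expression of the UpperT list minus that
of the LowerT list; its population tertiles (computed on all cases of a
cohort, never within subsets) define the patient strata for downstream
evaluation.

## Survival machinery and conventions

Cox models are fitted by the `survival` package's Newton-Raphson machinery
with **Efron** handling of tied event times; per-term inference is by Wald
test with $\exp(\beta \pm 1.96\,\mathrm{se})$ confidence intervals. These
are conventions of this package (the reference survival ecosystem's
defaults), fixed for determinism. Monotone likelihood and non-convergence
are never fatal: the affected fit is flagged non-estimable, and genes
without both T1 and T3 estimates are excluded from parity ranking but kept
in the output with a reason code — this prevents $\pm\infty$ parity
artifacts. Binary nuisance indicators with zero events on either side
(e.g. a missing-stage level concentrated in a small tertile) are dropped
from that fit before estimation, since they carry no partial-likelihood
information and would only force spurious non-convergence.

Overall survival is administratively censored at 8 years (inclusive: an
event at exactly 8 years is retained), which standardizes follow-up across
cohorts and limits age-related mortality. Samples with zero follow-up time
are dropped with a warning, since their risk-set contribution is
undefined. Partially missing age is mean-imputed within cohort; a fully
missing covariate is dropped from every model with a logged message.
Two-sample comparisons use a Welch t-test when both samples pass
Shapiro-Wilk normality at $\alpha = 0.05$ and the Mann-Whitney rank-sum
test otherwise.

## The synthetic cohort generator

`simulation_spec()`/`simulate_cohort()` generate cohorts with the
statistical structure the scan assumes, so every stage is testable without
external data. Expression is gene-wise normal on log2 scale (baselines
uniform on [4, 12], noise sd 1); the two score genes (*GZMA*, *PRF1*)
share correlated noise ($\rho = 0.6$ by default) and the CYTscore is their
per-sample mean. Covariates emulate a high-grade serous ovarian carcinoma
cohort loosely: age $\sim N(60, 10)$, 80% stage high, 40% suboptimally
debulked, each maskable to missing (5% by default). The per-sample
log-hazard is

$$\eta_i = \sum_{\text{planted } g} \beta_g \,\tilde s_i\,
  \mathbf 1[i \in \text{active tertile of } g]
  + 0.2\,\frac{\text{age}_i - 60}{10} + 0.4\,\mathbf 1[\text{suboptimal}_i],$$

where $\tilde s$ is the **centered** score. Centering is deliberate: Cox
fits are invariant to covariate shifts, so the inferential target is
unchanged, but an uncentered log2-scale score (≈ 8) would scale the active
tertile's hazard by $e^{-8}$, emptying it of events and making every
planted fit non-estimable rather than making the association strong. The
active tertile is computed from the simulated expression by the same
tertile rule the scan applies, so discovery is exactly the inverse of
generation. Event times follow a Weibull baseline (shape 1.2, scale 9.6
years, chosen to give roughly 55% events by year 8 at baseline
covariates); censoring is the minimum of a 10-year administrative horizon
and a uniform dropout time on [1, 25] years. Everything is reproducible
from the spec's single seed.

What the generator does **not** emulate: probe-level microarray structure,
batch effects, heavy-tailed or count-scale expression, correlated gene
modules, and informative censoring. Passing tests on these cohorts
therefore demonstrate the correctness and calibration of the machinery
under the model's assumptions, not robustness to real-data pathologies —
probe collapsing and the loader's strict missing-data policy handle part
of that gap, the rest is up to upstream normalization.

## Numerical and design choices

- **Tertile ties** break by original sample index (stable radix sort):
  deterministic output was preferred over randomized tie-breaking.
- **Percentile ranks** use 0-based average ranks scaled by
  $100/(n-1)$, so the observed extremes always map to 0 and 100.
- **Filter ordering**: the correlation filter runs after the scan and
  before ranking; percentile ranks are always recomputed over exactly the
  unfiltered, estimable records.
- **z-score signatures** (the APM antigen-presentation score) use the
  population (n-denominator) standard deviation, fixed for determinism;
  z-scores are computed within-cohort.
- **Missing signature genes** are omitted and reported, with an error when
  less than half of a list is present (override via `min_fraction`); this
  mirrors how partially represented platforms are handled in practice.
- **Score tertiles are frozen at the whole-cohort level** and carried into
  subgroups and stratifier tertiles, never recomputed inside subsets. This
  is the single most consequential design rule in the evaluation module:
  recomputing tertiles within a subset would answer a different question
  (relative rank within the subgroup rather than within the population).
- **Stratifier-score guard**: `evaluate_tertiles()` refuses a stratifier
  with $|r| > 0.5$ against the score, for the same compression reason as
  the scan's 0.15 gene filter; the evaluation threshold is looser because
  a composite signature aggregates away single-gene noise.
- **Benjamini-Hochberg** control is applied only in the per-gene survival
  screen (`gene_survival_screen()`, defaults HR < 0.80, adjusted
  p < 0.01), never to the scan itself, whose ranking is by parity score.
- The parity formula is implemented exactly as printed above; the ranking
  function is a seam (`parity_score()` is a plain vectorized function)
  so alternative contrasts can be swapped in by advanced users.
- Whether the interaction-term variant should participate in selection was
  an open design question; it is emitted for comparison and never used.

## Problem sizes used by the test-suite

The packaged checks run the full pipeline at deliberately moderate sizes —
cohorts of 120-600 samples and 10-2,000 genes, 5-10 seeds or seed pairs
per property — which keeps the whole suite in the minutes range while
leaving the planted effects ($\beta = -1$ per score unit, active in one
tertile of ~200 samples) strong enough for near-certain recovery. Null
calibration is assessed at 2,000 genes x 5 seeds. One caveat discovered
during development and worth knowing: conditional on a single simulated
cohort, the per-gene within-tertile score tests are strongly dependent
(they share one realized score-survival dataset), so the across-gene
rejection fraction of a single cohort is heavy-tailed around its nominal
level even though it is unbiased across seeds.

## Worked example

```{r example, eval = FALSE}
spec <- simulation_spec(
  n_samples = 600, n_genes = 2000,
  planted = list(list(gene = 10, active_tertile = "T3", beta_score = -1),
                 list(gene = 11, active_tertile = "T1", beta_score = -1)))
pair <- simulate_cohort_pair(spec, seed_a = 11, seed_b = 12)

scan_one <- function(cohort) {
  cohort <- cap_followup(cohort, 8)
  cyt <- score_signature(cohort$expr, builtin_signature("CYTscore"))
  correlation_filter(constru_scan(cohort, as.numeric(cyt)), 0.15)
}
tabs <- lapply(pair, scan_one)
select_candidates(tabs, cutoff_percentile = 4)
```

## Known limitations

Tertiles are the only quantile partition implemented (no per-gene optimal
cut-point search); Cox fitting excludes time-varying covariates, strata,
frailty and competing risks; the scan applies no multiplicity control by
design (ranking, not testing); and the simulator's normality means heavy
platform-specific artifacts must be handled before loading.
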