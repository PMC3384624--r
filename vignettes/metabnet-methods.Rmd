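---
title: "Models and methods behind metabnet"
author: "metabnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metabnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabnet)
```

# Scope and model

`metabnet` analyses a subjects × metabolites concentration table from a
targeted serum metabolomics panel against a continuous body-composition
phenotype, by default the fat free mass index (FFMI, kg/m²).  The working
model is that log concentrations are jointly Gaussian: each metabolite
$j$ satisfies

$$ z_j = \beta_j \,\mathrm{FFMI} + \gamma_a\,\mathrm{age} +
   \gamma_s\,\mathrm{sex} \,(+\,\mathrm{batch}) + \varepsilon, $$

where $z_j$ is the inverse log-normal standardisation
$z = (\ln x - \overline{\ln x})/\mathrm{sd}(\ln x)$ and the noise vector
has an (unknown) sparse inverse covariance.  Three consequences drive the
pipeline design: betas on the $z$ scale are comparable across metabolites;
log-ratios of metabolites are differences of logs, so a shared
multiplicative factor cancels in a ratio (the rationale for the p-gain
statistic); and the precision matrix of the residuals encodes full-order
partial correlations, the edges of the Gaussian graphical model (GGM).

# Quality control

QC runs in a fixed order: CV filter → missingness filter → outlier
detection → subject policy → imputation.  All comparisons are strict, per
their usual phrasing ("bigger than", "exceeded", "more than"):

* **CV filter.** For every metabolite and plate with ≥ 2 reference-sample
  replicates, CV = sample SD / mean; the mean CV over plates (unweighted;
  zero-mean plates excluded with a warning) must not exceed 25%.
* **Missingness.** Metabolites with > 5% missing cells are removed.
* **Outliers.** A cell is flagged iff it lies strictly outside
  mean ± 5 SD of its metabolite, with mean and SD computed in a single
  pass over all subjects including the candidate — iterative re-estimation
  is deliberately not done, so the flag set is a deterministic function of
  the matrix.
* **Independent outliers.** Two flagged metabolites of one subject count
  as one event when their full concentration columns correlate at
  |r| ≥ 0.70 (pairwise-complete, over all subjects); a subject's
  independent-outlier count is the number of connected components of this
  dependency graph restricted to their flagged metabolites.  Column
  correlation is the only interpretation of outlier "dependence" that is
  computable from the stated data, and components give a conservative
  count.  Subjects with more than three independent outliers are dropped;
  otherwise only the flagged cells become missing.
* **Imputation.** Chained-equations regression on the log scale: targets
  in decreasing-missingness order, each regressed on its 10
  most-correlated metabolites (current working values), five sweeps, one
  completed dataset.  The fill is the linear prediction plus residual
  noise drawn under the recorded seed; `noise = FALSE` gives the
  conditional-mean fill.  Note the two modes answer different questions:
  the noisy fill preserves variances (its RMSE against withheld truth is
  inflated by a factor of about $\sqrt2$ by construction), the mean fill
  minimises prediction error and is what imputation-quality checks should
  score.  Ill-conditioned regressions fall back to the metabolite mean,
  logged in the report.

The `QcReport` records every exclusion with exactly one reason, every
flagged cell and every imputed cell, so the QC'd matrix can be replayed
from the input.

# Association and multiple testing

Ordinary least squares per trait, two-sided t test on the exposure
coefficient, adjusted $R^2$ of the full model; sex is coded 0/1 and batch
enters as indicator contrasts.  Robust/sandwich errors are not used — the
model is evaluated under its own assumptions, which the simulator
reproduces.  The default significance threshold is $\alpha/M_\mathrm{eff}$
with $M_\mathrm{eff}$ the Li–Ji eigenvalue estimator
$\sum_k \big[ I(\lambda_k \ge 1) + (\lambda_k - \lfloor \lambda_k \rfloor)\big]$
on the trait correlation matrix: with uncorrelated traits it equals the
Bonferroni count $M$ exactly (the eigenvalues sum to $M$ and all lie in
$(0,2)$), and with perfectly correlated traits it collapses to 1.
Published fixed thresholds (e.g. $3.12\times10^{-4}$) can be replayed via
`threshold_method = "fixed"`; they are not derivable without the original
correlation structure.  Stratified analyses (sex, age ≤/> 65, activity,
BMI </≥ 30) recompute the threshold within each stratum and skip strata
under 50 subjects.

# Ratios and the p-gain

All unordered intra-class pairs become ratio traits (orientation
lexicographic; swapping numerator and denominator only flips the beta sign
under the log transform).  The p-gain of a ratio is
$\min(p_{M1}, p_{M2})/p_\mathrm{ratio}$, computed in log10 space so
p-values below double precision do not underflow.  A ratio is significant
when its p-value clears the metabolite threshold *and* its p-gain strictly
exceeds the cutoff; the default cutoff is the number of metabolites after
QC, a Bonferroni-flavoured guard against ratios that merely inherit one
constituent's signal.  The class partition behind any published pair count
is generally not recoverable from class sizes alone, so the partition is
configurable: default one class per chemical class, plus a `merge_lipids`
preset pooling PC aa / PC ae / lysoPC.

# The Gaussian graphical model

Covariates (age, sex, FFMI, batch) are removed from every transformed
metabolite by linear residualisation first — covariates are treated
asymmetrically from metabolites, matching the "controlled for age, sex,
FFMI and the remaining metabolites" formulation — and the precision matrix
$\Omega$ of the residual covariance gives
$\rho_{ij} = -\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$.  This equals the
per-pair regress-out-everything-else residual correlation on every
dataset, an identity the test suite checks to $10^{-10}$ on random SPD
instances.  Edge significance uses the Fisher z statistic
$\operatorname{atanh}(r)\sqrt{n-k-3}$ with $k$ counting every conditioned
variable (covariates plus the $M-2$ other metabolites), Bonferroni over
$\binom{M}{2}$ pairs at $\alpha=0.01$; edges additionally require
$|r| \ge 0.3$ (inclusive, on the absolute value — the sign is kept as an
attribute).  An optional covariance ridge (off by default; $n = 965$
comfortably exceeds $M = 166$) marks results as regularised for small
cohorts.  Exports (GraphML/GML via igraph, TSV edge list) round-trip all
node and edge attributes at full double precision.

# The synthetic cohort

The generator is a pure function of its configuration (including the
seed).  Defaults are the study conditions:

* **Phenotypes** (n = 965): sex Bernoulli(½); FFMI normal with
  sex-specific moments 19.71 ± 1.66 (men) / 16.99 ± 1.85 (women); body fat
  mass index 8.34 ± 2.29 / 11.24 ± 3.08; heights 172.3 ± 6.4 cm /
  159.3 ± 6.0 cm; age normal(63.2, 5.5²) truncated to [51, 80]; fat free
  and fat mass back-computed as index × height²; three measurement batches.
* **Concentrations**: a latent Gaussian log-scale vector per subject with
  noise covariance $\Omega^{-1}$, mapped to µmol/l with per-metabolite
  location/scale chosen so raw-scale mean and SD approximate published
  per-metabolite values where available (e.g. Val 227 ± 53 µmol/l, hexose
  from the 5.18 mmol/l serum glucose figure) and class-typical values
  otherwise.
* **Effects**: the default effect table is the published non-obese-stratum
  standardized betas of the strongly associated single metabolites (Val
  0.14, Ile/Leu 0.13, Tyr 0.14, C5 0.14, C3 0.13, PC ae C42:3 −0.16, plus
  weaker ones down to ±0.07); BCAAs positive, lysoPCs negative, so sign
  patterns are exercised.  The FFMI effect is calibrated analytically
  (solving $c = \beta\,\sigma_x(c)$ with the population moments, including
  the FFMI–sex covariance) so that the *planted* value is exactly the
  standardized coefficient the association stage estimates; age/sex
  nuisance effects default to 0.05 so covariate adjustment matters.
  An `obeseNull` switch zeroes the effects in subjects with BMI ≥ 30,
  emulating obesity-restricted effect modification for the stratified
  tests.
* **Dependence**: within-class edges at density 0.02 with partial
  correlations drawn from ±U(0.3, 0.6); the matrix is shrunk towards the
  identity until its smallest eigenvalue clears a margin, and the *implied*
  partial correlations after shrinkage are recorded as truth.  The sparse
  default reflects how sparse estimated metabolite GGMs are (on the order
  of one edge per node) and keeps shrinkage — which would otherwise pile
  implied correlations just above the 0.3 cutoff — near zero.
* **QC stress**: reference samples (10 plates × 5 replicates) default to
  7% CV with the 19 biogenic amines and acylcarnitine C3:1 planted at 60%,
  so the CV filter removes exactly 20 metabolites and 166 remain, as in
  the cohort the pipeline emulates.  Injected outliers displace cells to
  mean ± U(6, 9) SD on the raw scale (so the ±5 SD detector must catch
  them); missingness is completely at random and disjoint from the
  outlier cells, keeping the ground-truth masks unambiguous.

What the simulator does *not* reproduce: assay nonlinearity near detection
limits, plate-position and drift artefacts, non-Gaussian biological tails,
correlated (non-MCAR) missingness, and cross-class dependence.  Passing
the recovery suites therefore shows the pipeline is correct and calibrated
under its own model, not that the model captures every feature of real
cohort data.

## The QC validation fixture

Exact recovery of the injected-outlier mask is only a well-defined target
when natural > 5 SD cells are essentially impossible, so the dedicated QC
fixture (`qcFixtureConfig()`) uses 500 subjects with 5% biological CV
(natural tails then sit near 4σ on the log scale) and displaces injected
outliers by 12–15 SD: even when several injections land on one metabolite
and inflate its sample SD by a factor of ~2, the flagged z stays above 5.
With injection rate 0.005 over 166 surviving metabolites, subjects
exceeding three independent outliers occur regularly, exercising the
subject-exclusion rule.

# Numerical and design choices

* "Inverse log-normal transformation" is read as ln-then-z-score (matches
  "standardised" and log-normal marginals); a rank-based inverse normal
  transform (Blom offset) is available for heavy-tailed traits.  Zeros are
  replaced by ε·min(positive) before the log, with a message.
* All model fitting is QR-based multi-response least squares; collinear
  designs error with the offending columns named.  p-values are computed
  on the log scale (`pt(..., log.p = TRUE)`) and stored alongside log10 p,
  so p-gains survive p-values below ~10⁻³⁰⁸.
* Eigenvalues are rounded at 10⁻⁸ before the Li–Ji floor term: an
  eigenvalue of $4 - 10^{-16}$ must count as 4, not as $3 + 1$.
* Quintile assignment ranks with ties broken by input order, so group
  sizes differ by at most one and boundary values fall to the lower
  quintile.
* Result tables are written with 6 significant digits, making repeated
  runs byte-identical; network files keep full precision.
* Weight stability keeps the boundary (≤ 0.5%/year, "did not exceed");
  the CV, missingness and outlier-count comparisons are strict.

# Validation strategy and problem sizes

The test suite validates each operation against an independent oracle
(hand-coded SD/mean loops for CVs, brute-force graph components, per-pair
regression partial correlations, closed-form arithmetic) and the pipeline
end-to-end against simulator ground truth.  The calibration suite uses 100
replicate cohorts at the default size (n = 965, 186 → 166 metabolites) for
coverage of ±2 estimated-SE intervals around the planted betas in
[0.13, 0.16] and for the type-I error of null metabolites; coverage is
assessed pooled over betas × replicates because a per-beta binomial at 100
replicates cannot distinguish the nominal 95.4% coverage of a 2-SE
interval from a 95% bar.  Network recovery pools five replicate cohorts:
sensitivity is measured on edges whose implied |ρ| ≥ 0.3 (edges drawn near
0.3 are recovered at ~50% by construction — the sample estimate sits
symmetrically around the cutoff — which the ≥ 0.9 target accommodates),
and false discoveries are detections outside the planted edge set.

# Known limitations

* The imputation is single (one completed dataset), matching the
  downstream analysis design; between-imputation variance is not
  propagated.
* The effective-tests threshold depends on the observed correlation
  matrix, so stratified thresholds vary with stratum size.
* GGM estimation requires $n > M + \text{covariates} + 3$; for smaller
  cohorts the ridge option changes the estimand (results are flagged
  regularised).
* The p-gain cutoff default (number of metabolites) is a heuristic guard,
  not a formal error-rate control.
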