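# metabnet

Quality control, metabolome-wide association and partial-correlation
networks for targeted serum metabolomics panels measured against a
continuous body-composition phenotype.

## The scientific problem

Skeletal muscle mass shapes the circulating metabolome: branched-chain
amino acids (BCAAs) rise with muscle mass during overnight fasting,
acylcarnitines track fatty-acid oxidation, and phosphatidylcholine (PC)
side-chain composition shifts with lipid turnover.  Epidemiological studies
probe this with the **fat free mass index** (FFMI = fat free mass in kg /
height in m²), a height-independent proxy for muscle mass, against a
Biocrates-style targeted panel (amino acids, biogenic amines,
acylcarnitines, PC aa/ae, lysoPC, sphingomyelins, hexose; concentrations in
µmol/l).

`metabnet` implements that analysis as a reusable, tested pipeline:

1. **Quality control** — per-plate coefficients of variation from
   replicated reference samples (metabolites with mean CV > 25% removed),
   missingness filter (> 5%), outlier flagging at mean ± 5 SD (single
   pass), the independent-outlier subject rule (subjects with more than
   three independent outlying metabolites excluded; an outlier is
   independent of another when their concentration columns correlate below
   70%), and chained-equations regression imputation.
2. **Association** — each metabolite is standardised with the inverse
   log-normal transform *z* = (ln *x* − mean ln *x*) / sd ln *x* and
   regressed on FFMI adjusted for age, sex (and batch); the significance
   threshold is α / M_eff with M_eff the eigenvalue-based effective number
   of tests (Li–Ji), or a fixed replay value such as 3.12×10⁻⁴.
3. **Ratios** — all intra-class metabolite pairs become ratio traits,
   scored with the **p-gain** = min(p_M1, p_M2) / p_ratio; a ratio is
   significant when its p-value clears the threshold *and* its p-gain
   exceeds the cutoff (default: number of metabolites after QC).
4. **Gaussian graphical model** — full-order partial correlations
   ρᵢⱼ = −ωᵢⱼ/√(ωᵢᵢωⱼⱼ) from the precision matrix of
   covariate-residualised metabolites, Fisher-z tests with Bonferroni
   correction at α = 0.01, an |r| ≥ 0.3 edge cutoff, and nodes coloured by
   association sign (red positive, blue negative, white not significant).
5. **Synthetic cohorts** — a generator that emulates the cohort's
   statistical structure (sex-specific FFMI/height/body-fat distributions,
   log-normal concentrations with class-structured partial correlations,
   planted standardized effects, batch shifts, injected outliers and
   missingness, plate-replicated reference samples) together with the
   ground truth, so every stage is testable without access to the
   restricted cohort data.

## Worked example

```r
library(metabnet)

cohort <- simulateCohort(simConfig(seed = 1))   # n = 965, p180 panel
qcd    <- runQC(cohort)
qcReport(qcd)
#> QcReport
#>   excluded metabolites: 20 (cv: 20, missingness: 0)
#>   excluded subjects:    0
#>   outlier cells:        45
#>   imputed cells:        45

res <- mwas(qcd, exposure = "ffmi", covariates = c("age", "sex", "batch"))
res[res$trait == "Val", c("beta", "se", "p", "r2_adj", "significant")]
#> DataFrame with 1 row and 5 columns
#>        beta        se           p    r2_adj significant
#> 1  0.140523 0.0171868 9.22236e-16  0.122665        TRUE
```

QC removes the 20 planted high-CV metabolites, leaving 166 (the 45 flagged
cells are natural > 5 SD tails of the log-normal marginals, set to missing
and imputed); the fitted standardized beta for valine (planted 0.14 per
kg/m² FFMI) is recovered well within one standard error and is significant
at the effective-tests threshold (3.33×10⁻⁴ here).  `ratioMwas()` then
scores the ~4,500 intra-class
ratios, and

```r
pcm <- partialCorrelations(qcd, covariates = c("age", "sex", "ffmi", "batch"))
net <- buildNetwork(pcm, testEdges(pcm, alpha = 0.01), res, r_cutoff = 0.3)
exportNetwork(net, "network.graphml")
```

builds and exports the association-coloured metabolite network.
`runPipeline()` (or the `inst/scripts/metabnet.R` command line, subcommands
`simulate | qc | associate | ratios | ggm | all`) chains everything and
writes deterministic TSV/GraphML outputs.

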