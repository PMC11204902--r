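# prscad

Replication of published polygenic scores (PGS) in a case-control genotype
panel: scoring-file harmonization, dosage-weighted score computation,
array-era quality control, Tracy-Widom-selected principal components for
population structure, and nested logistic models quantifying each score's
incremental contribution to disease discrimination. A fully seeded
synthetic-cohort generator makes the entire pipeline testable against known
ground truth without access to any private cohort.

## The science in brief

A polygenic score for individual *i* is the weighted dosage sum

    PRS_i = Σ_j  w_j · g_ij,     g_ij ∈ [0, 2]

over the variants *j* of a published scoring file. Before scoring, each
file variant must be **harmonized** to the panel's allele orientation:
effect/other vs REF/ALT may be *exact*, *switched* (weight negated),
*flipped* (opposite strand, weight kept), or *flipped-switched* (negated);
palindromic (A/T, C/G) variants are dropped as unresolvable, and variants
missing from the panel can be rescued by a nearby LD proxy (r² > 0.8
within ±500 kb). Every decision is recorded in an audit table.

Each score is then evaluated against case-control status with two nested
logistic models — **null** (covariates + PCs) and **full** (+ PRS) — and
summarized by:

* **adjusted PRS R²** = Nagelkerke R²(full) − Nagelkerke R²(null): the
  discrimination attributable to the score beyond the covariates;
* the Wald **odds ratio per SD** of the score, with 95% CI and p-value;
* **Bonferroni** significance across the family of scores (p < α/m).

Covariate sets: `model1` = sex, age, weight, type-2 diabetes; `model2`
adds smoking, systolic blood pressure and total cholesterol. The number of
PC covariates is chosen by the sequential Tracy-Widom test on the genotype
covariance spectrum. QC: sample call rate ≥ 0.95, heterozygosity within
3 SD, variant call rate ≥ 0.98, Hardy-Weinberg exact p ≥ 1e-4.

See `vignettes/prs-replication-methods.Rmd` for formulas, defaults and the
numerical choices (notably the moment-matching effective-marker estimator
behind the Tracy-Widom statistic and its calibration).

## Worked example

Simulate a cohort (924 samples, 390/924 expected case fraction, calibrated
covariates) with one causal score (planted per-SD OR 1.5) and two null
scores, each emitted with deliberate file corruption — 20% allele
switches, 10% strand flips, 10% of variants dropped from the panel with an
exact LD proxy planted — then run the full pipeline:

```r
library(prscad)

cfg <- simulationConfig(n_samples = 924, n_variants = 500, n_causal = 50,
                        per_sd_or = 1.5, seed = 42)
paths <- simulateCohort(cfg, "cohort", n_scores = 3,
                        corruption = c(allele_switch = 0.2,
                                       strand_flip = 0.1,
                                       drop_with_proxy = 0.1))
run <- runPipeline(pipelineConfig(panel = paths$vcf,
                                  phenotypes = paths$phenotypes,
                                  scores = paths$scores, ld = paths$ld,
                                  out_dir = "results"))
read.delim("results/report_model1.tsv")
```

```
            ID  model   R2 R2_null Adjusted_PRS_R2 PRS_OR  p_value
1 PGS_SYNTH_01 model1 8.1%    4.9%            3.2%  1.393 2.36e-06
2 PGS_SYNTH_02 model1 5.1%    4.9%            0.2%  1.085 2.29e-01
3 PGS_SYNTH_03 model1 5.0%    4.9%            0.1%  0.939 3.58e-01
  bonferroni_significant
1                   TRUE
2                  FALSE
3                  FALSE
```

The planted causal score is recovered (OR 1.39 per SD against a planted
1.5 at n = 924, Bonferroni-significant at 0.05/3), the null scores are
not. Individual results print as S4 objects:

```r
run$results$model1[[1]]
#> AssociationResult PGS_SYNTH_01 [model1]: R2 null 0.049 full 0.081
#>   (PRS 0.032); OR[per_sd] 1.393 (1.214-1.599), p = 2.36e-06
```

The run log shows what the pipeline did with the corrupted file — all 50
causal variants were used despite the corruption (29 exact, 10 switched
with weight reversal, 5 strand-flipped, 6 rescued through the planted
r² = 1 proxies):

```r
str(run$log$harmonization$PGS_SYNTH_01)
#> List of 4
#>  $ exact   : int 29
#>  $ flipped : int 5
#>  $ proxied : int 6
#>  $ switched: int 10
```

`results/` also contains per-variant harmonization audits, per-sample
score tables, QC reports, PC coordinates with the eigenvalue/TW report,
raw (unrounded) association tables, and a JSON run log. Running the same
configuration twice gives byte-identical outputs.

The same drive-through is available from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/prscad-cli.R", package="prscad"))') \
    simulate --out cohort --seed 42 --n-scores 3 --corrupt-switch 0.2
```

with subcommands `simulate`, `qc`, `harmonize`, `score`, `pca`, `assoc`
and `run-all` (see the script header for options).

## Testing

```r
testthat::test_dir("tests/testthat", package = "prscad",
                   load_package = "installed")
```

The suite covers every module with independent oracles (a double-loop PRS
sum, a recurrence-based exact HWE enumeration, closed-form 2×2 logistic
MLEs, complement-table harmonization), property tests (round trips,
invariances, determinism) and statistical acceptance checks
(`tests/testthat/test-acceptance.R`): type-I error of the Wald test,
planted odds-ratio recovery and CI coverage, Tracy-Widom calibration on
noise and detection under Fst = 0.05 structure, and generator
self-consistency.

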