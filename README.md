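# methaccord

Agreement analysis for the two most widely used surrogate markers of
global DNA methylation: **LINE-1 pyrosequencing** (mean % methylation of
four CpG sites in the LINE-1 retrotransposon promoter) and **LUMA**, the
luminometric methylation assay (HpaII/MspI isoschizomer digestion of CCGG
sites quantified from pyrosequencing peak heights, with
Methylation (%) = (1 − HpaII/MspI) × 100).

Both assays are routinely treated as interchangeable readouts of global
methylation, yet they interrogate different genomic compartments — LINE-1
elements sit in A+T-rich regions, HpaII sites are enriched in C+G-rich
regulatory regions.  `methaccord` implements the statistical toolbox of a
laboratory method-comparison study for this assay pair, aimed at
epigenetics labs validating biomarkers and at statisticians interested in
method-comparison workflows:

* **Quantification** — pyrogram peak heights → enzyme ratios → calibrated
  % methylation, with the published QC exclusion rules (low peaks,
  MspI/MfeI > 4.2, trailing dATP dispensation > 25 % of the first),
  replicate averaging and two-point 0 %/100 % control calibration.
* **Agreement statistics** — per-tissue descriptives, repeated-measures
  ANOVA (assay as within-, data subset as between-subject factor),
  Wilcoxon signed-rank tests, Spearman correlation with 1000-resample
  bootstrap CIs, and the Bland–Altman method: fixed bias (mean difference
  d̄ with one-sample *t* test), 95 % limits of agreement d̄ ± 1.96·SD(d),
  and proportional bias (OLS slope of the difference on the pairwise
  average).
* **Pattern analysis** — a univariate Gaussian mixture
  p(x) = Σᵢ wᵢ·N(x | Meanᵢ, SDᵢ) fitted to the Pareto density estimate of
  the interassay differences, Bayes decision boundaries between adjacent
  components, a χ² test of tissue-by-component association, and an
  entropy-impurity decision tree predicting the component from the tissue
  label, cross-validated by 100 leave-one-tenth-out repetitions.
* **Subset-specific regression** — Methylation_LINE1 =
  (Intersection + θ_Int,s) + (Slope·θ_Slope,s)·Methylation_LUMA + ε per
  data subset s, fitted by maximum likelihood and reduced by stepwise
  likelihood-ratio tests (retain a parameter iff Δ(−2LL) < −3.84), with
  stratified-bootstrap percentile CIs from 1000 refits.
* **Effect sizes** — Cohen's d for every pairwise treatment comparison
  within each cell line, under both assays, and the cross-assay Spearman
  correlation of the two effect-size profiles.
* **Calibrated synthetic data** — a generator reproducing the study
  layout (238 samples: 73 treated MCF7, 34 treated SHSY5Y, 131 human
  blood) with the published per-subset marginals, rank correlations and
  difference SDs, plus pyrogram-level records that round-trip through the
  quantification stage exactly.

## Worked example

```r
library(methaccord)

samples <- generate_samples(synth_config(seed = 1))   # 238-sample study layout
ba <- bland_altman(samples[samples$subset == "blood", ])
ba
#> Bland-Altman agreement analysis (n = 131 )
#>   fixed bias (mean difference): 20.255  [19.649, 20.860], t-test p = <2e-16
#>   95% limits of agreement:      [13.388, 27.121]
#>   proportional bias slope:      -0.264  [-0.512, -0.015], p = 0.0379
#>   normality of differences (lilliefors): D = 0.0637, p = 0.216
```

In blood, LINE-1 reads on average 20.3 percentage points higher than
LUMA — a large fixed bias; the limits of agreement say an individual
sample's two readouts can disagree by anywhere from 13 to 27 points, so
the assays are not interchangeable there even though both are valid
methylation markers.

```r
fit <- build_final_model(samples)
fit
#> Subset-specific linear model: line1 = (Intersection + theta_Int,s) + (Slope * theta_Slope,s) * luma + e
#>   Intersection (theta1): 0 (fixed)
#>   Slope        (theta2): 0.9141
#>  subset   n intercept  slope theta_int theta_slope
#>    MCF7  73     0.000 0.9141 0 (fixed)   1 (fixed)
#>  SHSY5Y  34     8.258 0.9141    8.2581   1 (fixed)
#>   blood 131    73.379 0.2642   73.3790      0.2891
#>   sigma2 = 17.03,  -2LL = 1350.095,  n = 238, parameters = 5
```

The stepwise search lands on the tissue-dependent structure: the two cell
lines share a common slope (≈0.91) but differ in intercept (MCF7 pinned
at zero, SHSY5Y ≈8), while blood follows a much flatter relation
(intercept ≈73, slope ≈0.26) — the relation between the two assays
depends on the tissue.  `fit$step_log` holds every likelihood-ratio
decision; `confint(fit)` adds bootstrap CIs.

The full pipeline (agreement → mixture/tree → regression → effects) runs
with

```r
report <- run_pipeline(pipeline_config(seed = 1), out_dir = "results")
```

or from a shell via `Rscript inst/scripts/methaccord.R all --seed 1 --out results`.

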