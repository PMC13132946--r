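# twinace

Classical twin-design variance decomposition for objective and self-evaluated
phenotypes, by full-information maximum likelihood (FIML).

## The scientific problem

How much of the variation in a trait — and in people's *self-evaluation* of
that trait — is genetic, and do the same genes drive both? The classical twin
design answers this by contrasting monozygotic (MZ) twin pairs, who share all
of their segregating genes, with dizygotic (DZ) pairs, who share half on
average. For a phenotype with additive-genetic variance A, shared-environment
variance C and unshared-environment variance E, the expected twin-pair
covariance structure is

    within twin:   V        = A + C + E
    across twins:  cov(MZ)  = A + C
                   cov(DZ)  = ½A + C

`twinace` fits this model (and its ADE variant, with dominance D replacing C)
to twin-pair tables by FIML, so that singletons and partially observed pairs
contribute their marginal normal densities. The multivariate *correlated
factors* model additionally estimates the cross-trait component covariances
under **direct symmetric parameterisation** — every unique element of A, C
and E is a free parameter, with no positivity or correlation bounds — giving
the genetic correlation

    r_g = A21 / sqrt(A11 · A22)

and the contribution of each component to a phenotypic correlation r_p,

    bivariate A = sqrt(a1) · r_g · sqrt(a2) / r_p

(on standardized components; identically for C and E). Because components are
unbounded, estimated component correlations can exceed 1 at boundaries; they
are reported verbatim with a boundary flag plus a capped display value.

The package targets studies of singing ability and singing self-evaluation —
an objective singing phenotype index (SPI) alongside a factor-score (SSE-Factor)
and a single 1–7 item (SSE-Single) self-evaluation — but every function is
generic over traits.

It provides:

- `read_twin_table()` / `write_twin_table()` — delimited one-row-per-twin IO
  with validation, winsorization of training years, and explicit missingness;
- `ace_model_spec()`, `saturated_spec()` and constraint verbs
  (`drop_component()`, `drop_component_for()`, `fix_component_correlation()`,
  `equate_params()`) — the model algebra behind every nested submodel;
- `fit_twin_model()`, `likelihood_ratio_test()`, `aic()`, `profile_ci()`,
  `profile_share_ci()` — FIML fitting and inference;
- `run_assumption_ladder()` — the saturated-model equality ladder across twin
  order, zygosity and sex at α = 0.01;
- `intraclass_correlation()`, `ctct_correlation()`, `select_model_family()`,
  `standardize_components()`, `genetic_correlation()`,
  `bivariate_contributions()`, `decompose_fit()` — derived quantities;
- `twin_sim_config()` / `twin_sim_preset()` / `simulate_twin_data()` — a
  generative simulator with the study composition built in;
- `run_twin_analysis()` / `write_report()` — the full pipeline with
  CSV/JSON/log report output;
- `tidy()`/`glance()` methods and `autoplot()`/`plot_twin_correlations()`
  graphics.

## Worked example

Simulate a study-shaped dataset (335 MZ pairs, 118 DZ pairs, 90 singletons;
generating components taken from published univariate estimates) and run the
complete analysis:

```r
library(twinace)

d <- simulate_twin_data(twin_sim_preset(), seed = 2026)
twin_counts(d)
#>   n_mz_pairs n_dz_pairs n_singletons
#> 1        335        118           90

rep <- run_twin_analysis(d, ci = FALSE, seed = 1)
rep
#> Univariate estimates (table 1):
#>        trait family     A     C     E icc_mz icc_dz minus2LL EP n_pairs     D
#> 1        SPI    ACE 33.47 43.03 23.50   0.77   0.61  2436.59  6     543    NA
#> 2 SSE_Factor    ACE 48.71 23.84 27.45   0.73   0.49  2514.66  6     543    NA
#> 3 SSE_Single    ADE 50.36    NA 27.89   0.70   0.34  2554.89  6     543 21.75
#>
#> Model comparison (table 2):
#>   model EP minus2LL   df      AIC delta_m2ll delta_df     p
#> 1   ACE 27 5870.559 2691 5924.559         NA       NA    NA
#> 2    AE 21 5888.765 2697 5930.765     18.206        6 0.006
#> 3    CE 21 5941.889 2697 5983.889     71.330        6 0.000
#> 4     E 15 6495.741 2703 6525.741    625.182       12 0.000
#>
#> Decomposition (table 3):
#>      trait_i    trait_j  r_p pct_A pct_C pct_E  r_g  r_c  r_e ctct_MZ ctct_DZ
#> 1        SPI SSE_Factor 0.66 37.48 47.25 15.27 0.61 0.98 0.40    0.56    0.45
#> 2        SPI SSE_Single 0.58 49.28 39.52 11.20 0.56   NA 0.26    0.51    0.39
#> 3 SSE_Factor SSE_Single 0.70 56.90 27.39 15.71 0.64   NA 0.40    0.58    0.41
```

Reading the output: the univariate rows give each trait's standardized A/C/E
shares in percent with the MZ/DZ intraclass correlations that motivated the
model family — note that for `SSE_Single` this replicate's DZ correlation fell
below half the MZ value, so the `r_MZ < 2 r_DZ` decision rule selected an ADE
model (the D column) for that trait, exactly as the rule is meant to operate on
sampled data. The model-comparison table shows that dropping C (AE), A (CE) or
both (E) from the trivariate correlated-factors model significantly worsens
fit (all likelihood-ratio p < 0.01), and the AIC column satisfies
AIC = −2LL + 2·EP row-wise. The decomposition table gives, per trait pair, the
model-implied phenotypic correlation, the percent of it carried by the A, C and
E cross-paths (summing to 100), the component correlations, and the
cross-twin cross-trait (CTCT) correlations by zygosity; an `NA` component
correlation arises when a fitted component variance is negative — legitimate
under direct symmetric parameterisation — and is flagged as a boundary case.

`write_report(rep, "out/")` writes `table1_univariate.csv`,
`table2_model_comparison.csv`, `table3_decomposition.csv`, `report.json` and
`analysis_log.txt`.

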