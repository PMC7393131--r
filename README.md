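# radiometab

Metabolite pathway correlates of radiosensitivity in glioblastoma models.

Glioblastoma (GBM) cell lines span a wide range of intrinsic resistance to
radiation therapy, and that phenotype tracks with their metabolite pools.
`radiometab` is an R package for the full computational chain behind that
kind of study, for analysts working with targeted LC-MS/MS metabolite panels
and radiation-response assays:

1. **Radiosensitivity quantification** — surviving fractions from clonogenic
   colony counts, constrained linear-quadratic fits
   (SF(d) = exp(−(αd + βd²)), α, β ≥ 0), the mean inactivating dose
   **Dmid = ∫₀^dmax SF(d) dd** (area under the linear-scale survival curve;
   larger = more resistant), enhancement ratios
   **ER = Dmid(control)/Dmid(treatment)** (ER > 1 = radiosensitization), and
   GI50-based ER for viability assays.
2. **Panel QC** — detection threshold (mean replicate-group area ≥ 3000 ion
   counts) and reproducibility filter (replicate CV ≤ 0.5), sample
   normalization, fold changes, stable-isotope fractional enrichment.
3. **Pathway discovery** — per-metabolite z-transform across cell lines,
   up/down regulation calls at z > +1 / z < −1, per-pathway scores
   (fraction of measured metabolites regulated), Pearson correlation of
   pathway scores with radiosensitivity (sensitivity = −Dmid), two-sided p
   from t(n−2), Benjamini–Hochberg FDR across pathways.
4. **Endpoints** — caliper volumes (π/6)·L·W², day-1 normalization, LOCF
   imputation, tumor tripling time (earliest measured day ≥ 3× baseline,
   censored if never reached), Kaplan–Meier curves, log-rank (Mantel–Cox)
   tests, univariate Cox hazard ratios, and median-split survival analysis
   of expression-annotated cohorts.
5. **Synthetic data** — generators with recorded ground truth for every
   input (coupled metabolite panels, Poisson clonogenic counts, exponential
   tumor growth and survival cohorts), so the whole pipeline is testable by
   parameter recovery with no external data.

The statistical procedures (Pearson r/p, pooled/Welch t-tests, Holm–Šidák,
BH FDR, Kaplan–Meier, log-rank, Cox with Breslow ties) are implemented from
their defining formulas; the test suite verifies them against independent
oracles (`cor.test`, `t.test`, `p.adjust`, the `survival` package, hand
enumeration and grid search).

See `vignettes/radiometab-methods.Rmd` for the model assumptions, parameter
defaults, numerical choices and known limitations.

## Worked example

```r
library(radiometab)

# a 23-line panel whose guanylate pathway is coupled to radiosensitivity
sim <- simulate_metabolite_panel(seed = 1)          # r_true = 0.8
qc  <- qc_filter(sim$panel)                          # 3000-count / CV 0.5 QC
zm  <- z_transform(panel_line_means(qc$panel))
scores <- pathway_scores(regulation_calls(zm, -1, 1), default_pathway_map())
corr <- correlate_pathways(scores, sim$resistance, direction = "up")
corr[order(corr$p), ]
#>            pathway direction  n       r        p      q significant
#> 1       guanylates        up 23 -0.6664 0.000516 0.0031        TRUE
#> 6 nucleotide_sugar        up 23  0.4861 0.018686 0.0561        TRUE
#> 3       inosinates        up 23 -0.2849 0.187694 0.3754       FALSE
#> ...
```

The planted pathway is recovered: its up-score has the strongest correlation
(r = −0.67, q = 0.003).  The sign is negative because the correlation is
reported against the sensitivity orientation (−Dmid): guanylate-high lines
are the radioresistant ones.  (`nucleotide_sugar` at q = 0.056 is a false
positive at this seed — with 12 tested families, occasional q < 0.1 noise
hits are expected.)

```r
# radiosensitivity from a clonogenic assay (Poisson counts, true alpha 0.2)
assay <- simulate_clonogenic_assay(alpha = 0.2, beta = 0.05, seed = 42)$assay
fit_survival_curve(assay)
#> LQ survival curve: alpha = 0.2351 /Gy, beta = 0.03928 /Gy^2,
#>   Dmid(fitted) = 2.539 Gy, Dmid(trapezoid) = 2.603 Gy

# enhancement ratio of a radiosensitizer that raises alpha 0.2 -> 0.35
er <- enhancement_ratio(dmid(0.2, 0.05, 8), dmid(0.35, 0.05, 8))
sprintf("ER = %.3f (%s)", er$er, er$classification)
#> "ER = 1.298 (radiosensitization)"
```

`run_pipeline(run_config(), inputs, out_dir)` drives the whole chain from
files to result tables plus a manifest (config, input checksums, version)
that makes the run byte-reproducible.  A thin command-line wrapper with
`simulate | qc | score | fit-survival | endpoints | run` subcommands is
installed at `inst/cli/radiometab.R`.

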