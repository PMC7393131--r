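---
title: "Methods: from metabolite panels to radiosensitivity correlates"
author: "radiometab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from metabolite panels to radiosensitivity correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiometab)
```

## The problem

Glioblastoma (GBM) cell lines differ widely in intrinsic radiosensitivity.
`radiometab` implements the computational chain that connects a targeted
LC-MS/MS metabolite panel measured across a cell-line collection to that
phenotype: quantify radiosensitivity per line, score per-pathway metabolite
regulation per line, correlate the two under false-discovery-rate control,
and carry the downstream treatment questions into in-vivo and clinical
endpoint statistics (tumor tripling time, survival curves, hazard ratios).

All inputs are long-format CSV/TSV tables with declared schemas
(`table_schemas()`), and a synthetic-data module generates every one of them
with recorded ground truth, so each stage is testable by parameter recovery
without any external data.

## Quantifying radiosensitivity

**Surviving fractions.** A clonogenic assay plates a known number of cells at
each radiation dose and counts the colonies they form.  With plating
efficiency $PE$ = mean(colonies/cells plated) at dose 0, the surviving
fraction at dose $d$ is
$SF(d) = \overline{\text{colonies}(d)/\text{plated}(d)} / PE$, so
$SF(0) = 1$ by construction.

**Linear-quadratic fit.** The field-standard parameterization
$SF(d) = \exp(-(\alpha d + \beta d^2))$ is fitted by least squares on
$\ln SF$ subject to $\alpha, \beta \ge 0$.  Because the problem has only two
parameters, the non-negative least-squares solution is computed exactly: the
unconstrained normal-equations solution is used when feasible, otherwise the
best boundary fit ($\alpha = 0$, $\beta = 0$, or both) by residual sum of
squares.  `fit_lq()` is unweighted by default; `fit_survival_curve()` weights
each dose by its total observed colony count, the inverse-variance weight for
log-transformed Poisson counts.  Without the weights the nearly-empty
high-dose plates (a handful of colonies at 8 Gy) dominate the log-scale
residuals and roughly double the error of $\hat\alpha$; with them the
estimator is near the Poisson maximum-likelihood information limit, which we
verified by comparing against a Poisson regression fit on simulated assays.

**Dmid.** Radiosensitivity is summarized as the mean inactivating dose: the
area under the survival curve on a *linear* SF axis,
$D_{mid} = \int_0^{d_{max}} SF(d)\,dd$.  Two estimators are provided and the
run manifest records which was used: `fitted` integrates the LQ curve by
adaptive quadrature (absolute tolerance 1e-8), `trapezoid` integrates the
measured points model-free.  The integration range defaults to the maximum
assayed dose (8 Gy in the assays this pipeline is designed around); larger
Dmid = more radioresistant.  On noiseless LQ curves sampled every 0.5 Gy the
two estimators agree within 2%; at 1-2 Gy spacing the trapezoid rule
overestimates steep curves ($\alpha \gtrsim 0.4$/Gy) by slightly more than
2%, which is ordinary discretization error, so dense dose grids are preferred
when the model-free estimate matters.

**Enhancement ratio and GI50.** A radiosensitizer (or protector) is scored as
$ER = D_{mid}(\text{control}) / D_{mid}(\text{treatment})$; $ER > 1$ is
radiosensitization, $ER < 1$ radioprotection, equality within 1e-6 neutral.
For viability-based neurosphere assays the analogous ratio uses GI50, the
dose at which viability first crosses 50% of the unirradiated value, found by
linear interpolation between the bracketing measured doses.  Interpolation
was chosen over a 4-parameter logistic because it is assumption-free and
exactly testable; there is no extrapolation — a curve that never reaches 50%
raises a not-reached error rather than guessing.

## Panel quality control

Targeted LC-MS/MS panels are preprocessed with two filters applied per
(metabolite, cell line, condition) replicate group:

* **detection threshold** — the group is set missing when its mean area falls
  below `min_ion_area` (default 3000 ion counts);
* **reproducibility** — the group is set missing when its coefficient of
  variation sd/mean exceeds `max_cv` (default 0.5).  The sample standard
  deviation (denominator $n-1$) is used; a group with a single replicate
  cannot be assessed and passes the CV check.

The mean-area reading of the detection threshold (a group either passes
whole or is wholly missing) treats it as a detection limit rather than a
per-replicate censor.  A metabolite missing in more than `max_missing_frac`
(default 50%) of its groups is dropped entirely — this drop rule is this
package's own convention.  Every removal is written to a QC report with its
reason, and the filter is idempotent.

Sample normalization is exposed (`none`, `total_signal`, `median`,
`reference_sample`) with `none` the default, because the acquisition-side
normalization basis of a deposited panel (cell number, protein, total ion
current) is typically not recoverable from the table itself; the chosen
method and per-sample factors are logged.  Stable-isotope tracing tables are
summarized as the raw labeled fraction
$\sum_{k \ge 1} A_{M+k} / \sum_{k \ge 0} A_{M+k}$ with **no**
natural-abundance correction, matching how raw labeled fractions are usually
quoted; corrected enrichment is out of scope.

## Pathway scoring and correlation

The discovery computation standardizes each retained metabolite across cell
lines (z-transform: mean 0, sample sd 1, denominator $n-1$; zero-variance
metabolites are dropped, never emitted as $z = 0$), then calls a metabolite
**down**-regulated in a line when $z < -1$ and **up** when $z > +1$.  The
thresholds are strict inequalities: a z-score of exactly $\pm 1$ is "none".
Per (pathway, line), the down- and up-scores are the fractions of the
pathway's *measured* metabolites called down or up, so missingness changes
the denominator rather than silently counting as "none".

Each pathway's score vector is then Pearson-correlated with the
radiosensitivity of the lines.  Two orientations of the phenotype exist in
practice; we fix **resistance score = Dmid** and **sensitivity = -Dmid**, and
report the sensitivity-oriented correlation by default, storing the
orientation with every result.  Two-sided p-values come from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, and q-values from
Benjamini-Hochberg step-up.  The down- and up-score families are adjusted
separately (direction is an argument), since down-regulation correlations
are typically reported as their own family; pathways whose score vector has
zero variance are reported with missing r and excluded from the family.

The post-irradiation variant runs the same cascade on treated/control fold
changes.  Fold changes are log2-transformed before standardization so up- and
down-regulation are treated symmetrically (a raw ratio of 2 and of 0.5 are
equidistant from no change); this is a documented choice, as is the unit of
analysis (`cell_line_mean` by default, `replicate` optionally, since with
only a handful of post-irradiation lines the effective n of the correlation
is materially different under the two readings — neither unit is claimed to
reproduce any particular published p-value).

Under a global null (all metabolites independent noise, 23 lines, 30
pathways, 1000 simulations — the sizes the acceptance suite runs), the
pathway-level test rejects at $p < 0.05$ at rate ~0.052 and BH at 0.1 yields
a family-level false-discovery probability ~0.11; with one pathway coupled
at $r = 0.8$ across 23 lines, that pathway ranks first by $|r|$ with
$q < 0.1$ in 98/100 seeds.

## In-vivo and clinical endpoints

* **Caliper volume** $(\pi/6) L W^2$ (mm³), with length the larger dimension
  (reversed inputs are swapped with a warning).
* **Day-1 normalization** to 100% at the first measured day of each series.
* **LOCF** imputation fills bioluminescence time points after euthanization
  with the most recent observed value, flagging imputed points and never
  altering observed ones.
* **Tripling time** is the earliest *measured* day a tumor reaches at least
  3x its first-day value (inclusive boundary, no interpolation between
  measurement days).  Animals never reaching 3x are censored at their last
  measured day; censoring, rather than exclusion, keeps the risk set honest
  when a death precedes tripling, and is this package's documented choice.
  "First day of treatment" is identified with the first measured day, since
  measurement begins at randomization.
* **Arm comparison** uses the Kaplan-Meier estimator per arm with all
  pairwise log-rank tests.
* **Median-split survival** stratifies subjects at the median expression
  value; ties go to the *low* group, matching a strictly-greater-than-median
  definition of "high".  Output is the KM curves, log-rank p, and the
  univariate Cox hazard ratio (high vs low) with a Wald 95% CI.

The survival machinery itself (`km_curve`, `logrank_test`, `cox_univariate`,
`pearson_r_p`, `ttest_unpaired`, `holm_sidak`, `bh_fdr`) is implemented
directly from the defining formulas so that agreement with independent
oracles is a testable property; the test suite cross-checks against
`survival::survfit/survdiff/coxph` and base `cor.test/t.test/p.adjust`, but
those libraries are never the implementation.  Conventions where references
differ: Breslow handling of tied event times in the Cox fit; events precede
censorings at tied times in risk sets; KM median = smallest event time with
$S(t) \le 0.5$ ("not reached" when the curve stays above 0.5); Newton
convergence tolerance 1e-8 with at most 50 iterations and an explicit
monotone-likelihood (complete separation) error rather than a runaway
estimate; the pooled-variance Student t-test is the default (`welch`
available) because "unpaired t-test" without qualification usually means the
pooled form.

## What the synthetic data emulate — and what they do not

Each generator is a pure function of its parameters and seed, and its
defaults are the study conditions the package is tested at:

* **Panel** (`simulate_metabolite_panel`): 23 cell lines; per-line Dmid
  uniform on 2-6 Gy (the span a GBM panel assayed to 8 Gy typically covers);
  one coupled pathway whose metabolite log-levels follow
  $r\,s + \sqrt{1-r^2}\,\varepsilon$ against the standardized Dmid $s$
  (population correlation exactly $r$, default 0.8); all other metabolites
  independent; triplicate measurements with lognormal noise (sd 0.1 on the
  log scale) on a baseline of 5e4 ion counts, comfortably above the
  detection threshold.
* **Clonogenic** (`simulate_clonogenic_assay`): colonies ~
  Poisson(plated · PE · $SF_{LQ}(d)$), PE 0.8, 500 cells plated, triplicates
  at 0/2/4/6/8 Gy.
* **Growth** (`simulate_growth_cohort`): exponential volume growth with
  multiplicative lognormal noise, 10 animals/arm from 90 mm³, measured three
  times weekly.
* **Survival** (`simulate_survival_cohort`): exponential event times, 42-day
  baseline median, group hazard ratio (default 0.6 on the high-expression
  group of a 208-subject cohort), administrative censoring, optional
  group-separated expression values for the median-split analysis.

These generators reproduce the *statistical structure the analysis assumes*
— which is exactly what makes them sharp tools for parameter recovery — and
deliberately omit much of what real data contain: batch and run-order
effects, heteroscedastic and correlated metabolite noise, heavy-tailed
measurement error, non-exponential growth and survival, informative
censoring, and misannotated pathway membership.  A passing recovery suite
therefore demonstrates that the pipeline correctly extracts the signal it
models, not that the model captures every property of laboratory data.

## Numerical and reproducibility choices

Quadrature: `stats::integrate` with absolute tolerance 1e-8.  LQ fit:
exact 2-parameter non-negative least squares (no iterative optimizer, no
starting-value sensitivity).  Zero surviving fractions are excluded from the
log-scale fit with a warning.  Degenerate inputs error loudly (zero plating
efficiency, constant expression at the median split, zero-variance
correlation inputs) rather than returning conventional values, except where
a convention is standard and stated (t = 0, p = 1 for identical constant
groups; log-rank p = 1 with zero events).  Tables are written with integers
exact and floats at 6 significant digits, missing values as empty fields, so
identical runs are byte-identical; the run manifest embeds the full
effective configuration, input checksums and package version, and suffices
to re-run the pipeline.

Problem sizes used by the tests and the acceptance script — 200 random
panels for oracle equivalence, 1000 global-null panels, 100 recovery seeds,
100 clonogenic fits, 500 Cox cohorts at n = 208 — were chosen to keep Monte
Carlo error well inside the asserted bands while completing in a few minutes
on one CPU.

## Known limitations

Single-membership pathway annotation only (a metabolite mapped to two
pathways is an error, matching vendor-style annotation); no rank-based
metabolite-set enrichment; no multivariable or stratified survival models;
no dose-rate or repair-kinetics survival models; no isotopic
natural-abundance correction; no batch correction.  The bundled pathway map
is synthetic and illustrative — real analyses should supply their own
annotation table.
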