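---
title: "Flavonoid permeability analytics and QSPR modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flavonoid permeability analytics and QSPR modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavperm)
library(dplyr)
```

## The problem

Flavonoids are plant polyphenols with broad bioactivity whose usefulness as
nutraceuticals is limited by poor intestinal absorption, and absorption
varies strongly with substitution pattern (hydroxylation, methoxylation,
glycosylation).  The standard in vitro surrogate for intestinal absorption
is the Caco-2 cell monolayer grown on a permeable transwell insert: compound
is dosed on the apical (A) or basolateral (B) side and its appearance on the
other side gives the apparent permeability coefficient

$$P_\mathrm{app} = \frac{\Delta Q / \Delta t}{A \, C_0}\quad[\mathrm{cm/s}],$$

with $\Delta Q/\Delta t$ the appearance rate in the receiver chamber, $A$
the insert area and $C_0$ the initial donor concentration.  flavperm
implements the full analysis around such a dataset: bidirectional transport
analytics, cellular-accumulation analytics, solvent-stability and
mass-balance quality control, and a quantitative structure–permeability
(QSPR) modelling engine that relates $-\log_{10} P_\mathrm{app}$ (written
pPapp) to four molecular descriptors.  The package ships a transcription of
a published 30-flavonoid study (`load_study("fang2017")`) in which all of
these quantities are tabulated, so every stage can be exercised on real
printed data, and seeded generators (`sim_qspr_study()`,
`sim_transport_assay()`) that produce data with the same statistical
structure for testing.

## Transport analytics

The efflux ratio $\mathrm{ratio}_p = P_\mathrm{app}(B\to A) /
P_\mathrm{app}(A\to B)$ summarizes directionality.  `classify_transport()`
maps it onto a mechanism class using three literature cut-offs:

* ratio in the closed band [0.8, 1.5] — **passive** diffusion;
* ratio strictly above 2.0 — **efflux_implicated** (apically directed
  active transport);
* ratio at or below 0.5 — **preferential_absorptive**;
* anything else — **indeterminate**.

Two boundary choices are deliberate.  First, the unnamed gaps (0.5, 0.8)
and (1.5, 2.0] are *not* forced into a named class: quercetin's ratio of
1.84 is exactly the kind of value that the transport literature treats as
unresolved, and the classifier says so.  Second, the absorptive bound is
inclusive (≤ 0.5) rather than strict: ratios are reported to two decimals,
so a compound tabulated at 0.50 (glycitein here) belongs to the
low-ratio group its study placed it in; an exclusive bound would
misclassify every compound sitting exactly on the printed boundary.
Ratios are computed from replicate-mean Papp values, matching how such
tables are built, not per-replicate and then averaged.

Cellular accumulation (CA, µmol per g of cellular protein) gets the same
treatment: `accumulation_ratio()` for the B→A/A→B ratio, and
`compare_ca_directions()` for a two-sided *pooled-variance* Student t-test
between directions (pooled rather than Welch because that is the test the
assay convention prescribes for small equal-size replicate groups).
`correlate_papp_ca()` quantifies the (lack of) association between how
fast a compound crosses the monolayer and how much of it the monolayer
retains; on the packaged study both directions give $R^2 < 0.02$.
Compounds whose accumulation is coded `ND` (not detected) or `NT` (not
tested) are excluded from all statistics — the two codes are kept distinct
throughout and are never silently treated as zero.

## Stability and quality control

`relative_concentration()` expresses a compound's chromatographic peak
area in assay buffer relative to methanol (percent; values above 100% are
legal).  `classify_stability()` uses the two stated cut-offs — stable at
or above 50%, unstable below 40% — and labels the unaddressed [40, 50)
band `questionable` rather than inventing a rule for it.
`mass_balance_recovery()` totals receiver, donor and cellular compartments
against the dose; the acceptance gate (default 60%) is a configurable
argument of `stability_summary()`.  `qc_monolayer()` encodes the
monolayer-integrity gate: TEER strictly above 600 Ω·cm² and Lucifer yellow
flux strictly below 0.5×10⁻⁶ cm/s, with each violated gate named in the
verdict.

## The QSPR engine

The response is pPapp(A→B); the four descriptors are the atomic partial
charge on carbon 3′ of the B ring (`QC3p`, e), a solvation-energy
descriptor (`E_sol`), a surface-area descriptor (`SlogP_V3`, the van der
Waals surface area of atoms with atomic logP contribution in a fixed bin)
and the hydrophobic integy moment (`vsurf_ID1`).  Descriptor values are
consumed as data; computing them from structures is out of scope.

The workflow is:

1. **Correlation screening** — `correlation_matrix()` over response and
   descriptors (errors on constant columns, requires complete cases).
2. **Collinearity filtering** — `filter_collinear()` greedily resolves
   inter-descriptor pairs with |r| above 0.7 (default), dropping the
   member with the weaker absolute correlation to the response, ties
   broken alphabetically, until no violation remains.
3. **Stepwise selection** — `stepwise_select()`, forward with backward
   elimination on partial-F p-values with the classic SPSS thresholds
   (enter 0.05, remove 0.10, both configurable).  For a single added term
   the partial F is the square of its t statistic, so the coefficient
   t-test p-value is used.  Ties break on lowest p then alphabetically,
   making the procedure fully deterministic.
4. **Fitting** — `qspr_fit()`, OLS (via QR / `lm`) or univariate NIPALS
   PLS.  PLS autoscales descriptors and response (mean 0, variance 1)
   before extracting components and back-transforms the coefficients, so
   both methods yield a plain linear equation
   `intercept + sum(coefficient × descriptor)`.  With all components
   retained on a full-rank matrix PLS equals OLS (asserted in tests to
   1e-8); truncating components is the regularization.  OLS is the default
   reproduction path because it is deterministic and maximizes in-sample
   R² among linear models in the same descriptors; when a PLS component
   count is not given it is chosen to maximize the leave-one-out Q²,
   standard chemometric practice.
5. **Validation** — `loo_q2()` (leave-one-out: PRESS and
   $Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$, with the conventional
   reliability gate $Q^2 > 0.5$), `rmse()`, and `validate_external()`
   ($R^2_\mathrm{pred}$ referenced to the *training-set mean*, the
   standard external-validation convention, plus test RMSE).
6. **Outlier screening** — `screen_outliers()`: one fit on all candidates,
   exclusion of compounds with signed residual above 0.600 pPapp units,
   one refit.  The rule is deliberately a single pass (a compound whose
   residual rises above the threshold only after the refit is retained)
   and one-sided: a large positive residual means the measured
   permeability is far lower than the structure predicts — the signature
   of assay instability or degradation, which is what the screen is for.

On the packaged training set (22 compounds) the stepwise procedure selects
all four descriptors (the solvation term enters last at p = 0.045) and OLS
gives R² = 0.881, Q² = 0.809 and training RMSE = 0.141 — the worked
example in the README prints these.  Note that `run_pipeline()` applies
the outlier screen only on request (`outlier_screen = TRUE`): the packaged
descriptor table is already post-screening (two unstable compounds were
removed before the tabulated split was made), so re-screening is not part
of reproducing it.

## The synthetic generator

`sim_qspr_study()` draws descriptors from a multivariate normal whose
marginal means/SDs default to the empirical moments of the packaged
descriptor table and whose correlation target defaults to its reported
Pearson block, then generates
`ppapp = 4.715 + 1.358·QC3p + 0.059·E_sol + 0.020·SlogP_V3 +
0.056·vsurf_ID1 + N(0, noise_sd)` with `noise_sd = 0.141` (the training
RMSE of the packaged fit) and a 22/6 training/test split.  These defaults
are the study conditions; they are not tuned per test.
`sim_transport_assay()` generates replicate receiver rates under
sink-condition linear flux with *multiplicative* Gaussian noise (CV-based,
because chromatographic quantification error scales with signal, whereas
pPapp noise is additive on the log scale).  Assay defaults mirror the
transwell geometry: 1.12 cm² insert, 40 µM dosing, 60 min, 0.4/1.95 mL
chamber volumes.

What the generator does *not* emulate: non-linear (non-sink) flux — it
refuses parameter combinations where the receiver would exceed 10% of the
dose, which at 60 min means truly high-permeability compounds must be
simulated with shorter incubations than the laboratory protocol used;
saturable efflux kinetics; metabolism; correlated replicate errors; and
non-Gaussian descriptor distributions (the real `SlogP_V3` column is
bimodal — 0 for most aglycones, ~21–42 for glycosides and flavonols).
Passing tests on synthetic data therefore demonstrate correctness of the
estimators under the stated model, not robustness to those real-data
features; that is what the packaged-study checks are for.

## Numerical choices and degenerate inputs

* Papp is held in cm/s internally; files and reports use the display scale
  1e-6 cm/s.  Conversions to pPapp are exact `-log10` / `10^-` pairs.
* OLS refuses rank-deficient designs (classed singularity error) rather
  than silently dropping terms; PLS refuses component counts above the
  rank of the autoscaled matrix, and a leave-one-out fold that becomes
  singular names the offending fold.
* Autoscaling refuses constant columns and a constant response.
* The direction t-test returns `unevaluable` (not an error) below two
  replicates per side, and p = 1 for identical constant samples.
* All random procedures (`sim_*`) take an explicit integer seed and are
  bit-reproducible; the package default is 20171129.
* Reported tables round to the source's printed precision (2 decimals for
  Papp ×10⁻⁶ and ratios, 3 for pPapp and descriptors); full precision is
  kept internally.

Test problem sizes were chosen to keep the whole suite fast while leaving
no estimator untested at realistic scale: leave-one-out oracles run at
n ≤ 12, null and scrambling simulations use 50–100 seeds, coverage and
recovery simulations 20 seeds at n = 200, and the type-I-error check of
the direction t-test 1000 null replicates at n = 3 per arm.

## Known limitations

* The classifier bands, stability cut-offs and QC gates are literature
  conventions, not estimated quantities; compounds near a printed boundary
  inherit the two-decimal rounding of their inputs.
* $R^2_\mathrm{adj}$ and F are reported with k = number of descriptors
  (OLS) or components (PLS); other software sometimes reports PLS F on
  different degrees of freedom, so cross-package comparisons of F are not
  meaningful.
* `screen_outliers()` is intentionally not iterated; users wanting
  iterative trimming should call it repeatedly and justify doing so.
* The packaged dataset reflects its printed source exactly, including its
  few internal rounding inconsistencies; tests that touch those entries
  check agreement at the precision the printed inputs support.
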