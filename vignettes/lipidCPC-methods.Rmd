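---
title: "Compositional feature selection for MRM-profiling lipidomics: methods and design"
author: "lipidCPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional feature selection for MRM-profiling lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`lipidCPC` implements a complete analysis chain for flow-injection
MRM-profiling lipidomics of mouse epidermis, built around a murine
dermatitis model: SHARPIN-deficient *cpdm* mice develop a chronic
proliferative dermatitis resembling human atopic dermatitis, and their
epidermal lipid profile changes with sex, genotype and disease stage.  The
chain is:

1. **Extraction** — SRM chromatograms are read from mzML files and
   aggregated into a samples x transitions intensity matrix
   (`extractIntensities()`), with sample identity and metadata taken from a
   manifest, never from file names.
2. **Compositional preprocessing** — flow-injection MRM intensities carry
   only relative information, so each sample is closed to a unit-sum
   composition (`closeComposition()`), zeros are imputed
   (`replaceZeros()`), and the data are mapped to unconstrained coordinates
   by the centered or isometric log-ratio transform (`clr()`, `ilr()`).
3. **Compression** — each annotated lipid category is treated as its own
   subcomposition and compressed by SVD into compositional principal
   components ("CPC" features) retaining 95% of the category variance
   (`compressCategories()`).
4. **Two-tier selection** — a univariate filter (per-feature linear models
   with eta-squared effect sizes and Benjamini-Hochberg adjustment,
   `fitFeatureModels()`) followed by an elastic-net wrapper
   (`trainEnet()`) that ranks the survivors by the absolute value of their
   penalized coefficients.
5. **Evaluation** — leave-one-out class predictions feed an accuracy with
   exact binomial confidence interval and unweighted/weighted Cohen's
   kappa (`classificationMetrics()`).

A first-class synthetic-data generator (`simulateLipidomics()`) emulates
the study design so that every stage has a fully reproducible, no-download
test surface.

# The data model

The central container is the `IntensityMatrix`, a `SummarizedExperiment`
with transitions in rows (annotated by a `TransitionTable`: precursor and
product m/z, polarity, collision energy, tentative attribution, lipid
category) and samples in columns (sex, genotype, age in weeks, and ordinal
disease stage; the stage is `"control"` exactly for wild-type samples).
The stage ordering control < non-lesional < established < advanced is
total, and maps to ages of 5, 7 and 10 weeks in the mutant genotype.

Ten category labels are allowed, several of them deliberately overlapping
(e.g. "phospholipid-or-glycerolipid"): a single MRM transition cannot
always attribute an ion uniquely, and the label set models that
uncertainty honestly rather than forcing a guess.

# Extraction choices

The in-house integration scheme of the original acquisition pipeline is
not published, so the extractor exposes the aggregation statistic as a
parameter: `sum` of all chromatogram intensity points over the injection
window (default — robust for flow-injection plateaus, no chromatographic
peak exists), with `mean` and `max` available.  Q1/Q3 matching tolerances
default to 0.5 Th, appropriate for a unit-resolution triple quadrupole;
two chromatograms matching one transition within a single file indicate an
over-wide tolerance and are treated as an error rather than silently
summed.  A transition with no matching chromatogram in any of a sample's
files yields 0 with a warning.  When several files of one sample carry the
same transition, their values are summed, since methods are disjoint by
design and duplication indicates reinjection.

# Compositional preprocessing

**Zero replacement.**  Log-ratios are undefined at zero.  The default is
multiplicative replacement: each zero becomes
`delta = 0.65 * min(positive values of that part)`, and the nonzero parts
of the row are rescaled so the row still sums to one.  This is standard
practice in compositional omics; a simple pseudocount is available for
comparison.  Parts that are zero in every sample cannot be imputed and are
dropped with a warning.

**CLR vs ILR.**  The source analyses mention both transforms without
assigning them to specific steps.  The package defaults to CLR for
feature-level work, because CLR coordinates keep a one-to-one
correspondence with ions (essential for interpreting per-ion effect sizes
and importance scores) and because the visualization-oriented
standardization step is explicitly defined on the centered log-ratio
scale.  ILR (with the pivot / sequential-binary-partition basis, recorded
in the output metadata) is offered for distance-based work; ILR and CLR
coordinates have identical Euclidean geometry, which the tests verify.

**Per-category closure.**  Before compression, each category is re-closed
as its own composition.  The alternative — slicing a single global CLR —
is available (`globalClr = TRUE`) and flagged in the result.  Re-closure
matches the idea of compressing each category sub-dataset independently.

# CPC compression

`fitCPC()` column-centers the log-ratio matrix and computes the SVD.
Centering is applied even though the upstream description does not mention
it: without centering, "variance fractions" conflate the mean with the
spread and are not comparable across categories.  No per-ion scaling to
unit variance is applied — compositional PCA operates on the log-ratio
covariance, and per-ion scaling would distort the closure geometry.  The
component count per category is the smallest k whose cumulative variance
fraction reaches the 95% target.  A deterministic sign convention (the
largest-magnitude loading of each component is positive) makes CPC
features reproducible across runs and platforms.  Feature names follow the
"<category> CPC <j>" scheme.

# Univariate filtering

One OLS model per feature regresses the feature on the study factor.
Disease progression enters as the numeric ordinal score 0-3 by default,
reproducing a linear trend test; a 4-level categorical coding is available
(`progression = "categorical"`).  Effect sizes come from the sequential
sum-of-squares decomposition with the factor entered last, so that
`partial_eta2` is well defined when covariates are present; without
covariates eta-squared and partial eta-squared coincide.  BH adjustment is
performed within each factor's family of tests (the features actually
fitted in that call), matching the per-analysis framing of the original
workflow.  Whether sex should be a covariate of the genotype models or
only an exclusion filter is ambiguous in the source; the package defaults
to the filter reading (`selectGenotypeIons()`: keep genotype adjusted
p < 0.01, drop sex adjusted p < 0.05, rank by partial eta-squared, keep
the top 100, ties broken lexicographically for determinism) and exposes
covariates through `fitFeatureModels(covariates = )`.

# Elastic net

The penalty follows the convention in which `alpha = 1` is the pure L1
(lasso) limit and `alpha = 0` the ridge limit; the narrative description
in the source contradicts its own printed equation on this point, and the
package follows the equation (which is also the glmnet convention).
Because the task is classification, the squared-error loss of the printed
objective is replaced by the binomial/multinomial deviance — the standard
classification analogue, required to produce class probabilities.

The mixing parameter is not reported in the source; the default searches
the small grid {0.1, 0.5, 0.9} and selects, jointly with lambda, the value
minimizing the mean leave-one-out deviance (no 1-SE rule).  The lambda
path is computed once on the full data and shared across folds.
Imbalance handling (inverse-frequency class weights, or SMOTE) is applied
inside each training fold only — the left-out sample never contributes to
synthetic points, which a structural test asserts.  Predictors are
standardized inside the solver and coefficients are reported on the
standardized scale so that |beta| importance compares features fairly.

**Importance scaling.**  Per-class importance is |beta| rescaled by a
single global constant chosen so that the maximum *overall* score (the sum
of a feature's per-class scores) is 100.  This preserves the additive
structure of the published multiclass tables (per-class columns summing to
the overall column, maximum overall of 100) while remaining invariant to
rescaling of the coefficient vector.

**A note on LOO with null data.**  When the data carry no class signal,
penalty selection correctly collapses to the intercept-only model, whose
leave-one-out prediction is the training fold's majority class — which,
for a balanced design, is always the *other* class.  Null-data LOO
accuracy therefore concentrates near 0, not 0.5.  This is a well-known
artifact of leave-one-out majority voting, not a defect of the fit; the
tests assert "no better than chance" for null data.

**Metrics.**  Accuracy uses the exact Clopper-Pearson binomial interval
(the source's CI method is unstated).  Cohen's kappa is computed from the
confusion matrix; the weighted variant uses linear disagreement weights
over the ordinal stage ordering by default (quadratic available), so
confusing adjacent stages is discounted relative to distant ones.

# The synthetic-data generator

`simulateLipidomics()` draws log-normal intensities for a balanced
2 (genotype) x 2 (sex) x 3 (age) design with 6 samples per cell (72
samples), over 1030 ions in the ten categories.  Defaults are fixed once
as the package's study conditions:

* **Category sizes** — the exact per-category ion counts of the motivating
  study are not published; the default is a plausible phospholipid-heavy
  allocation (400 phospholipids, 150 sphingolipids, 150 glycerolipids,
  80 acylcarnitines, 60 cholesteryl esters, 50 DAGs, and 30-40 per
  overlapping label) summing to 1030.  These are configuration, not
  constants.
* **Baseline** — per-ion baseline log-abundances are N(log 1e5, 1.5) and
  within-ion noise is N(0, 0.5) on the log scale, giving realistically
  unequal ion abundances and a dynamic range of several orders of
  magnitude.
* **Effects** — a *diffuse* sex effect (eta-squared 0.15 per ion over 300
  ions of all categories, with balanced random signs), a *concentrated*
  genotype effect (eta-squared 0.6 on 60 phospholipid/glycerolipid ions),
  and a monotone ordinal stage effect (eta-squared 0.5 on 50 ions of the
  phospholipid, cholesteryl-ester, acylcarnitine and sphingolipid
  categories, profile 0:1:2:3).  These mirror the qualitative structure of
  the modeled study: sex variability dispersed over many lipids, genotype
  differences driven by phospholipids and glycerolipids, stage effects
  spread over several categories.
* **Zeros** — injected completely at random at rate 0.02 (the original
  zero pattern is undescribed); this exercises the zero-replacement path
  without dominating it.

**Calibration.**  For a factor carrier `c` (group indicator or stage
profile), the per-ion log-scale shift is
`delta = sigma * sqrt(eta2 / (1 - eta2)) / sd(c)`, the two-group ANOVA
identity solved for the shift.  Concentrated (same-sign) effects are
additionally rescaled by `1 / (1 - k/p)`: shifting k of p ions moves the
per-sample geometric mean by `(k/p) * delta`, attenuating the CLR contrast
by exactly that factor.  Without the correction the realized eta-squared
falls short of the target whenever the targeted set is a sizable fraction
of the composition; with it, the realized values match the target to
within Monte-Carlo error (verified by simulation over seeds).  Two
consequences of closure are worth stating because they are genuine
properties of relative data, not bugs: a same-sign shift of *every* ion is
pure scale and unobservable on the log-ratio scale (the generator refuses
it), and a concentrated shift necessarily induces a small opposite
apparent shift in all non-targeted ions (negligible at the default 1030-ion
scale, material in heavily reduced simulations).

**What the generator does not emulate** — instrument noise physics,
isotopic interference, chromatographic shape, batch effects, or
heavy-tailed contamination.  Passing recovery tests on this generator
demonstrates that the pipeline's statistics behave as designed under the
stated model; it does not certify performance on real acquisitions.

# Numerical and testing choices

* CLR row sums are enforced to 1e-9; CLR/ILR isometry to 1e-9; CPC
  variance fractions agree with a direct eigendecomposition to 1e-10;
  loading orthonormality to 1e-8.
* The ridge and lasso limits of the solver are verified against a closed
  form and an independent coordinate-descent implementation (1e-6 and
  1e-5).  For a gaussian response the solver standardizes y internally,
  so its quadratic penalty at a user lambda corresponds to the textbook
  ridge penalty at `lambda / sd(y)`; the check accounts for that
  convention.
* The mzML fixture writer emits minimal standard-conformant mzML 1.1.0
  (uncompressed little-endian 64-bit floats); conformance is checked by
  reading fixtures back through an independent mzML reader, and the
  round trip reproduces the matrix to machine precision.
* Tests and the acceptance script run reduced problem sizes chosen as the
  smallest that still exhibit each property: 120-300 ions for pipeline
  behavior, the full 1030-ion design for planted-ion recovery (where the
  closure backlash must be negligible) and for the headline metrics, and
  72 x 50 for the mzML round trip.

# Limitations

* Tentative lipid attributions are metadata only; nothing validates them
  against MS/MS identification, which is out of scope.
* The elastic-net importance ranking is conditional on the univariate
  pre-filter; features excluded there cannot resurface.
* With 72 samples and leave-one-out evaluation, accuracy confidence
  intervals are wide, and kappa estimates for the 4-class task rest on 12
  samples per disease stage.
* The generator's effect calibration targets the large-n CLR scale;
  realized per-ion eta-squared at n = 72 scatters around the target with
  Monte-Carlo spread of roughly ±0.05-0.1.
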