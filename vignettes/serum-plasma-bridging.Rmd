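---
title: "Bridging serum and plasma proteomic measurements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridging serum and plasma proteomic measurements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmabridge)
```

## The problem

Serum and plasma are both routinely profiled in blood-based biomarker
studies, but the two fractions are not interchangeable: plasma retains
fibrinogen and other clotting factors, while serum is enriched in proteins
released during clot formation and depleted of clot-bound ones. On
multiplexed aptamer assays, which report relative fluorescence units (RFU)
per protein, most proteins nevertheless track each other closely across the
two fractions within the same blood draw. `plasmabridge` exploits that
concordance: it derives a per-protein affine map from serum to plasma
measurements, screens out the proteins for which no stable map exists, and
surrounds the mapping with quality-control gates so that a transfer between
specimen types is attempted only when the data support it.

## The model

All modeling is done on `log2(RFU)` values, where assay distributions are
approximately Gaussian. For each protein $j$, matched serum–plasma sample
pairs provide observations $(s_{ij}, p_{ij})$, and the bridge is ordinary
least squares of plasma on serum:

$$ p_{ij} = \beta_j \, s_{ij} + \alpha_j + \varepsilon_{ij}, $$

fitted per protein by minimizing the residual sum of squares, with no
regularization. Serum measurements are then mapped to plasma equivalents by

$$ \log_2(\mathrm{RFU})_{\text{scaled}} =
   \log_2(\mathrm{RFU})_{\text{raw}} \cdot \beta_j + \alpha_j . $$

The closed-form solution ($\beta_j = \mathrm{cov}(s,p)/\mathrm{var}(s)$,
$\alpha_j = \bar p - \beta_j \bar s$) is computed vectorized across
proteins; `fit_scaling_factors()` also reports the per-protein Pearson fit
correlation, residual sd, and the Spearman concordance screen (correlation,
two-sided p, Benjamini–Hochberg q), matching the shape of a publishable
factor table. A linear map is a deliberate choice: simple functions need
few pairs and do not overfit, and apparent non-linearity in this kind of
data is dominated by outliers rather than by curvature.

Two variants support validation. When factors must be applied to the same
cohort they came from, `fit_scaling_factors_cv()` partitions pairs into
$k$ folds (default $k = 5$) at the *patient* level — a patient who
contributes both a baseline (T0) and an on-treatment (T1) pair never spans
folds — and returns the out-of-fold scaled serum, so every sample is scaled
by factors it did not influence. As a negative control,
`mismatched_control()` re-pairs plasma to serum by a seeded derangement (a
permutation with no fixed points); fits on that null have slopes centered
near zero and intercepts near the per-protein plasma mean.

A subtlety of the derangement null worth recording: sampling a permutation
with no fixed point induces a small negative dependence,
$E[r] = -1/(n-1)$ per protein. The mean null slope is therefore of order
$-(\sigma_p/\sigma_s)/(n-1)$ rather than exactly zero, and because the
intercept is $\bar p - \hat\beta \bar s$ with $\bar s \approx 8$ log2
units, the mean intercept sits roughly $\bar s/(n-1)$ above the plasma
mean. At 50 pairs that is ~0.2 log2 units; the package's own null checks
run at 200 pairs, where the artifact is well below 0.1.

## Protein selection

Rank correlation is the primary concordance screen. Rare values far from
the detection floor agree well between fractions even for proteins whose
bulk is compressed at the floor; such points inflate Pearson but not
Spearman correlations. `protein_concordance()` therefore reports both, and
the difference `pearson_r - spearman_r` together with a floor-distance
statistic (median log2 value minus the protein's 1st percentile, pooled
over both specimens) as a diagnostic for that pattern. Selection
(`select_proteins()`) requires a Benjamini–Hochberg `q < 0.05` on the
Spearman p-value; because at typical pair counts that threshold
corresponds to a weak correlation (roughly r ≈ 0.3 at ~50 pairs), an
optional `r_floor` lets a user demand stronger agreement. Spearman
p-values use the exact permutation null for n ≤ 9 pairs and the t
approximation otherwise.

## Outlier machinery and normalization

Every screen reuses one rule (`iqr_bounds()`): values outside
$[Q_1 - m\,(Q_3 - Q_1),\; Q_3 + m\,(Q_3 - Q_1)]$ are outliers, with
$m = 1.5$ by default. Quartiles use linear interpolation between order
statistics (`stats::quantile` type 7); since the fence position depends on
the convention, the type is exposed as a parameter.

The fence multiplier deserves a note. At $m = 1.5$ the fences sit ~2.7 sd
from the center of a Gaussian, so roughly 0.7% of clean units fall outside
by chance. That is the right stringency for conservative screening — it
was designed for it — but when the goal is to *identify exactly* the
incompatible units (e.g. recover a planted set of shifted proteins in a
validation experiment), a stricter fence ($m = 3$, ~4.7 sd, false-positive
probability ~10⁻⁶) is appropriate, and the package's planted-truth checks
use it. Defaults remain 1.5 throughout.

Two normalizations are provided. *Iterative scaling*
(`iterative_scale()`): per protein, z-score, exclude values beyond 4 sd,
re-standardize, repeat until no new outliers (the excluded set grows
monotonically, so at most n iterations; a cap of 50 guards adversarial
input), then impute excluded values to exactly ±4 sd of the final
distribution. *Robust scaling* (`robust_scale()`): `(x − median)/IQR`,
preserving extremes — the cross-check that conclusions do not hinge on
outlier handling. z-scores use the sample sd (n−1) by default; a
population-sd switch exists. Zero-variance proteins are zeroed and flagged
rather than erroring, because multiplexed panels routinely contain dead or
saturated analytes and a pipeline must proceed past them.

Normalization is always per specimen type: serum and plasma differ by
per-protein offsets and scales, and standardizing each fraction separately
is exactly what removes the specimen component from the principal
components (`pc_association()` demonstrates this on synthetic data: before
normalization the top PC separates specimens; after per-specimen iterative
scaling no leading PC is specimen-associated). When a cohort is compared
against reference samples, cohort and reference are standardized against
the *reference* distribution (parameters fitted on the reference, applied
to both), so scores are in reference sd units.

## QC gates

`run_pipeline()` executes the workflow with four hard gates before fitting
and one after scaling; each failure carries a distinct status code, and
`force = TRUE` downgrades halts to carried flags (an investigated override
— sometimes one proceeds deliberately with a flagged factor source to
study the consequences).

1. **Assay QC** (`scale_factor_filter()`): samples whose per-sample assay
   normalization scale factor falls outside [0.4, 2.5] — read inclusively
   at both ends — are excluded, and a pair is excluded if either member
   fails. A missing factor flags but never excludes.
2. **Pairing QC** (`pairing_qc()`): profiles are z-scored per protein
   within specimen (pooled across cohorts — the pooled convention is the
   default, a per-cohort switch is available by subsetting), each pair's
   cross-specimen Pearson correlation is computed over the selected
   biomarkers (all shared proteins if no panel is given), and pairs below
   the lower IQR fence are excluded. If the *median* pair correlation is
   below 0.3 the gate halts outright: bridging is meaningless when pairs
   are generally uncorrelated.
3. **Contamination QC** (`contamination_scores()`): marker-panel proteins
   (platelet / erythrocyte panels) are standardized against an external
   reference cohort; a sample's score is the mean standardized panel
   value, so a sample elevated by d reference-sds on the panel scores ~d.
   A cohort is flagged when its median score exceeds the upper IQR fence
   of the *reference samples' own score distribution*. The reference
   defines the null here deliberately: with a handful of cohorts, an IQR
   fence computed on the cohort medians themselves can never flag the
   largest median (with three medians a ≤ b ≤ c the upper fence is
   1.25c − 0.25b ≥ c), so a reproducible rule must anchor the fence in a
   distribution with more support.
4. **Generalizability QC** (`generalizability_qc()`): per-protein medians
   of the paired cohort are compared with an external reference of the
   same specimen type; proteins outside the IQR fences of the
   median-difference distribution form the outlier set, and the check
   flags when that tail exceeds 5% or the Spearman correlation of the
   median vectors drops below 0.8 (both configurable; they encode as a
   reproducible rule what is otherwise judged from scatterplots). A pure
   global offset flags nothing protein-wise and is reported as a
   systematic-offset note. Between-protocol offsets are genuine
   incompatibility, not noise — which is why planted-shift validation is
   run against a same-protocol reference.
5. **Bridging QC** (`pair_coclustering()`, `prediction_agreement()`):
   after scaling, sample pairs should be mutual nearest neighbors in the
   combined data and the 2-cluster Ward cut should no longer follow
   specimen; and a downstream predictor applied to scaled serum should
   agree with its plasma output. Two coefficients are reported: agreement
   with the unity line, $R^2 = 1 - \sum(y - x)^2 / \sum(y - \bar y)^2$
   (plasma as reference $y$; penalizes bias, can be negative), and
   agreement with the fitted line, $r^2$ (squared Pearson; blind to affine
   bias and never smaller than the unity-line value, by least-squares
   optimality). A biased factor source shows exactly the signature
   $r^2 \approx 1$, $R^2 \ll 1$ — the downstream scores are still
   perfectly ranked, just displaced, and a simple affine recalibration of
   the scores would repair them. Class agreement at a probability
   threshold is tested with a two-sided Fisher exact test on the 2×2
   concordance table.

Downstream predictors are out of scope by design; the package ships
`surrogate_predictor()`, a frozen-weight standardized linear score with a
logistic link, as the test stand-in. Its weights are positive (uniform on
[0.5, 1.5]) so that a systematic shift of the inputs moves the score — a
signed-weight score could by chance sum to zero sensitivity and mask an
injected bias — and its per-protein centers and scales are frozen at
construction (from a training matrix), never re-learned from the input,
for the same reason. The logistic gain of 2 spreads typical standardized
panels over roughly 0.2–0.8 probability without saturating.

## The synthetic-data generator

`generate_cohorts()` emulates the structure the pipeline exists to handle.
On the log2 scale:

* serum value = protein baseline (N(8, 2) across proteins, a typical
  multiplexed-assay dynamic range) + per-cohort per-protein shift
  (sd 0.2, kept below the specimen effect so cohort separation is weaker
  than specimen separation) + patient effect (sd 1) + noise (sd 0.3);
* plasma value = true slope × serum value + true intercept + independent
  noise, with slopes N(1, 0.2) and intercepts N(0, 0.5) across proteins.

Plasma is generated from the *measured* serum value, so the per-protein
OLS slope is an unbiased estimator of the planted slope; generating from a
latent noise-free signal would instead impose errors-in-predictor
attenuation of about $\sigma_u^2 / (\sigma_u^2 + \sigma_e^2)$ and no
estimator of the planted value would be validatable against it.

Layered subpopulations: detection-limit proteins (default 5%) have
baselines ~2 log2 units below a hard floor at 4; floored values are
replaced by floor + independent noise (sd 0.1), which is the simplest
mechanism that reproduces floor compression with poor precision and broken
rank correlation. Coagulation-affected proteins (default 2%, split between
plasma-retained and serum-accumulated) carry intercepts of ±log2(100),
producing ~100× and ~0.01× plasma-to-serum ratios; their slopes are pinned
to the configured mean so the planted ratio magnitude is not smeared by
slope heterogeneity. Contamination markers are spiked, in the flagged
cohort's plasma only, by a configured multiple of each marker's plasma sd.
T1 re-samples share the patient effect plus a damped perturbation
(sd 0.5), reproducing the observation that within-patient correlation
across timepoints exceeds between-patient correlation. Planted pairing
failures regenerate a pair's plasma from a fresh patient effect.

Defaults mirror the design of a three-cohort bridging study (55/82/47
pairs, second cohort ~48% T1 re-samples, third cohort
contamination-flagged, 7289 proteins). What the generator does *not*
emulate: analyte-specific dilution groups and calibrator chemistry,
heavy-tailed biological outliers, correlated protein modules, and
non-linear serum–plasma relationships. Passing tests on this generator
demonstrates that the machinery recovers planted structure under the
stated model, not that real cohorts satisfy the model.

## Numerical choices and degenerate inputs

* Quartiles: type 7 (linear interpolation); configurable.
* z-scores: sample sd (n−1); population-sd switch.
* Iterative scaling: imputation to exactly ±sd_bound in units of the
  final outlier-excluded distribution; iteration cap 50.
* Zero-variance / zero-IQR proteins: zeroed and flagged, never an error;
  zero serum variance in factor fitting: protein skipped with a warning,
  never silently zero-filled.
* Missing factors at scaling time: `error` (default), `drop`, or
  `passthrough`, chosen explicitly by the caller.
* Factor tables are written with 9 significant digits; round-trips are
  exact to ~1e-7 relative, which is far below any fit uncertainty.
* Every stochastic step (fold assignment, derangement, generator) takes an
  explicit integer seed and restores the caller's RNG state.
* Each (patient, timepoint) pair is one observation in fitting; a patient
  with T0 and T1 contributes two pairs (and is kept within one CV fold).
  Factors are fitted on QC-passing pairs only.

## Problem sizes in the shipped checks

The package's tests and the acceptance script run the statistical checks
at deliberately desk-sized conditions chosen so that each property is
well-powered: 500 proteins × 50 pairs for parameter recovery, 2000
proteins × 50 pairs × 3 seeds for null calibration of the Spearman screen,
200 pairs for the derangement null (see above), 50 pairs with 5 planted
mismatches for pairing QC, 100 seeded replicates of a 3-cohort + reference
design for contamination flagging, and 2 cohorts × ~50 pairs × 300
proteins for the end-to-end bridging exercise. These sizes are the
package's own choices; all of them scale up by configuration.

## Limitations

The method is linear per protein and offers no non-linear (spline or
quantile) mapping by design. Only the serum→plasma direction is provided;
the mathematics is symmetric and a user can swap inputs. Contamination
scoring covers panel-based platelet/erythrocyte signals, not hemolysis
indices or lipemia. Enrichment is restricted to user-supplied panels; no
annotation databases are consulted. The sensitivity of the whole pipeline
to proteins compressed at the detection limit depends on an assay's true
floor behavior, which the generator only caricatures.
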