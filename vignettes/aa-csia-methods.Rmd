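---
title: "Methods: amino acid isotope analysis for trophic ecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amino acid isotope analysis for trophic ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aacsia)
```

## The problem this package addresses

Bulk tissue δ13C and δ15N values integrate over every macromolecule in a
sample, which makes them blunt instruments for mixotrophic symbioses: a reef
coral hosting Symbiodiniaceae receives carbon and nitrogen both from symbiont
photosynthesis (autotrophy) and from captured plankton and organic matter
(heterotrophy), and changes in tissue composition or baseline isotope values
easily masquerade as trophic shifts. Compound-specific isotope analysis of
individual amino acids (AA-CSIA) resolves this by exploiting biochemistry:

* **Carbon.** Animals cannot synthesize the carbon skeletons of essential
  amino acids (Ile, Leu, Lys, Met, Phe, Thr, Val); their δ13C passes from
  diet to consumer with little fractionation, so the *multivariate pattern*
  of essential δ13C values — the "fingerprint" — identifies the biosynthetic
  source of the amino acids independently of local isotope baselines.
* **Nitrogen.** "Trophic" amino acids (Glx, Asp, Ala, Ile, Leu, Pro, Val)
  are enriched in 15N at each trophic transfer through transamination,
  while "source" amino acids (Phe, Met, Lys, and the limited/"source-like"
  Gly, Ser, Thr, Tyr, Arg) record the baseline. Their spacing yields a
  trophic position estimate internal to a single sample.

`aacsia` implements the full analysis chain for such data: validated
long-format isotope tables, trophic position and mixing-model estimators
with propagated uncertainty, the ΣV resynthesis index, and the multivariate
machinery (mean-normalization, PCA, PERMANOVA, discriminant classification)
used for fingerprinting, plus a synthetic-data generator so every stage is
testable end to end without any external dataset.

## Trophic position from the Glx–Phe spacing

The trophic position of a sample is estimated from the δ15N spacing between
glutamic acid (trophic) and phenylalanine (source):

$$\mathrm{TP}_{\mathrm{Glx-Phe}} =
  \frac{\delta^{15}\mathrm{N}_{\mathrm{Glx}} -
        \delta^{15}\mathrm{N}_{\mathrm{Phe}} - \beta}{\Delta} + 1$$

with defaults β = 3.4 ‰ (the Glx–Phe spacing in primary producers) and
Δ = 7.6 ‰ (the per-trophic-step enrichment of that spacing). Both are
`tp_params()` fields, so alternative calibrations drop in without code
changes.

Uncertainty is propagated to first order. Writing `tp` for the estimate,

$$\sigma_{\mathrm{TP}}^2 = \frac{\sigma_{\mathrm{Glx}}^2 +
  \sigma_{\mathrm{Phe}}^2 + \sigma_\beta^2 +
  \left((\mathrm{tp}-1)\,\sigma_\Delta\right)^2}{\Delta^2}.$$

By default `sd_beta = sd_delta = 0`: the propagated SD then carries only the
analytical replicate SDs of Glx and Phe. This is a deliberate choice — the
canonical β and Δ values are point calibrations whose uncertainties are not
part of a routine report — and the full Jarman-style propagation is enabled
simply by setting those two fields. The closed form is verified in the test
suite against Monte-Carlo propagation at 10^6 draws (2 % relative
tolerance), including the β/Δ terms.

## Baseline-free proxy and ΣV

The δ15N-weighted mean, `weighted_mean_d15n()`, is the inverse-variance
estimator Σ(xᵢ/σᵢ²)/Σ(1/σᵢ²) over a trophic (Ala, Leu, Glx) or source
(Lys, Phe) panel; the trophic–source difference is a TP proxy that requires
no assumed β or Δ. A replicate SD of exactly zero would give an infinite
weight; we treat it as an error by default because a triplicate SD of zero
indicates degenerate input, with `zero_sd = "substitute"` replacing zeros by
the smallest positive SD present when the user prefers robustness.

ΣV, the heterotrophic-resynthesis index, is implemented as the **mean
absolute deviation** of trophic amino acid δ15N values (Ala, Leu, Pro, Asp,
Glx) about their mean: ΣV = (1/n) Σ|χᵢ|. The phrase "summed variance" is
used loosely in the literature; the mean-absolute-deviation convention is
the one whose magnitude (~1 ‰ for metazoan tissue, 2–3 ‰ for heavily
microbially reworked material) matches reported values, so it is the
default, with `mode = "variance"` exposing a plain sample variance for
comparison. ΣV is nonnegative, translation-invariant, and |a|-homogeneous
about the mean — all property-tested.

## Percent heterotrophy: a two-end-member mixing model

With an autotrophic end-member (symbiont-derived nutrition, TP = 1.0) and a
heterotrophic end-member, the fractional contribution of heterotrophy is
linear mass balance:

$$f = \frac{\mathrm{TP}_{mix} - \mathrm{TP}_{auto}}
           {\mathrm{TP}_{het} - \mathrm{TP}_{auto}}, \qquad
\sigma_f^2 = \frac{\sigma_{mix}^2 + f^2\sigma_{het}^2 +
  (1-f)^2\sigma_{auto}^2}{(\mathrm{TP}_{het} - \mathrm{TP}_{auto})^2}$$

(the Phillips–Gregg first-order Taylor form). Two heterotrophic scenarios
are built in: feeding on primary producers or algal detritus
(`tp_het = 2.0`, "detritivory" — one transfer above a producer) and
zooplanktivory (`tp_het = 3.0` — one transfer above TP-2 plankton);
`scenario_table()` crosses samples with scenarios and reports group
mean ± SD (SD, not SE, matching how such tables are conventionally
reported). Two numerical choices matter:

* Fractions are **never clamped** to [0, 1]. A value outside that range is
  returned with an `out_of_range` flag and a warning — it is diagnostic of
  end-members that do not bracket the mixture, and hiding it by clamping
  would suppress exactly the signal a careful analyst needs.
* The first-order variance is accurate when end-member SDs are small
  relative to the end-member span; the ratio of normals otherwise grows
  heavier tails than any linearization tracks. The test suite validates the
  formula against Monte Carlo in that regime; users with very uncertain
  end-members should interpret σ_f as a lower bound.

## Multivariate machinery

**Mean-normalization.** `mean_normalize()` subtracts each sample's row mean,
removing per-sample baseline shifts exactly (an identity we test, not
assume). Note a structural consequence: normalized panel columns sum to
zero, so the pooled covariance of a normalized fingerprint is singular *by
construction*. `lda_fit()` recognizes input carrying the `normalized` flag
and proceeds in the reduced-rank space (exactly what the standard
fingerprinting workflow does); collinearity in raw input, by contrast, is
an error unless an explicit ridge (`ridge * trace(W)/p` added to the
diagonal) is requested.

**PERMANOVA.** `aa_permanova()` computes Euclidean distances on optionally
transformed values, Gower-centers −d²/2, and partitions the centered matrix
by sequential (Type I) hat-matrix projections in the order given (default:
fraction, treatment, fraction × treatment). Pseudo-F per term is tested by
free permutation of observations with a mandatory seed, p = (#{F* ≥ F} + 1)
/ (n_perm + 1) with 999 permutations by default; `n_perm = "exact"`
enumerates all n! orderings for n ≤ 8, where the p-value is the exact
proportion. The implementation is cross-checked in the tests against
`vegan::adonis2` (identical SS, F, df) and against classical one-way ANOVA,
to which it reduces exactly for univariate input.

The two transforms mirror reporting conventions for isotope data:
`"abs"` for δ13C (all-negative values, so absolute value is a sign flip)
and `"shift_positive"` for δ15N (adds −min + 1). Euclidean distances are
translation-invariant and invariant to a global sign flip, so neither
transform can change any result — the package asserts this invariance in
its tests rather than assuming it, and keeps the transforms for fidelity to
the workflow users expect to reproduce.

**PCA.** `aa_pca()` is correlation-matrix PCA (center + unit scale, via
`prcomp`), reporting scores, loadings, variance fractions, and per-variable
Pearson correlations with the first two components flagged at α = 0.05
(uncorrected, matching common reporting practice). Reconstruction of the
scaled data from scores × loadingsᵀ is tested to 1e-8.

**LDA.** `lda_fit()`/`lda_loocv()`/`lda_predict()` wrap `MASS::lda` (the
implementation this analysis is conventionally run with), with
class-proportional priors by default and `"uniform"` as an option — both
are supported because published analyses rarely state which was used.
Predictions return equal-covariance Gaussian posteriors; a coarse-group map
collapses classes into nutrition groups (symbiont → autotrophy,
plankton/POM → heterotrophy). All quantities used downstream
(proportion-of-trace, classifications, posteriors) are invariant to the
sign indeterminacy of discriminant axes.

**Ellipses.** `sd_ellipse()` returns data-ellipse parameters from the 2-D
covariance eigenstructure scaled by √χ²₂(level); `kind = "mean"` rescales
by 1/n for a confidence ellipse of the group centroid. Both the 0.90
data-ellipse and 0.95 mean-ellipse conventions seen in ordination figures
are reachable through the `level`/`kind` parameters; drawing is left to
downstream plotting tools.

**Univariate models.** `two_factor_anova()` fits fraction + treatment fixed
effects (no interaction by default, matching the term list such analyses
report) with Tukey HSD treatment contrasts — Tukey is fixed as the post hoc
procedure since "post hoc" alone underdetermines it.

## The synthetic-data generator

`synthetic_preset()` encodes the study conditions the package is validated
under, chosen once and treated as fixed:

* 13 measured amino acids (the registry's 15 minus Arg and Met, whose
  nitrogen behaviour is unknown/limited and which are rarely resolved) —
  the unique choice under which the essential subset equals the 6-AA
  fingerprinting panel (Ile, Leu, Lys, Phe, Thr, Val);
* host δ13C means spanning −24.3 to −8.1 ‰; plankton δ13C on average
  5.5 ‰ below the host with per-amino-acid variation (a *pattern*
  difference — a uniform offset would vanish under mean-normalization and
  could never be fingerprinted);
* host and symbiont at TP 1.0 (Glx − Phe = 3.4 ‰), plankton at TP 2.0
  (spacing 11.0 ‰) with the remaining plankton δ15N 2.5 ‰ above the host;
* 2 genets × 3 nutrition treatments (L-NF, L-F, D-F) × 2 tissue fractions
  plus one pooled plankton sample; triplicate injections with analytical
  SD 0.3 ‰.

Noise is independent Gaussian per amino acid per replicate; replicates are
collapsed to mean ± SD exactly as a GC-IRMS triplicate report. An optional
per-sample baseline shift (`baseline_sd`) emulates the sample-mean
variation that mean-normalization removes. Ground truth (latent means,
TPs, effects, seed) is returned with every dataset and serialized next to
the CSV by `simulate_to_dir()`, so recovery tests never re-derive it.

What the generator deliberately does **not** emulate: amino-acid–amino-acid
covariance (unknown for this system; independence is a declared
simplification), nitrogen recycling between symbiotic partners, tissue
turnover dynamics, or instrument drift. Tests passing on synthetic data
therefore demonstrate that the estimators recover known structure under
the stated noise model — not that real coral data satisfy that model.

A note on design realism: the default keeps a *single* plankton sample, as
a pooled tow sample is what a feeding experiment typically archives. Any
analysis that needs plankton replication (LDA training classes need ≥ 2
members) must raise `n_plankton`, exactly as a real study would lean on
published plankton/POM libraries to train a classifier around a single
local end-member.

## Problem sizes and numerical tolerances

The package's own validation uses: Monte-Carlo oracles of 10^6 draws for
all error-propagation formulas (2 % relative tolerance); exhaustive
permutation enumeration at n = 6 against a brute-force oracle; 999-default
/ 199-in-simulation permutations for PERMANOVA; 200 replicate simulations
for the power check of a 2 ‰ fraction effect on 4 amino acids (power
≥ 0.8); 1000 null replicates for the type-I error of the two-factor model;
and 10^5-draw coverage checks for ellipses (±0.01). SS partitions are
checked to 1e-6 relative, PCA reconstruction to 1e-8, normalization
identities to 1e-12. These sizes keep the full suite under a minute while
leaving Monte-Carlo error well below each tolerance.

## Known limitations

* The trophic position model assumes canonical β and Δ; both are
  parameters, but no calibration machinery is provided.
* Only the linear two-source mixing model is implemented — no Bayesian
  multi-source mixing.
* Distances other than Euclidean are out of scope for PERMANOVA, as are
  nonlinear ordinations.
* The reader accepts long-format CSV only; instrument-vendor formats and
  raw-signal corrections (internal standards, derivatization carbon) are
  upstream of this package.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- list(seed = 11, simulate = list(n_plankton = 4),
            permanova = list(n_perm = 999))
bundle <- run_pipeline(cfg, output_dir = "aacsia-run")
bundle$lda$assignments$group   # coarse nutrition assignment per host
bundle$permanova$N$aov_table   # nitrogen PERMANOVA table
```

The output directory then holds the per-sample TP, heterotrophy,
ΣV and weighted-mean tables, both PERMANOVA tables, a JSON report with the
PCA/LDA summaries, the log, and a `config_resolved.yaml` echo — the
reproducibility contract: the same config and inputs regenerate every file
byte-identically.
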