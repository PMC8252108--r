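# aacsia

Compound-specific stable isotope analysis of amino acids (AA-CSIA) for
trophic ecology, built for mixotrophic symbioses such as reef corals and
their Symbiodiniaceae algae.

Bulk tissue δ13C/δ15N values average over all macromolecules and confound
trophic shifts with baseline and tissue-composition effects. AA-CSIA sees
through this: essential amino acid δ13C values pass from diet to consumer
nearly unfractionated, so their multivariate pattern ("fingerprint")
identifies the biosynthetic source of a consumer's amino acids, while the
δ15N spacing between trophic and source amino acids yields a trophic
position internal to each sample. `aacsia` implements the estimators,
their uncertainty propagation, and the multivariate statistics around them,
for anyone asking how much of a consumer's nutrition is autotrophic
(symbiont-derived) versus heterotrophic (plankton/POM-derived).

## What it computes

**Trophic position** from glutamic acid and phenylalanine δ15N:

```
TP = (δ15N_Glx − δ15N_Phe − β) / Δ + 1,      β = 3.4 ‰, Δ = 7.6 ‰
σ_TP = sqrt(σ_Glx² + σ_Phe² + σ_β² + ((TP−1)·σ_Δ)²) / Δ
```

**Percent heterotrophy** from a linear two-end-member mixing model with
first-order (Phillips–Gregg) variance:

```
f = (TP_mix − TP_auto) / (TP_het − TP_auto)
σ_f² = (σ_mix² + f²σ_het² + (1−f)²σ_auto²) / (TP_het − TP_auto)²
```

with built-in detritivory (TP_het = 2.0) and zooplanktivory (TP_het = 3.0)
scenarios, plus:

* inverse-variance **weighted mean δ15N** over trophic/source panels;
* **ΣV**, the mean absolute deviation of trophic amino acid δ15N (a
  microbial-resynthesis proxy);
* **mean-normalized essential-δ13C fingerprints**, PCA of the correlation
  matrix with significant correlation vectors, **PERMANOVA** on Euclidean
  distances (sequential SS, seeded or exhaustive permutation), **LDA** with
  leave-one-out cross-validation and autotrophy/heterotrophy group
  assignment, SD/confidence ellipse parameters, and per-amino-acid
  two-factor linear models with Tukey contrasts;
* a **synthetic-data generator** with serialized ground truth, emulating
  host/symbiont/plankton isotope structure for end-to-end validation;
* `run_pipeline()`, a config-driven orchestrator writing a reproducible
  report bundle (CSV + JSON + config echo).

## Worked example

```r
library(aacsia)

# a consumer sample: Glx 11.6 ± 0.3 ‰, Phe 3.1 ± 0.2 ‰
tp <- trophic_position(11.6, 3.1, sd_glx = 0.3, sd_phe = 0.2)
tp
#> Trophic position (Glx-Phe): 1.671 +/- 0.047

heterotrophy_fraction(tp, tp_auto = 1.0, tp_het = 2.0)
#> Heterotrophy (detritivory): 67.1% +/- 4.7%
```

The sample sits 0.67 of the way from the autotrophic end-member (TP 1, a
primary producer) to a detrital/algal diet end-member (TP 2): about 67 % of
its glutamic acid nitrogen is heterotrophically sourced under that scenario,
with the analytical replicate uncertainty propagated to ±4.7 points.

The same machinery runs end to end on synthetic data with known truth:

```r
g <- generate_dataset(synthetic_preset(n_plankton = 4), seed = 11)
tpt <- tp_by_sample(g$table)
aggregate(cbind(tp, sd) ~ fraction, tpt, function(x) round(mean(x), 2))
#>   fraction   tp   sd
#> 1     host 1.00 0.07
#> 2 plankton 2.03 0.05
#> 3 symbiont 1.01 0.04

# essential-δ13C fingerprinting: symbiont vs plankton nutrition sources
m  <- subset_matrix(g$table, "C", aa_set = aa_set("eaa6"),
                    fractions = c("symbiont", "plankton"))
fp <- mean_normalize(m)
lda_loocv(fp, attr(m, "metadata")$fraction)
#> LOOCV overall success: 100.0%
#>           predicted
#> true       plankton symbiont
#>   plankton        4        0
#>   symbiont        0        6
```

Host and symbiont recover their configured trophic position of 1 (producer
baseline) and plankton its TP of 2; the mean-normalized fingerprints of the
two nutrition sources are perfectly separable under leave-one-out
cross-validation. `run_pipeline(list(seed = 11))` chains every stage —
validation, TP, mixing scenarios, ΣV, weighted means, PERMANOVA (C and N),
PCA, fingerprint LDA — and serializes the report.

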