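---
title: "Methods: Pool-Seq contrasts of neutral and adaptive variation between stand types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Pool-Seq contrasts of neutral and adaptive variation between stand types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscape)
```

poolscape analyses pooled-sequencing (Pool-Seq) variant data from two
contrasting sets of forest stands — old-growth and recently planted — sampled
along a climate gradient, and asks whether the two stand types differ in
neutral diversity, in climate-associated (adaptive) variation, and in their
expected vulnerability to a projected future climate. This vignette explains
the models and statistics the package implements, the tunable parameters and
their defaults, what the synthetic-landscape generator does and does not
emulate, and the numerical and design decisions that were genuinely open.

## Data model

The raw observable is a `pool_counts` object: per SNP and per stand (one
sequencing pool of `n_h` haplotypes; 60 by default, i.e. 30 diploid trees),
the reference and alternate read depths. Allele frequencies are estimated as
raw read proportions `alt / (ref + alt)` — the standard Pool-Seq estimator,
whose error combines haplotype sampling (`~ sqrt(p(1-p)/n_h)`) and read
sampling (`~ sqrt(p(1-p)/depth)`). At the default simulated depth of 1850x
the haplotype term dominates.

SNP filters follow common Pool-Seq practice, applied in order: (a) minimum
total depth of 60 reads in every pool (1x per haplotype); (b) every pool's
depth inside its own 0.1–99.9% depth quantile band (paralogous or repetitive
loci inflate depth; dropouts deflate it); (c) overall depth-weighted
minor-allele frequency at least 0.008 (`~ 1/(2 x 60)`, a dataset-wide
singleton filter). Two points were open and are worth making explicit:

* *Quantile pooling.* The depth band is computed per pool by default (each
  pool has its own depth distribution), with `cov_scope = "global"`
  available.
* *Idempotence.* A quantile band recomputed on an already-trimmed
  distribution always shaves a few more SNPs, so "filter twice" is not
  literally a no-op. The realised band is therefore stored as attribute
  `cov_bounds` and can be reapplied, which is exactly idempotent; the naive
  re-application changes well under 1% of SNPs.
* *MAF scope.* Whether the MAF cut is global or per pool is a genuine
  ambiguity; global is the default (`maf_scope = "per_pool"` exists) because
  0.008 is naturally read as a dataset-wide singleton threshold.

## Pairwise FST for pools

`pairwise_fst()` implements the ANOVA-type Pool-Seq FST estimator of Hivert
et al. (2018). Under the hierarchical model — population frequency, then
`n_i` haplotypes per pool, then `c_i` reads drawn with replacement from the
haplotypes — the within-pool sum of squares `SSI = sum_i c_i p_i (1 - p_i)`
and the between-pool sum of squares `SSP = sum_i c_i (p_i - pbar)^2` have
expectations that are linear in `F` with coefficients depending on
`D2_i = (n_i + c_i - 1) / n_i`, the read-duplication correction. The
estimator pairs an unbiased numerator (proportional to `F`) with an unbiased
denominator (proportional to total variance) and combines loci as a *ratio
of sums* — the stable multilocus combination. Properties worth noting:

* slightly negative estimates are legitimate sampling noise and are
  *not* clamped (clamping would bias the Mantel statistics downstream);
* with one locus the multilocus estimate equals the single-locus estimate;
* the estimator recovers the drift parameter of a Balding–Nichols
  simulation (truth 0.05 recovered as 0.049 +/- 0.002 over replicates in the
  test suite).

## Outgroup f3

`outgroup_f3()` estimates `f3(O; A, B) = E[(p_O - p_A)(p_O - p_B)]`, the
shared drift of two sources relative to an outgroup; larger values mean the
sources are more similar. Because `p_O` appears in both factors, its
sampling variance biases the plain product upward; the estimator subtracts
an unbiased estimate of that variance,
`p_O (1 - p_O) (n_O + c_O - 1) / ((c_O - 1)(n_O - 1))`, accounting for both
pool size and read depth. Uncertainty comes from a delete-one block
jackknife over contiguous blocks of 500 SNPs (default; the block size is a
robustness device against local LD, which the simulation does not generate).
`f3_locality_scan()` cycles the outgroup role within each locality trio:
with the old stand as outgroup the comparison class is "P vs. P", otherwise
"O vs. P".

## Gene–environment association

Two detection routes are implemented, run separately for the old and the
planted stand set.

**Correlation with a Monte-Carlo null.** `corr_null_threshold()` draws one
million random frequency vectors, pairs each with a randomly selected
climate variable, and takes the 99.9% quantile of the Pearson correlations;
a SNP–variable pair whose signed correlation strictly exceeds the threshold
is declared associated (an `|r|` mode exists). For 15 stands the Gaussian
null gives r = 0.730, equal to the exact Student-t closed form
`t / sqrt(t^2 + df)` with `t = qt(0.999, 13)`. A caution we found worth
documenting: the far tail of this null is *not* distribution-free at small
n. The closed form is exact for spherically symmetric draws, but for
Uniform(0,1) draws the 0.999 quantile depends on the shape of the fixed
partner vector — near 0.74 against smooth ramp-like climate vectors, and
well below 0.73 against a spiky partner. Gaussian draws are therefore the
default; the threshold is computed once from the old-stand count (n = 15)
and applied to both stand sets, which is conservative for the larger
planted set.

**Latent-factor regression.** `lfmm_associations()` regresses each SNP on
the climate variable plus K latent factors taken as the first K principal
components of the frequency matrix (K = 4 by default), converts the
variable's t statistic to a z-score, recalibrates the squared z-scores by
the genomic inflation factor (median z² over the chi-square(1) median), and
applies a Bonferroni cut of `alpha / n_snps`. GIF recalibration is monotone,
so p-value ranks are unchanged. Variables nearly collinear with the factor
span are flagged — in that regime the correction has absorbed the signal and
the scan has no power, which is a property of the design, not a bug.

## Isolation by distance and by environment

Geographic distances use the Haversine great-circle formula with the mean
Earth radius 6371.0088 km. Climate distances standardise each variable to
zero mean and unit variance across stands and take Euclidean distances; the
per-variable distance used in the stand-type contrast tables is the absolute
standardised difference of the single named variable, while the
all-variable distance uses all seven.

`mantel_test()` and `partial_mantel()` correlate strictly-lower-triangle
entries, with one-sided upper-tail permutation p-values
(`p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`, 9999 permutations by
default; the count is a convention choice, not reported by most studies).
The partial statistic is the first-order partial correlation; permutations
relabel the first matrix and recompute it. Both functions reproduce vegan's
`mantel`/`mantel.partial` statistics exactly and are implemented in-package
for full seed control (vegan serves as an independent cross-check in the
test suite). The IBE design follows the stand-type contrast tables: the
dependent matrix is FST from the outlier SNPs of a variable, the predictor
is that variable's climate distance, and the control is FST from all
remaining SNPs. The per-variable outlier set is the union of old- and
planted-detected SNPs: scoring both stand sets on a shared set is the only
way a set with zero own detections can still be evaluated (as the real
tables require), and the union is overwhelmingly old-detected SNPs.

## Risk of non-adaptedness (RONA)

For each associated SNP, an ordinary least-squares regression of frequency
on the raw (unstandardised) climate variable — slopes keep per-unit meaning —
and per stand a required allele-frequency shift, averaged over SNPs with
r² weights. Two shift forms are provided:

* `form = "observed"` (default): `|(a + b e_future) - p_observed|`, the
  distance from the stand's *current observed* frequency to the fitted
  future expectation. This form carries any mismatch already present under
  the current climate — which is exactly why maladapted (planted) stands
  score high, and is the behaviour the real-data pattern requires.
* `form = "predicted"`: `|b| |e_future - e_current|`, a pure
  climate-displacement term. It is zero under a zero shift and exactly
  linear in the shift (both properties are unit-tested), but it cannot rank
  a maladapted stand above a well-adapted one when the maladapted stand's
  fitted slope is attenuated; it is the right form for "how much change
  does the climate displacement itself demand".

Regressions are fitted within the stand set being scored. RONA is invariant
to which allele is labelled alternate (the absolute value cancels the slope
sign flip under `p -> 1 - p`).

## The synthetic landscape

The generator provides ground truth for every stage. Its defaults are the
study conditions: 15 localities (1 old + 2 planted stands each) along a
west–east axis, seven collinear climate variables that are monotone in the
axis plus noise, 20,000 neutral and 700 adaptive SNPs (100 per variable),
pools of 60 haplotypes at mean depth 1850x (negative-binomial, dispersion 5,
so the coverage filters are exercised), per-read error 0.001.

* **Neutral SNPs** follow Balding–Nichols drift: ancestral frequency
  `pi ~ U(0.05, 0.95)`, stand frequencies Beta with mean `pi` and variance
  `pi(1-pi) F` (`F = 0.05`).
* **Latent structure.** Four latent factors load (on the logit scale,
  sd 0.6) on neutral SNPs, with stand scores orthogonalised against the
  climate axis within each stand type. They emulate population structure
  that is *not* climate-collinear — recolonisation history, provenance
  blocks — i.e. precisely the structure a latent-factor correction is meant
  to absorb. Without any such structure the first principal components *are*
  the adaptive cline, the K = 4 correction absorbs the climate variable, and
  the latent-factor scan has no power at any effect size; with random
  (non-orthogonalised) factor scores, four random directions in 15-stand
  space still absorb ~2/7 of the axis, which at 9 residual degrees of
  freedom pushes every adaptive p-value above the Bonferroni cut. The
  orthogonalised design keeps the confounder and the signal separable, as
  they evidently were in the real data (where the scan had power). The
  factor strength is set so the four factor eigenvalues dominate the
  adaptive-axis eigenvalue.
* **Adaptive SNPs** sit on a logistic cline in their standardised driver:
  old-stand mean `plogis(qlogis(pi) + 1.5 z)`. The slope 1.5 per driver
  standard deviation makes mid-frequency clinal SNPs clear 0.73 comfortably
  in old stands — the regime the study's detection counts imply.
* **Planted decoupling.** Each planted stand draws one source position
  `z_src ~ N(0, 0.5^2)` on the axis — one seed lot per stand, with orchard
  material climatically closer to the range centre than the sampled extremes
  — and its adaptive mean is `(1-d) cline(z_local) + d cline(z_src)` with
  `d = 0.8`. The *stand-level* source term is the crucial design choice: a
  decoupling applied uniformly (pulling every planted stand toward the
  ancestral mean) leaves planted stands internally consistent on their own
  flattened cline, so their regression residuals match the old stands' and
  neither the elevated planted RONA nor the absent planted IBE can emerge.
  One source draw per stand creates (i) stand-specific current-climate
  mismatch (the RONA pattern), (ii) a per-pair FST random effect shared
  across SNPs that swamps the residual `(1-d)` cline in the planted Mantel
  tests, and (iii) extra mutual similarity of planted stands (the f3
  pattern, since `source_sd < 1`). With `d = 0` the model reduces exactly to
  the old-stand model — the negative control under which no downstream stage
  may separate the stand types.
* **Future climate** adds a warming-consistent shift of 0.25 x each
  variable's spatial gradient coefficient: over a region spanning a steep
  coast-to-mountain gradient, an end-of-century mid-range scenario moves
  local climate by a modest fraction of the spatial spread.

What the generator does **not** emulate: linkage between SNPs (each locus is
independent, so block-jackknife errors are conservative for real data), GBS
fragment structure and restriction-site dropout, shared orchard ancestry at
neutral loci across planted stands (the real "P vs. P" similarity likely has
a genome-wide component ours restricts to adaptive loci), spatially
autocorrelated drift, and reference-bias or mapping artefacts. Passing tests
on this landscape therefore demonstrate that the estimators recover their
own generating model — a necessary check, not evidence about any particular
real data set.

## Numerical choices

* Seeded randomness throughout; `run_pipeline()` derives per-stage seeds
  from one master seed, so changing the Mantel seed changes only Mantel
  outputs.
* Ties at the correlation threshold count as non-significant (strict
  inequality).
* SNPs with zero variance across stands get an `NA` correlation and never
  pass; constant SNPs get slope 0 and r² 0 in the RONA regressions.
* Beta means are clamped to `[1e-9, 1 - 1e-9]` before drawing drift noise.
* FST pairs drop loci with zero depth in either pool and loci whose
  effective-size denominator vanishes (depth 1 in both pools); a pair with
  no usable loci is a hard error.
* Problem sizes in the test suite: the full default landscape (20,700 SNPs,
  45 stands) is simulated once and shared across the end-to-end checks;
  parameter-recovery oracles use 5,000 loci and 20 replicates; Mantel
  calibration uses 200 independent null replicates at 199 permutations.

## Package shape

Result tables (stand metadata, climate, outlier reports, f3 tables,
diversity, RONA) are tibbles and compose with the pipe; fitted Mantel
results have `tidy()`/`glance()` methods; `plot_*()` helpers return ggplot2
objects. The core containers — allele-count matrices, frequency matrices,
distance matrices — remain base matrices, as in the field's established
packages: a 45 x 20,000 tibble would be the wrong tool.

## Known limitations

* The latent-factor association is a fixed-effect regression on principal
  components with genomic-control calibration — the design the study
  describes — not the ridge/EM latent-factor estimator; with very small
  stand numbers (n < ~12) it has essentially no power at Bonferroni
  stringency.
* The correlation-null threshold inherits the far-tail shape sensitivity
  discussed above; the false-positive rate of the correlation scan on
  Beta-distributed neutral frequencies is of the design order (measured
  ~0.0008 against a nominal 0.001) rather than exactly nominal.
* RONA is a proxy for required allele-frequency change, not a fitness
  measure, and per-variable results are strongly correlated because the
  climate variables share one gradient.
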