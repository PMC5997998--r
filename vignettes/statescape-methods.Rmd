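---
title: "Physiological state-space mapping and early-warning statistics: methods"
author: "statescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiological state-space mapping and early-warning statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statescape)
```

# The problem

Batch cultures of phytoplankton under compounding stress can collapse
abruptly. Before collapse, replicate cultures stop adopting the internal
(transcriptomic, physiological) state that matches their external
environment: light-phase transcriptomes stop looking light-like,
replicates diverge from one another, and the variability of
photosynthetic efficiency inflates. `statescape` operationalizes this
*loss of relational resilience* as a set of computable statistics on an
expression matrix (FPKM), sample metadata, cell counts, and
dark-acclimated fluorescence yields.

# State descriptors

The reference population is the experiment's unstressed stage (default:
stage 1, both CO₂ conditions pooled — 24 samples in the canonical
design). For each axis (diurnal: light vs dark; growth phase: early vs
late), a transcript qualifies as a state descriptor when, on
log10(FPKM + 1):

1. a two-sided Mann–Whitney U test separates the two states at
   `alpha = 0.05` after Benjamini–Hochberg adjustment (`multiple_testing
   = "none"` is available for a more literal reproduction of workflows
   that did not adjust);
2. the absolute difference of state medians is at least log10(2)
   (twofold, `fold_change_min = 2`);
3. that median difference is at least `separation_sd_multiple = 1` times
   the mean of the two per-state sample SDs (n − 1 denominator).

Genes qualifying for both axes are assigned to the axis with the larger
separation-to-SD ratio, keeping the two sets disjoint. Each selected
gene's *profile* records the per-state medians Q₂, observed extremes,
orientation ε = +1 iff Q₂(φ_α) < Q₂(φ_β) (α = light or early), and the
gap θ between the distributions with its centre θ_c when they do not
overlap.

Choices worth noting: the significance test, α and adjustment are not
uniquely determined by the workflow this package generalizes, so all
three are exposed in `descriptor_criteria()`; the pseudocount of 1
before log10 bounds fold-change inflation at zero FPKM while preserving
order; SDs and medians are computed in log10 space throughout, and the
same pseudocount must be used at selection and at mapping.

# Position scores

For one descriptor with profile as above and observed log10 expression
κ, the score λ(κ) is piecewise linear:

* κ inside the gap: λ = 2ε(θ_c − κ)/θ (0 at the centre, ±1 at the
  edges);
* otherwise, with δ = +1/−1/0 by whether κ is closer to Q₂(φ_α),
  Q₂(φ_β), or equidistant, and φ the state selected by δ:
  λ = 1.5δ + ε|κ − Q₂(φ)| / (2|φ_min − Q₂(φ)|) for κ below the median,
  λ = 1.5δ − ε|κ − Q₂(φ)| / (2|φ_max − Q₂(φ)|) above it, λ = 1.5δ at it.

So each state's range maps onto [1, 2] (or [−2, −1]), with the median at
±1.5, the outer extreme at ±2 and the gap-facing extreme at ±1,
continuous with the gap interpolation. Edge decisions, made once and
used everywhere:

* **Out-of-range κ** (beyond all observed extremes): clamped to ±2; the
  equations would otherwise extrapolate without bound on unseen data.
* **Exact tie** (δ = 0, only reachable when the distributions overlap):
  λ = 0, matching the gap formula's value at θ_c.
* **Overlapping distributions** (θ = 0): only the within-range formula
  applies.
* **Continuity** holds at every branch boundary whenever the
  equidistant switch point of δ lies inside the gap — the generic case
  for well-separated descriptors. When the two distributions are
  strongly asymmetric (switch point inside one state's range) or
  overlap, the published piecewise rules are inherently discontinuous at
  the switch; this is a property of the method, not of the
  implementation, and the oracle-equivalence tests cover both regimes
  while continuity is asserted on the continuous one.

```{r lambda-example}
p <- descriptor_profile("demo", "diurnal",
                        alpha = c(0.5, 1.0, 1.5), beta = c(2.5, 3.0, 3.5))
transcript_position_score(c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5), p)
```

Coordinates are uniform-weight averages per axis (the selection
criteria provide no per-gene weighting signal, so ω_i = 1/n, ω_j = 1/m),
giving s_x, s_y ∈ [−2, 2]. Sign convention: positive s_x is light-like,
positive s_y early-like.

# Reference regions and classification

The four reference regions are circles centred on the mean reference
position of each state. The radius is 1.96 × the SD of reference
positions about their centroid, i.e. `1.96 * sqrt(var(s_x) + var(s_y))`
— the standard deviation of the position vector, giving ~98% coverage
for approximately Gaussian clouds (the per-axis-RMS variant,
`radius = "axis_rms"`, is available but covers only ~85% in 2D). Two
estimation choices matter at the canonical design size of 6 samples per
state:

* **Pooling** (`pool = TRUE`, default): the dispersion is pooled across
  the four states (n − 1 weighted, deviations from each state's own
  centroid). A per-state variance with ~5 df per axis is noisy enough
  that expected held-out coverage drops by several points purely from
  estimator noise.
* **Leave-one-out positions** (`crossvalidated_reference_positions()`,
  used by the pipeline): reference samples are re-scored against
  profiles rebuilt without them. In-sample positions understate
  held-out scatter — a sample can never exceed extremes it helped
  define, and beyond the gap-facing extreme the gap branch is ~4× as
  steep — so regions built from in-sample positions misclassify ~15% of
  genuinely pure held-out samples. LOO positions measure generalization
  dispersion directly; held-out corner classification is then ~95–98%
  on the default synthetic study.

A position gets the label of the nearest centroid if it lies within that
region's radius, otherwise (including exact ties) "non-distinctive".

# Resilience statistics

* `pairwise_spearman()`: SCC between all sample pairs on the genes with
  FPKM ≥ 5 in *every* sample (one shared compendium per comparison set;
  per-pair filtering is an option). Average ranks for ties.
* `replicate_distance_per_timepoint()` + `test_distance_shift()`:
  Euclidean distances between replicate positions per (condition, stage,
  time-point), compared between stages by two-sided Mann–Whitney U
  (exact for small tie-free samples via `stats::wilcox.test`). Note
  that the three pairwise distances of a replicate triple share
  positions; treating pooled distances as independent observations makes
  the test mildly anticonservative (~1.9× nominal in simulation). This
  mirrors the field's practice; the calibration tests therefore use
  independent distances, and stage comparisons should be read as
  descriptive significance.
* `cv_over_replicates()` + `test_cv_shift()`: per-time-point CV
  (n − 1 SD over mean) of replicate F_v/F_m, paired across stages by
  within-stage time index (truncating to the shorter series), two-sided
  Wilcoxon signed-rank, zero differences dropped, exact p for n ≤ 25
  without ties; fewer than 5 usable pairs triggers an error or the
  unpaired Mann–Whitney fallback.

With the canonical 3 replicates per time-point, the per-time-point CV
estimate carries χ²₂-type noise: under a 3× CV inflation the probability
that a single pair points the wrong way is P(F(2,2) > 9) = 0.10, and the
exact two-sided signed-rank at 12 pairs needs a negative-rank sum ≤ 5
(p = 0.0049) — enumeration puts the detection probability at p < 0.005
near 0.75, and ~0.9 would need ≥5 replicates. The package reports this
detection rate honestly rather than overstating the power of triplicate
designs.

# Growth physiology

`compute_fvfm()` is (F_m − F_o)/F_m. `specific_growth_rate()` is the OLS
slope of ln(count) vs time (days) over a user window or an auto-detected
steepest 4-point run (a heuristic, reported with the window used).
`fit_logistic_with_lag()` fits, by least squares on ln(count)
(multiplicative noise model, consistent with the μ definition), the
explicit-lag logistic

N(t) = n0 for t ≤ lag;  N(t) = K·n0·e^{μ(t−lag)} / (K + n0·(e^{μ(t−lag)} − 1)) after,

isolated in `logistic_lag_curve()` so the functional form can be
swapped. This form was chosen over smooth three-feature sigmoids because
it equals n0 exactly through the lag and makes K, μ, lag directly
interpretable. Initial values are seeded from the data (first count, max
count, steepest log-linear segment and its intercept); optimization uses
`minpack.lm::nlsLM` with a `stats::nls` fallback; non-convergence and
plateau-free series (boundary K) are flagged, never silent. At 5%
multiplicative noise on a twice-daily, 10-day sampling grid the ML lag
estimate has a sampling SD near 6% of a 1-day lag (bias ≈ 0; profiling
the SSE over lag confirms the optimizer attains the optimum), so
single-series lag estimates should be quoted with that uncertainty.

# The synthetic-study generator

`synth_config()` defaults define the study conditions the package is
validated under: 3000 genes of which 60 diurnal + 220 growth-phase
planted descriptors (mirroring the 58/218 descriptor counts of the
motivating study), state-median separation 0.6 log10 (~4-fold) against
within-state SD 0.12 log10, background genes with a long-tailed
log10-mean distribution (mean 1.2, SD 0.8) so the 5-FPKM filter is
exercised, 2 conditions × 2 × 2 × 3 replicates = 24 reference samples,
F_v/F_m base 0.65, growth K = 2e6 cells/mL, μ = 0.9 d⁻¹, lag = 1 d,
n0 = 1e5 cells/mL (typical seeding density). Expression noise is normal
in log10 space because every selection and separation criterion operates
there. Dysregulation has two independent knobs, matching the two
observed pre-collapse signatures: `mixing` scrambles a descriptor's
state per (sample, descriptor) draw (loss of state coherence), and
`position_jitter_scale` multiplies within-state SD per stage (inflated
replicate dispersion). All randomness flows through R's default
Mersenne-Twister stream from a single integer seed; regeneration is
bit-identical.

What the generator does *not* emulate: the real transcriptome's
correlation structure between genes, library-size artefacts, the actual
gene catalog of any organism, or dose-response of the stressors. Passing
recovery tests therefore demonstrate that the pipeline's inference is
correct under its own statistical assumptions, not that those
assumptions hold for any particular dataset.

# Problem sizes and numerical choices

The validation suite uses: oracle equivalence on 10,001 κ values × 20
random profiles (agreement to 1e−12; continuity probed at ±1e−13 around
every branch edge); descriptor recovery and held-out classification on
the default 3000-gene study with 15 replicates (24 reference samples,
96 held-out); 100 seeded simulations each for the dispersion (400
genes, 2 stages) and CV detection rates; 1000 simulations for null
calibration. Descriptor-set JSON is written with 17 significant digits
because profile extremes are branch boundaries of the score and must
survive serialization bit-exactly; tabular output uses 15 significant
digits and fixed column order so repeated runs are byte-identical.

# Known limitations

* Mapping requires every descriptor gene present in the target
  transcriptome; cross-platform mapping (microarray compendia) needs an
  upstream id harmonization the package does not provide.
* The state space is 2D by construction; additional physiological axes
  require their own descriptor sets.
* The dispersion test's independence caveat and the triplicate CV power
  limit are described above.
* Descriptor selection assumes the reference stage is itself healthy;
  a dysregulated reference yields few descriptors and a warning.
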