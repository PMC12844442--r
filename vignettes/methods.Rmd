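---
title: "Models and methods behind microscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microscale)
```

This vignette explains the statistical machinery the package implements,
the choices made where the methodology was genuinely open, and what the
synthetic-data generator does and does not emulate. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The nested design

All spatial analyses assume samples collected on nested quadrats: at level
*k* the quadrat has side `side0 * 2^k`, hence area `(side0 * 2^k)^2` m²,
and each smaller quadrat lies inside all larger ones of the same plot.
With `side0 = 0.5` m, thirteen levels span 0.5 × 0.5 m² to
2048 × 2048 m². Samples sit at quadrat corners. "All samples within the
level-*k* quadrat" therefore means all samples at levels ≤ *k* of that
plot, and both the taxa–area and node–area machinery use this cumulative
inclusion (a non-cumulative per-level mode is exposed on `buildNar()` for
sensitivity analysis).

## Taxa–area relationship

Two classical species–area forms are fitted:

* the **logarithm model** `S = c + z log(A)`, a closed-form OLS on
  log-transformed area;
* the **power model** `S = c A^z`, Levenberg–Marquardt nonlinear least
  squares on the original richness scale, started from the log–log OLS
  solution (with two fallback starts).

R² is computed on the original *S* scale for both, so the models compete on
the same footing. The logarithm of area is base 10 by default; the slope
*z* — the spatial turnover rate — scales with the base, so the base is
stored inside every `SarFit` and reported alongside *z*. Replicate plots
contribute separate points to one pooled fit per group; fitting per plot
and averaging is possible by subsetting the curve but pooling is the
default because the replicate scatter then informs the fit's R².

Group differences in *z* are tested by permutation: the pooled
(area, richness) points are randomly reassigned to the two groups
preserving group sizes, the model is refitted on each side, and the
two-sided p-value is `(1 + #{|Δz_perm| ≥ |Δz_obs|}) / (n_perm + 1)`. For
the logarithm model the refit is a closed-form slope, which keeps
999 permutations effectively instantaneous and makes large calibration
studies feasible; power-model permutations refit by NLS and are markedly
slower. Points within a plot share the nested pooling and are therefore
not independent; a plot-level permutation unit (`unit = "plot"`) is
provided for a conservative alternative. The point-level test is exact
under the null that the two groups' curves are exchangeable, which the
test suite verifies by Monte-Carlo calibration (500 replicates × 999
permutations; empirical type-I error at α = 0.05 within [0.02, 0.08]).

## Co-occurrence networks and the node–area relationship

Networks are built from pairwise Spearman correlations (average-rank tie
handling) among taxa that pass the conventional pre-filter: overall
relative abundance ≥ 0.1 % of the grand total and prevalence ≥ 20 % of the
samples at hand. Edges require |r| strictly above 0.80 and two-sided
p < 0.05; p-values use the t approximation
`t = r sqrt((n − 2)/(1 − r²))`, adequate at the sample sizes the NAR uses
(see below), with exact ±1 mapped to p = 0. Constant taxa have undefined
correlations and are recorded as r = 0, p = 1 and flagged. No
multiple-testing correction is applied by default (the raw-p convention of
the co-occurrence literature); Benjamini–Hochberg is available by flag and
can only remove edges. Topological summaries (degree, density, components)
come from igraph.

The node–area relationship repeats, per nested level: collect the samples
inside that level's quadrat (cumulative), re-apply the abundance/prevalence
filter *to that sample set*, build the network, record node and edge
counts against area. Re-filtering per level is deliberate: prevalence is
only defined relative to a sample set, and the growing set is exactly what
"the community observed at this scale" means on a nested design.

Two numerical guards matter here:

* **Minimum sample count.** With ~10⁴ taxon pairs tested, small sample
  sets produce spurious strong correlations: at n = 12 the chance of
  |Spearman| > 0.8 is large enough to yield dozens of phantom nodes, and
  every such coefficient also passes raw p < 0.05. Levels with fewer than
  `min_samples = 16` samples are therefore skipped (with a warning); at
  n = 16 the expected number of chance edges is down to a handful, and it
  is negligible by n = 24.
* **Breakpoint detection.** The NAR curve is summarized by comparing a
  single line to a continuous two-piece linear regression on
  (log₁₀ area, node count), with the break searched over the interior
  observed levels by SSE. The curve is called *unimodal* only when the
  segmented model improves SSE by at least 10 % **and** the slope switches
  from positive to negative at the break; otherwise it is monotonic with
  the single line's slope sign, flat curves counting as
  monotonic-decreasing. The 10 % hurdle stops the extra two parameters
  from winning on noise alone.

## Sloan neutral community model

For a taxon at source-pool relative abundance *p*, the stationary Sloan
model puts its local relative frequency on `Beta(Nm p, Nm (1 − p))`, where
*N* is the local community size (taken as the uniform per-sample read
depth, enforced by requiring rarefied input) and *m* the migration rate.
The predicted occurrence frequency is one minus the Beta CDF at the
detection limit *d*. `fitNcm()` estimates *Nm* by least squares of
observed occurrence frequencies on this prediction across taxa,
initializing Levenberg–Marquardt from a log-spaced grid; R² is reported on
the frequency scale and taxa are partitioned against a 95 % Wilson
binomial band around the fitted curve.

The detection limit deserves a note. The classical convention is
*d = 1/N* ("one read"). But under multinomial read sampling a taxon at
frequency *q* is detected with probability `1 − (1 − q)^N`, which crosses
½ at `q = ln 2 / N ≈ 0.69/N`. Using the hard threshold 1/N therefore
under-predicts detection and inflates the fitted *Nm* — by 25–45 % on
communities simulated exactly from the Sloan model. The package defaults
to `d = log(2)/N`, which centres the hard-threshold approximation where it
matters and recovers generating migration rates within ~12 % across
m ∈ {0.05, 0.1, 0.3, 0.6} (S = 500 taxa, 100 samples, 2000 reads — the
problem size the acceptance checks use). The one-read convention remains
one argument away.

## Normalized stochasticity ratio

Observed pairwise dissimilarities *D* (Bray–Curtis by default, binary
Jaccard optionally) are compared to their expectation *E* under a null
model that preserves each sample's richness and read depth, draws taxon
occupancy proportional to regional occurrence frequency, and assigns reads
multinomially proportional to regional relative abundances. Per pair, the
selection strength is `C = (D − E)/(1 − E)` when observed dissimilarity
exceeds the null expectation and `C = (E − D)/E` otherwise; stochasticity
is `ST = 1 − C`, and the NST is the mean ST over pairs, clipped to [0, 1].
The standard error is taken over the pairwise ST values — the resampling
unit is the pair, which the output documents explicitly since other
conventions (bootstrap over samples) exist. Pairs with E = 0 carry no
information under this normalization and are excluded with a count.

The estimator's defining behaviour — the one the acceptance checks pin
down — is directional: communities generated by the null model itself, or
by neutral Beta sampling, score NST well above 0.5, while strongly
niche-filtered communities (Gaussian niche kernel with strength ≥ 10 on a
unit-variance environmental field) score below 0.5. With 25 samples,
300 taxa and 200 null draws this direction is stable across seeds.

## Niche breadth, diversity, environment

Levins niche breadth is `B_i = 1/Σ_j P_ij²` with *P* the taxon's
occurrence proportions across samples; the community value is the
unweighted mean over taxa with nonzero totals (abundance weighting is an
option). Alpha diversity reports richness, Shannon (natural log) and
Gini–Simpson `1 − Σ q²` — the bounded Simpson variant, chosen because it is
the one usually plotted alongside Shannon. Beta diversity is Bray–Curtis
on raw counts via vegan.

Environmental heterogeneity z-scores every variable (sample sd, n − 1)
across **all** samples and then computes within-group pairwise distances.
Euclidean distance on z-scores is the default; a Bray–Curtis option is
provided because both conventions circulate, with each standardized
variable shifted to minimum zero first since Bray–Curtis is undefined on
negative values. The two metrics answer slightly different questions and
the package surfaces the choice rather than resolving it silently.
Mantel tests correlate lower triangles (Pearson by default, Spearman
optionally) with joint row/column permutation of the second matrix,
one-tailed "greater" by default — the convention of the ecological
literature — with a two-sided option.

## The synthetic generator

The generator exists so that every estimator above can be tested against
known truth. It emulates:

* a **lognormal metacommunity** (rank-abundance realism without taxonomic
  identity);
* **neutral assembly** by drawing per-sample frequencies from the
  stationary Sloan Beta distribution and reads multinomially — exactly the
  model `fitNcm()` assumes, which is what makes sharp parameter-recovery
  tests possible;
* **niche assembly** via a smooth synthetic environmental field (linear
  gradient plus a low-frequency random cosine surface, standardized to
  unit variance) and Gaussian niche kernels around per-taxon optima, with
  soil-style variables (SWC, pH, SOC, TN, TP, NH4, NO3) emitted as noisy
  linear transforms of the field;
* **guilds**: sets of taxa jointly scaled by a shared log-normal latent
  factor, giving strong positive rank correlations. Beyond a guild's
  `collapse_level` the factor is drawn independently per taxon, destroying
  the correlation at large scales. With `scale_ramp = TRUE` the factor's
  sd grows linearly with nested level, so member taxa appear uncorrelated
  inside small quadrats and the co-occurrence edges only emerge once the
  sampled extent is wide — the mechanism by which environmental drivers
  that vary over large distances create scale-dependent co-occurrence.
  Ramp plus collapse is the designed generative route to a unimodal
  node–area curve with a controllable tipping point; a flat factor can
  only produce flat-then-falling curves because the within-guild
  correlation is then scale-independent.

Default study conditions: 9 nested levels from 0.5 m side (areas 0.25 m²
to 16 384 m²), 3 plots per group, 4 corner samples per plot and level
(108 samples per group), 500 taxa, 2000 reads per sample; three groups
contrasting a neutral regime with an always-collapsed guild, a neutral
regime with guilds collapsing at level 7, and a niche-filtered regime.
These sizes keep the full pipeline in seconds while leaving all estimators
comfortably identified; the test suite uses the same or smaller sizes and
documents each within its fixtures.

The generator deliberately does **not** emulate: real taxonomic
composition or phylogeny, sequencing error and chimeras, compositional
biases of library preparation, spatial autocorrelation beyond the
environmental field, temporal dynamics, or rare-biosphere tail behaviour
below the detection limit. Passing tests therefore demonstrate estimator
correctness under the stated generative models — not robustness to every
artefact of real amplicon data.

## Numerical conventions and degenerate inputs

* All generators and permutation tests are pure functions of their inputs
  and an integer seed; the RNG state of the session is saved and restored
  around every seeded computation.
* Rarefaction subsamples without replacement to exactly the target depth;
  samples below depth are dropped with a warning, never padded.
* An empty filter result is a warning plus an empty table, not an error —
  downstream code treats zero taxa as an empty network.
* Spearman matrices clip |r| to 1 before the t transform; constant taxa
  are flagged rather than propagating NA.
* The power-model SAR fit retries from three starts before raising an
  error that carries the data ranges; the logarithm model cannot fail.
* NST values are clipped to [0, 1] after the per-pair normalization;
  saturated occurrence tables (every taxon in every sample) make *Nm*
  weakly identified and are warned about.
* Pipeline outputs are written with fixed formatting and no timestamps, so
  identical inputs, configuration and seed reproduce every output file
  byte for byte.

## Known limitations

* The Spearman p-value's t approximation is inaccurate below ~10 samples;
  the NAR guard (`min_samples = 16`) makes this moot for networks, but
  direct `spearmanMatrix()` calls on 5–9 samples should be interpreted
  with care.
* The segmented NAR fit places the break at an observed level; it does not
  interpolate between levels, which is the appropriate resolution for a
  design whose areas are discrete powers of two.
* The NST null model is the proportional-occupancy/fixed-richness variant;
  other null families (fixed-occupancy, swap algorithms) would shift the
  absolute NST value, though not the neutral-vs-niche direction the
  package validates.
* Slope comparison permutes observed points; it does not model
  within-plot autocorrelation beyond the optional plot-level permutation
  unit.
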