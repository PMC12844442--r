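# microscale

Spatial scaling and community-assembly analysis of soil microbial
communities sampled under a **nested quadrat design** — quadrats whose side
doubles at each level (e.g. 0.5 × 0.5 m² up to 2048 × 2048 m²), each smaller
plot lying inside the larger ones. From an OTU count table, nested-plot
metadata and (optionally) soil variables, the package computes:

- **Taxa–area relationship (TAR).** Richness of cumulatively pooled samples
  against area, fitted with the logarithm model *S = c + z log₁₀ A* (closed-form
  OLS) and the power model *S = c Aᶻ* (nonlinear least squares). The slope
  *z* is the spatial turnover rate; slope differences between groups are
  tested by permutation of the pooled (area, richness) points.
- **Node–area relationship (NAR).** At each area, a co-occurrence network is
  built from the samples inside it (Spearman |r| > 0.80, p < 0.05, after a
  0.1 % relative-abundance / 20 % prevalence pre-filter) and the node count
  is tracked against area. A continuous two-piece segmented regression
  classifies the curve as monotonic or unimodal and locates the tipping
  point beyond which co-occurring richness collapses.
- **Community assembly.** The Sloan neutral community model (occurrence
  frequency *F̂ = 1 − I_d(Nm p, Nm(1−p))* fitted for the immigration
  parameter *Nm*, reported with *m = Nm/N* and R²), the normalized
  stochasticity ratio (NST; > 0.5 read as stochastic-assembly dominance)
  against a richness-preserving occupancy null model, and Levins niche
  breadth *B = 1/Σⱼ P²ⱼ*.
- **Diversity and environment.** Richness / Shannon / Gini–Simpson, Bray–Curtis
  beta diversity, within-group environmental heterogeneity on z-scored soil
  variables, and permutation Mantel tests between community and
  environmental distances.
- **A synthetic nested-community generator** with known ground truth
  (migration rate, niche strength, guild correlation structure and its
  spatial collapse), so every stage can be validated end-to-end without
  sequencing data.

The intended users are microbial ecologists studying distance–decay,
species–area scaling and stochastic vs. deterministic assembly in soils or
other spatially structured habitats.

## Worked example

Simulate a neutral community on a 9-level nested design (3 plots, 4
corner samples per level, 2000 reads per sample, migration rate m = 0.1),
then fit the TAR, the neutral model and the NST:

```r
library(microscale)
p     <- makeMetacommunity(S = 500, lognormal_sigma = 2, seed = 1)
frame <- generateNestedDesign(levels = 9, side0 = 0.5, n_plots = 3, groups = "steppe")
otu   <- simulateNeutral(p, frame, N_reads = 2000, m = 0.1, seed = 1)
otu
#> OtuTable: 108 samples x 500 taxa
#>   per-sample totals: 2000 .. 2000 (median 2000)
#>   sparsity: 77.9% zero cells

fitSar(buildTar(otu, frame), "logarithm")
#> SarFit (logarithm model): S = 266.8 + 34.49 log10(A)
#>   z = 34.4927, R^2 = 0.8908, n = 27

fitNcm(otu)
#> NcmFit: Nm = 203.6, m = 0.1018 (N = 2000, d = 0.000346574), R^2 = 0.985, 443 taxa
#>   partition: 29 above / 399 within / 15 below the 95% band

computeNst(otu, frame, n_null = 200, seed = 1)[, c("group", "nst", "se")]
#>    group       nst          se
#> 1 steppe 0.8442909 0.001092206
```

Reading the output: pooled richness grows by ~34.5 OTUs per decade of area
(the turnover rate *z* under the base-10 logarithm model); the neutral fit
recovers the generating migration rate (m̂ = 0.102 vs. the true 0.1) with
R² = 0.985; and NST = 0.84 > 0.5 correctly flags stochastic assembly for a
community that was, by construction, neutrally assembled.

`runPipeline()` chains every stage (rarefaction → filtering → diversity →
TAR → NAR → NCM/NST/niche breadth → Mantel) on TSV inputs and writes one TSV
per stage plus a `run_manifest.json` with all seeds and thresholds;
`inst/scripts/microscale.R` exposes the same stages as shell subcommands
(`simulate`, `run-all`, `tar`, `nar`, `assembly`, `diversity`, `mantel`).

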