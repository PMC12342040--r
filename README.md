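# neutralcore

Community-assembly analysis for enrichment-reactor microbiomes from ASV
count tables: who persists (the core microbiome), who got there by
chance (Sloan's neutral model), and which taxa track an environmental
gradient (a compositional lasso).

The package is aimed at microbial ecologists running selective
enrichments — the motivating system is polyhydroxyalkanoate (PHA)
enrichment at three temperatures sampled over time in triplicate — but
every method takes a generic ASV × sample table with taxonomy, metadata
and an optional rooted tree.

## What it computes

* **Diversity**: analytic rarefied richness `E[S] = Σᵢ (1 − C(N−Nᵢ, n)/C(N, n))`,
  Shannon entropy, Bray–Curtis / Jaccard / unweighted and weighted
  UniFrac distances, classical PCoA, and one-factor PERMANOVA
  (McArdle–Anderson pseudo-F, seeded permutations, exact enumeration for
  small designs, numeric covariates via Gower-matrix regression).
* **Core microbiome**: taxa ranked by `(mean_t o_t + r)/2` where `o_t` is
  occupancy within timepoint t and `r` the fraction of timepoints with
  detection in every replicate; the core is the ranking prefix up to the
  last step whose relative gain in the Bray–Curtis explanatory value
  `E_k = BC(top-k)/BC(all)` exceeds 2%.
* **Neutral assembly**: fits the migration parameter m of the Sloan
  model, where occupancy is predicted from mean relative abundance p via
  `Beta(N m p, N m (1−p))` — either the classic threshold form
  `1 − I_{d/N}(·,·)` or (default) the exact Beta-binomial detection
  probability under read sampling — and classifies taxa as neutral,
  environmentally selected (above the 95% band) or dispersal limited
  (below).
* **CODA-LASSO**: `y = β₀ + Σ βⱼ log xⱼ + ε` with `Σ βⱼ = 0` and an L1
  penalty, solved by exact pairwise coordinate descent (compiled), with
  repeated-CV penalty selection; returns disjoint positively and
  negatively associated signatures.
* **Synthetic data**: a generator that emulates the 3-temperature ×
  4-timepoint × triplicate design (plus a cDNA-like phase) with known
  migration rate, planted core/selected/dispersal-limited taxa and a
  planted zero-sum temperature signal, so every stage is checkable by
  parameter recovery.

## Worked example

```r
library(neutralcore)

sim <- simulate_dataset(simulation_config(seed = 1))
sim$dataset
#> ASV dataset: 300 taxa x 63 samples
#>   read depth: 18933-190133  median 104938
#>   rooted tree with 300 tips
#>   groups: Low=21, Meso=21, Thermo=21

fit <- fit_neutral(sim$dataset, group = "Meso")
fit
#> Sloan neutral model fit (sampling detection): m = 0.02659, N = 86216, d = 1
#>   300 taxa, 12 samples, R2 = 0.754
#>
#> neutral   above   below
#>     245      11      17
```

m is the fitted migration rate (N is the mean read depth standing in for
the local community size, so m is an effective rate on that scale); R² is
the fit of the occupancy-abundance cloud. The 11 "above" taxa sit over
the 95% band — occupancy higher than neutral dispersal explains, i.e.
environmentally selected; they include the 5 planted ones. The 17
"below" include the 5 planted dispersal-limited taxa confined to one
replicate line.

```r
cm <- core_microbiome(sim$dataset, group = "Meso")
cm
#> Core microbiome[Meso]: 27 of 300 taxa (last >2% relative gain rule)
#>   mean Bray-Curtis similarity (all taxa): 0.5923
#>   core: ASV_0137, ASV_0151, ASV_0113, ASV_0210, ASV_0080, ASV_0158, ASV_0177, ASV_0082 ...

all(sim$truth$planted_core_ids %in% cm$core)
#> [1] TRUE
```

The 10 planted persistent taxa occupy the top 10 ranking positions and
the core extends to 27 taxa before additional members stop adding 2%
explanatory value.

```r
dna <- sim$dataset$metadata$phase == "DNA-enrichment"
d <- jaccard_distance(sim$dataset$counts[, dna])
g <- setNames(sim$dataset$metadata$group[dna], colnames(sim$dataset$counts)[dna])
permanova(d, g, permutations = 999, seed = 1, name = "group")
#> PERMANOVA [group]: pseudo-F(2,33) = 5.895, R2 = 0.263, p = 0.001 (999 permutations)
```

Temperature groups share their dominant taxa but differ in the
sub-dominant fraction, so presence-based metrics separate them sharply
(p at the permutation floor).

```r
sig <- temperature_signature(sim$dataset, seed = 1)   # CODA-LASSO
```

returns the genera whose log-abundance contrasts predict the temperature
covariate, split into positively and negatively associated sets.

A command-line wrapper covers the same pipeline
(`inst/scripts/neutralcore`, subcommands `simulate`, `preprocess`,
`diversity`, `core`, `neutral`, `codalasso`, `run-all`).

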