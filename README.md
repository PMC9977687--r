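# devocomp

Comparative developmental transcriptomics in R: given gene × stage
expression time courses for two or more species plus an orthology map,
`devocomp` asks *when* each species uses its shared genes — and where the
timing has evolved. It is aimed at evo-devo groups comparing embryonic,
larval and juvenile transcriptomes across lineages with different life
cycles (e.g. feeding vs non-feeding larvae vs direct development), where
the questions are: which co-expression programmes are conserved, which
orthologues have heterochronically shifted between phases, and which
developmental stages correspond across species.

## What it computes

**Soft clustering of stage profiles.** Normalized profiles are z-scored
per gene and clustered by fuzzy c-means (membership update ∝
d<sup>−2/(m−1)</sup>, centroids as u<sup>m</sup>-weighted means). The
cluster number is chosen by the knee of the minimum centroid distance
d<sub>min</sub>(k), and the fuzzifier m defaults to the
dimensionality-based estimate used in soft-clustering practice.

**Orthogroup overlap and relative similarity.** Every cluster pair across
two species is tested for orthogroup overlap with an upper-tail
hypergeometric test (BH-adjusted). Clusters are classed early or late by
the life-cycle phase of their centroid peak, and each quadrant q of
cluster pairs is summarized by the relative similarity

&nbsp;&nbsp;&nbsp;&nbsp;RS<sub>q</sub> = mean(−log₁₀ p<sub>adj</sub>)<sub>q</sub> / mean(−log₁₀ p<sub>adj</sub>)<sub>total</sub>,

with RS > 1 marking higher-than-average overlap. One-to-one orthologue
pairs sitting in an early cluster in one species and a late cluster in
the other are the candidate heterochronic shifts.

**Jensen–Shannon divergence stage matching.** TPM columns are quantile
transformed, restricted to the one-to-one orthologue set and simplex
normalized; each stage pair gets

&nbsp;&nbsp;&nbsp;&nbsp;JSD(P‖Q) = ½ Σ p log₂(p/m) + ½ Σ q log₂(q/m), m = (p+q)/2,

in bits, bootstrapped over the orthologue set (250 replicates), adjusted
by the orthologue count and min–max normalized globally (JSD_norm) or per
comparison (relative JSD). The per-orthologue terms (gwJSD) sum exactly
to the JSD; genes with gwJSD below 25% of the mode of the gwJSD density
are reported as similarity drivers.

**Gene-label analytics.** Two-tailed Fisher tests of TF-class and
phylostratum representation per cluster, 75th-percentile phylostratum
expression summaries on quantile-normalized matrices, tissue-restricted
anterior / posterior gene sets from an adult tissue panel (strict TPM > 2
exclusivity rule), and per-stage Student t contrasts of two gene sets.

**Synthetic data.** A generator plants archetypes (Gaussian activation
bumps), a shared orthologue core, heterochronically shifted orthologues,
TF/phylostratum label structure, and negative-binomial count noise, with
a truth bundle, so the whole pipeline is testable without downloads.

## Worked example

```r
library(devocomp)

cfg    <- simulation_config(seed = 1)          # default 2-species world
bundle <- simulate_dataset(cfg)
bundle$expression$species_a$counts
#> ExpressionMatrix [species_a] 3300 genes x 20 columns, layer=counts
#>   stages: s01, s02, ..., s10   (2 replicates per stage)

z    <- standardize_profiles(size_factor_normalize(bundle$expression$species_a$counts))
scan <- min_centroid_distance(z, 2:8, seed = 1, restarts = 5)
(k   <- select_k_elbow(scan))
#> [1] 5                                        # d_min collapses after k = 5
model <- fuzzy_cmeans(z, k, seed = 1, restarts = 5)
model
#> ClusterModel: k=5, m=1.314, 3300 genes, objective=2245
```

The five recovered clusters match the five planted archetypes. Running
the full pipeline (`run_pipeline(run_config(sim = cfg, seed = 1), out)`)
prints the quadrant summary

```
     quadrant n_pairs mean_nlp    rs
1 early-early       4      150 2.500
2  early-late       6        0 0.000
3  late-early       6        0 0.000
4   late-late       9      100 1.667
```

— early clusters are the most conserved (RS 2.5), and the late–late mean
is diluted across the more numerous late programmes. Of 150 planted
shifted orthologues the early/late quadrant rule recovers 151 candidates,
150 of them true (precision 0.993, recall 1.000). The relative JSD grid
matches stages almost perfectly along the diagonal:

```
jsd_raw(c(0.5, 0.5), c(1, 0))
#> [1] 0.3112781        # bits
```

## Command line

```sh
inst/cli/devocomp simulate --out bundle_dir --seed 1
inst/cli/devocomp cluster  --counts bundle_dir/species_a_counts.tsv --out cl --k-range 2:8 --seed 1
inst/cli/devocomp run      --out results_dir --seed 1
```

Every output table is TSV with a `# devocomp <version> seed=<n>` header;
reruns with the same seed are byte-identical.

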