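---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each
statistic assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic generator does and does
not emulate, and where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## The setting

Developmental transcriptomes of different species cannot be compared
stage by stage: stage counts differ, absolute expression scales differ,
and the interesting biology is precisely that the *timing* of shared
programmes evolves (heterochrony). `devocomp` therefore works with three
complementary representations of a stage series: z-scored per-gene
profiles (for clustering temporal shapes), orthogroup sets per cluster
(for cross-species overlap tests), and per-stage probability
distributions over one-to-one orthologues (for divergence-based stage
matching).

## Expression layers and preprocessing

* **Expressed-gene rule.** A gene is expressed when its abundance is
  *strictly above* 2 TPM at one or more stages. The strict reading of
  "above" is a deliberate choice — a boundary gene at exactly 2.0 TPM is
  excluded — and both the threshold and the rule are arguments, not
  constants. Replicates are averaged on the TPM layer before
  thresholding; whether thresholding should happen per replicate or per
  stage mean is genuinely undetermined, and the per-stage-mean choice
  was made for determinism (one decision, applied everywhere).
* **Size-factor normalization** is the classic median-of-ratios scheme:
  a pseudo-reference gene is the geometric mean of each all-positive
  gene across columns (computed in log space for stability), and each
  column's size factor is the median ratio against it. It is plumbing —
  the package consumes normalized matrices and performs no differential
  expression testing.
* **Quantile transform** (per stage column): value with mean-tie rank r
  among n genes becomes (r − 1)/(n − 1), i.e. the uniform reference on
  [0, 1]. The reference distribution was an open choice (uniform vs
  normal); uniform was chosen because the downstream divergence only
  needs columns to share a marginal distribution, and the uniform grid
  makes the simplex projection transparent. Ties receive the mean rank
  so that equal abundances stay equal.
* **Quantile normalization** (across samples) replaces each column's
  sorted values by the row-wise mean of all sorted columns. It is
  idempotent and makes column multisets identical; it is used only for
  the phylostratum expression summaries.

## Soft clustering

Profiles are z-scored per gene with the n − 1 denominator (the sample
SD; this reproduces the worked convention (1,2,3) → (−1,0,1) and is what
the established soft-clustering tooling does). Zero-variance profiles
are removed with a logged count.

Fuzzy c-means minimizes Σᵢ Σ_c uᵢ_c^m ‖xᵢ − μ_c‖² under Σ_c uᵢ_c = 1.
Parameters:

* **Fuzzifier m** (> 1): not fixed a priori; the default is the
  empirical dimensionality-based estimate of Schwämmle & Jensen (2010),
  m = 1 + (1418/N + 22.05) D⁻² + (12.33/N + 0.243) D^(−0.0406 ln N − 0.1134),
  always recorded in the fitted model so a run can be reproduced.
* **tol = 1e−6** on the maximum centroid shift, **max_iter = 1000**,
  **restarts = 5** random initializations (best final objective wins).
  These are convergence-safety values for desk-scale data; the restart
  count matters in practice — the d_min(k) curve is noticeably smoother
  at 5 restarts than at 2, which stabilizes the elbow.
* **Distance** is Euclidean in z-score space, the standard choice for
  standardized profiles.

**Choosing k.** The minimum pairwise centroid distance d_min(k)
collapses once k exceeds the number of genuine temporal programmes
(two centroids are forced to share one). The selector returns the knee:
the interior k whose following drop most exceeds its preceding one.
Two numerical details are deliberate. First, the sign: the literal
"maximum second difference" statistic peaks one step *after* the cliff,
so the selector maximizes the negative second difference, which lands on
the last k before the collapse (this is also what the worked example in
the build contract demands). Second, d_min is not always monotone —
restarts can make d_min(3) exceed d_min(2) — and a preceding *rise*
would otherwise inflate the kink statistic; a negative preceding drop is
therefore clamped to zero. On a perfectly linear decay every interior
point ties and the smallest interior k is returned (documented
degenerate behaviour: there is no elbow to find).

Hardening is argmax with lowest-index tie-break, with an optional
minimum-membership filter whose exclusions are logged.

## Orthogroup overlap, RS and heterochrony

* **Universe.** The hypergeometric universe for a species pair is the
  set of orthogroups represented in *both* species' clustered gene sets.
  This was an open question; the intersection is the only choice under
  which every tested orthogroup could in principle have appeared in
  either cluster of a pair, and it is an explicit argument (`universe`)
  so union- or global-universe analyses remain possible.
* **Test.** p = P(X ≥ overlap), X ~ Hypergeometric(N = universe,
  K = n_A, n = n_B), BH-adjusted per species-pair comparison (the
  adjustment family mirrors one heatmap = one comparison; Bonferroni is
  available).
* **RS.** Adjusted p-values are floored at 1e−300 before −log₁₀ to
  avoid infinities; the floor means extremely significant pairs saturate
  at 300, which is intentional — RS is a *relative* statistic and the
  saturation keeps single astronomically small p-values from dominating
  a quadrant mean. The weighted identity Σ_q n_q·RS_q = N_total holds
  by construction and is property-tested.
* **Cluster phase classes** come from the life-cycle phase of the stage
  where a cluster's centroid peaks (pre-larval/larval → early,
  post-larval → late, adult-tissue → excluded). Shifted-orthologue
  extraction then takes the one-to-one pairs in a requested quadrant;
  both canned directions and custom phase pairs are supported.

## The JSD stack

The build's displayed divergence is JSD in bits (log₂) with the
0·log(0/x) ≡ 0 convention; it is symmetric, bounded by [0, 1] bits and
zero iff the distributions agree. How quantile-transformed values become
probabilities p_i was not specified anywhere; the package projects each
stage column, restricted to the one-to-one orthologue set, onto the
simplex by dividing by its sum. This is the minimal interpretation that
makes the displayed formula well-defined, and it is logged here as an
interpretation rather than a given.

* **Bootstrap**: the resampling unit is the orthologue *pair*, drawn
  with replacement at the original set size, B = 250 by default;
  per-cell means and SDs are reported and the whole procedure is
  deterministic given a seed.
* **Adjusted / normalized / relative**: the bootstrap-mean grid is first
  divided by the comparison's orthologue count (mean first, then
  adjustment — the stated ordering), then min–max rescaled with the
  extrema pooled over all comparisons (normalized) or within one
  (relative). A degenerate collection (max = min) is an error, not a
  silent zero grid.
* **Gene-wise JSD** is the per-orthologue term of the same sum (each
  term is non-negative by the log-sum inequality; the decomposition
  identity Σ gwJSD = JSD is tested to 1e−12).
* **Similarity drivers**: Gaussian kernel density (Silverman's rule
  bandwidth, 512 evaluation points from 0 to the maximum), mode = grid
  point of maximal density, threshold = 0.25 × mode, drivers = genes
  strictly below. All three knobs (mode fraction, bandwidth rule, grid
  size) are arguments. Since the Silverman bandwidth scales with the
  data, the rule is scale-equivariant: scaling all gwJSD values scales
  the threshold identically. The stage pairs to run it on are
  configuration, not code.

## Gene-label analytics

Fisher tests are two-tailed with the standard convention (sum of
probabilities of all fixed-margin tables no more probable than the
observed one) — stated because conventions differ. The per-stage
contrast of two gene sets uses the pooled-variance Student t by default
(Welch via `var_equal = FALSE`), Bonferroni-corrected across stages.
The 75th percentile in phylostratum summaries uses linear interpolation
between order statistics (R type 7) — quantile conventions differ enough
across tools that this is worth pinning down. The tissue-restriction
rule is strict: expressed above threshold in both designated tissues
and at-or-below it in *every* other panel tissue; whether the
exclusivity clause should span all tissues or a subset was not
determinable, so the strict reading is implemented and the designated
groups are arguments. The 36-class TF catalogue ships as an editable
TSV (`inst/extdata/tf_class_catalogue_synthetic.tsv`) whose identifier
lists are synthetic placeholders — the file format, not its content, is
the contract; no live database lookups are performed.

## The synthetic world

The generator emulates the *structure* of a multi-species developmental
RNA-seq study: 2 species × 10 ordered duplicate-sampled stages by
default (5–14 supported, including unequal grids mapped linearly onto
each other), 3,000 single-copy orthologues plus 300 species-specific
genes per species, and five temporal archetypes — Gaussian activation
bumps over stage ordinals. Defaults, chosen once:

* **Archetype layout**: two early archetypes (peaks at ordinals 1 and
  b − 1, b = first post-larval stage) and three late ones spread over
  the late phase. Late development gets more archetypes deliberately:
  organogenesis diversifies programmes, and this asymmetry is what makes
  the early–early quadrant *strictly* maximal in RS rather than tied
  with late–late. Peaks stay off the phase boundary so cluster phase
  classes are stable under noise.
* **Noise**: negative-binomial counts with dispersion 0.1 (a standard
  bulk RNA-seq value), log-normal library sizes (sdlog 0.1), per-gene
  log-normal amplitudes (sdlog 0.25) and peak jitter (SD 0.2 stages).
  With amplitude 150 over baseline 5 the peak-over-baseline signal is
  about three count-noise SDs at the peak — the separation regime the
  recovery guarantees are stated at.
* **Per-gene baselines** are log-normal (sdlog 1) and *shared across
  species for orthologues*, emulating conserved per-gene expression
  levels. This matters: with a flat common baseline all background genes
  are exchangeable, their ranks are pure noise, and the stage-wise JSD
  noise floor varies enough between stages to swamp the adjacent-stage
  signal — an artifact of an unrealistically degenerate world, removed
  by giving genes their own conserved dynamic range.
* **Heterochrony**: 5% of orthologues shifted by 3 stages, drawn from
  donor archetypes whose shifted peak lands on the other side of the
  early/late boundary. A planted "early-to-late shift" that stays within
  the early phase would be undetectable by the quadrant rule *by
  definition*, so the generator only plants genuine phase changes; the
  shifted fraction, size and direction are all configuration.
* **Labels**: genes are TFs with probability 0.08 (tripled in one
  designated archetype, the planted enrichment), classes drawn from the
  36-class catalogue; phylostrata are drawn from four ordered levels
  with fixed frequencies, species-specific genes always youngest.

What a green test does **not** establish: the generator produces
independent NB counts around smooth unimodal bumps — no bimodal
activation, no correlated gene modules beyond the archetypes, no 3′
bias, no isoform structure, no batch effects, and TPM is computed
without gene-length weighting (lengths are irrelevant to every
statistic in scope). Recovery results on this world bound what the
pipeline can do under its own assumptions; they are not evidence about
any particular real dataset.

## Determinism and numerics

All randomness flows from one root seed, split per stage with a fixed
affine rule (children stay below 2³¹); every stochastic function takes
an explicit seed and restores the caller's RNG state. Pipeline tables
are written with 6 significant digits and a version + seed header, so
two runs with one seed are byte-identical — this is itself an
acceptance criterion. Membership rows are renormalized exactly once per
iteration; squared distances are clamped at 0 before the negative-power
membership update, and a gene coinciding with a centroid receives all
its membership on the coincident centroids.

## Known limitations

* The elbow selector assumes one dominant cliff in d_min(k); data with
  several comparable programme scales (nested archetypes) can produce
  ambiguous knees, and on real data the selected k should be inspected
  against the scan table the CLI writes out.
* RS saturation at the p-floor means quadrant means compare *counts* of
  saturated pairs once overlaps are extreme; at desk scale this is the
  intended behaviour, but with very small universes the floor is never
  reached and RS behaves as a plain ratio of means.
* The JSD stage matching assumes the quantile-transformed columns are
  comparable, i.e. roughly equal numbers of expressed orthologues per
  stage; stages with pathological dropout would need filtering first.
* `read_bundle` exists to reload simulated bundles (with truth); the
  pipeline does not pretend to analyse arbitrary external data end to
  end without a truth bundle — the module functions are the API for
  that.
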