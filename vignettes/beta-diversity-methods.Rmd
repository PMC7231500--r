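---
title: "Methods: abundance-based beta diversity of reef-basin assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abundance-based beta diversity of reef-basin assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefbeta)
```

## The problem

Beta diversity — the compositional variation among communities — is the
quantity this package measures, tests, and simulates. The motivating
setting is reef-associated soft-bottom macrobenthos: small numbers of
sites (8–16), specimen counts per sample ranging from a few dozen to a
few thousand, strongly uneven species-abundance distributions, and a
shared regional species pool. The analytical questions are always the
same: how dissimilar are the communities, could that dissimilarity be a
sampling artefact of random assembly from the regional pool, and is it
structured by water depth, geographic distance, or age?

All computations start from an `abundance_table`, a samples × taxa matrix
of non-negative integer specimen counts. Validation drops taxa with zero
total count, so proportion vectors never carry all-zero columns, and
refuses empty samples.

## The core statistic

Pairwise proportional dissimilarity (PPD, also called relative
Bray–Curtis) between samples $j$ and $k$ is

$$d_{jk} = 1 - \sum_i \min(x_{ij},\, x_{ik}),$$

where $x_{ij}$ is the *proportional* abundance of taxon $i$ in sample
$j$. Because counts are normalised per sample before the sum of minima,
the measure is invariant to sample size — the property that makes it
usable across samples of 33 and 3,969 specimens alike. It ranges from 0
(identical composition) to 1 (no shared taxa) and equals the Bray–Curtis
dissimilarity of the proportion-normalised vectors (a test cross-checks
this against `vegan::vegdist` to 1e-12). PPD is a semimetric: the
triangle inequality can fail, which is why the ordination helpers treat
negative principal-coordinate eigenvalues as expected output rather than
an error. Nothing in the package assumes metricity.

The modified Gower measure is provided as the alternative abundance
metric: abundances are transformed as $t(a) = \log_b(a) + 1$ for $a > 0$
and $t(0) = 0$, and the dissimilarity is the mean absolute difference of
transformed abundances over taxa present in at least one of the two
samples (double zeros excluded). The logarithm base is a genuine
convention — it rescales the measure — and is not fixed by common usage;
the package defaults to base 2 and prints the base in the metric label.
Whenever modified-Gower values are compared across studies the base must
match.

### Sample preparation

Counting protocols in this field often record only the most abundant
species per sample. `top_n_reduce()` implements the top-$n$ rule with
ties included: every taxon tied with the count at rank $n$ is retained,
so a "top 10" sample can legitimately carry 11 or 12 taxa (both cases
occur in the packaged Triassic counts and are asserted in the tests).
The operation is idempotent and never retains a taxon rarer than a
dropped one. `exclude_taxa()` removes taxa counted inconsistently across
datasets (e.g. foraminifers) and logs the per-sample removals;
`merge_by_site()` combines replicate samples taken metres apart,
conserving specimen totals exactly and refusing (or resolving, under
`conflict = "first"`) contradictory metadata.

Relative water-depth ranking for fossil samples (`infer_depth_rank()`)
converts ecological attributes — suspension/deposit feeder ratio,
carnivore/grazer ratio, proportion of articulated bivalves, gastropod
abundance and diversity, encrustation, reef-builder fragments — to
average ranks, orients each by a fixed direction table (deeper-positive),
weights, sums, and centres to mean zero. The attribute weighting used in
the original depth assignments is not published in full; the package
defaults to equal weights and takes weights as an explicit argument, so
the default scores should be read as a reproducible stand-in, not a
reconstruction. The packaged metadata ships the published depth ranks
themselves, which downstream analyses use directly.

## The null model

The stochasticity test asks: how much mean PPD would we see if the
communities were assembled at random from the regional pool at the
observed sampling effort? `gamma_pool()` sums counts over samples into
one regional abundance vector; each of (by default) 1,000 iterations
draws one synthetic dataset — an independent multinomial sample per site,
of the observed site's size, with the pool proportions as weights — and
records its mean pairwise PPD. Resampling is with replacement: the
multinomial is the natural model for "resample using the proportional
abundance vector as probability weights", and a without-replacement
variant would be impossible at sites whose size approaches the pool.

The summary reports the null mean with both the standard deviation of the
per-iteration means and its standard error (sd/√iterations); published
"±" values of order 0.0004 at 1,000 iterations are standard errors, and
the package labels both to avoid ambiguity. The empirical p-value uses
the add-one correction $(b+1)/(m+1)$ on the upper tail (observed ≥ null),
with a two-sided option, and a standardized effect size
(observed − null mean)/null sd is attached. A single integer seed drives
a splittable stream: iteration $i$ derives its own sub-seed, so results
are reproducible independent of how many iterations are requested.

A calibration property is part of the test suite: for data genuinely
generated by the null model itself, the observed mean PPD falls inside
the central 95% of the per-iteration means in roughly 95% of replicate
experiments, and the null mean shrinks monotonically as sample sizes
grow (less multinomial noise).

## Alpha diversity

Per-sample indices are the Berger–Parker dominance (proportion of the
most abundant taxon), the Shannon index $H$ in natural-log units, and
Pielou's evenness $J = H/\ln s$, undefined for single-taxon samples.
$J$ is invariant to the logarithm base used consistently, which a test
asserts. Indices are computed on whatever table is passed; the pipeline
computes them on the top-10-reduced table to match the counting
protocol of the packaged data. One documented discrepancy: the evenness
values printed alongside the packaged Triassic metadata are **not**
reproducible from the top-10 counts (they give ≈0.48 and ≈0.93 where
0.29 and 0.54 are printed); they were evidently computed on the full,
unreduced samples, whose complete species lists are unpublished. The
packaged `evenness` column is therefore carried as provenance and never
asserted against computed values.

## Spatial and gradient analyses

Distance decay is the correlation between pairwise dissimilarity and
pairwise geographic distance over the $n(n-1)/2$ sample pairs. Distances
are great-circle (haversine, sphere radius 6371 km, via the
**geosphere** package); an equirectangular option exists for sensitivity
checks, and because Spearman's rho depends only on rank order, any
monotone distance formula gives the identical rho at these spatial
extents (asserted on the packaged data). The p-values reported are the
standard large-sample approximations, exactly as such analyses usually
print them, with an explicit caveat: the pairs are not independent, so
these p-values are anti-conservative. A Mantel-style permutation p is
available (`permutations > 0`) for comparison but is not used for
table parity.

Depth-group construction follows the published convention: a rank-based
median split for two groups, and shallowest-half / remainder-halved
(4/2/2 at eight sites) for three. The Kruskal–Wallis depth test pools
each group's counts into one composition and compares the rank
distributions of the pooled per-taxon abundances (positive counts only)
across groups — the most literal reading of "community composition data
within a depth group are combined"; because that reading is not unique,
the published Kruskal–Wallis p-values are treated as reference only.

## Inference on dissimilarity matrices

`permanova()` implements one-factor PERMANOVA from first principles:
$SS_{total} = \tfrac1N \sum_{i<j} d_{ij}^2$, within-group sums
analogously per group, pseudo-$F$ from the usual degrees of freedom, and
a permutation p counting the observed assignment among label
permutations. The partition is verified in tests against both a
brute-force double loop (1e-12) and `vegan::adonis2` (1e-10). Only the
one-factor design is provided, matching how depth and age groups are
tested separately. Note the degenerate behaviour on a constant
dissimilarity matrix: every permutation yields pseudo-$F = 1$ and
$R^2 = (a-1)/(N-1)$ (its null expectation), not 0.

`pcoa()` double-centres $-d^2/2$ and eigendecomposes, retaining and
reporting negative eigenvalues. `dispersion_of_homogeneity()` measures
distances to group centroids in that embedding with the standard
imaginary-axis correction (squared distance = positive-axis part minus
negative-axis part, floored at zero); it agrees with `vegan::betadisper`
(type `"centroid"`) to 1e-6. `nmds()` wraps vegan's non-metric MDS
engine (Kruskal stress-1, isotonic regression with primary tie
treatment, best of 20 random starts plus a metric start, deterministic
under a seed). Stress values are inherently implementation- and
start-dependent — local optima differ — so the package's own tests only
bound stress from above and assert that it is non-increasing in the
embedding dimension; small stress differences between software packages
are expected and meaningless.

## The synthetic metacommunity generator

The generator exists so that every pipeline stage can be exercised, and
the null model and gradient tests validated by parameter recovery,
without any external data. It emulates the statistical structure the
analyses assume: a regional pool of `gamma_richness` taxa with a
geometric (default) or log-series rank-abundance distribution tuned by a
`dominance` parameter; per-site expected compositions obtained by
multiplying the pool weights by

* a Gaussian depth-niche kernel around each taxon's depth optimum
  (optima uniform over the depth range; kernel width = depth range /
  (2 × `niche_strength`), so 0 means depth-blind and larger values mean
  sharper tracking), and
* a site-specific log-normal distortion with log-sd 6 × `idiosyncrasy`,
  a phenomenological stand-in for priority effects: it preserves the
  pool's support while allowing near-disjoint realised communities, and
  at `idiosyncrasy = 1` the limit is forced exactly by partitioning the
  taxa round-robin among sites;

then drawing one multinomial sample per site at the configured sizes.
Coordinates are drawn independently of composition, so distance decay is
absent by construction (a property test checks that the median decay
correlation over replicates is near zero). All randomness flows from one
seed through named substreams (niches, distortion, sampling,
coordinates), so outputs are byte-identical across runs.

Defaults follow the study design the package ships: `make_cassian_like()`
presets eight sites with the published specimen totals (315, 216, 558,
213, 229, 33, 296, 1026), published depth ranks and coordinates, a
60-taxon pool, geometric dominance 0.3 (Berger–Parker of the pool ≈ 0.3,
inside the published 0.16–0.73 per-sample range), and high idiosyncrasy
0.9, reflecting the priority-effect interpretation of the observed very
high beta diversity. What the generator does **not** emulate: taphonomy
and time-averaging, temporal turnover (age acts only as a label),
mechanistic colonisation/extinction dynamics, and spatial autocorrelation
of environment. Passing parameter-recovery tests therefore show that the
*statistics* behave as designed, not that real assemblages follow this
generative model.

Two recovery properties anchor the generator: the rank order of observed
mean PPD reproduces the rank order of true idiosyncrasy across five
levels (20 replicates each), and a median depth-split PERMANOVA detects
strong niches (`niche_strength = 6`, 16 sites) with ≥80% power while
keeping ≈5% rejections when both structure parameters are zero.

## Numerical conventions and problem sizes

* Table-parity comparisons round half away from zero to two decimals
  (`round_half_up()`), matching how printed tables round; analysis
  functions always return full precision.
* Mean-dissimilarity standard errors are sd of the contributing pairwise
  values / √(number of pairs); they quantify spread among non-independent
  pairs.
* The per-iteration seed is `(seed × 69069 + i × 12345) mod (2^31 − 1)`,
  exact in double arithmetic.
* The mangrove-channel depth printed as "<1 m" is stored as 0.5 m in the
  packaged metadata.
* Property-style tests run at deliberately small problem sizes chosen to
  make the checks sharp but quick: 100 generator draws for rank
  recovery, 25/60 replicates at 199 permutations for power and type-I
  rates, 200 replicates at 99 permutations for p-uniformity, 40
  replicates at 100 iterations for null-model calibration. These sizes
  are stated here because they set the Monte-Carlo tolerances the tests
  use; they are the package's own choices.

## Known limitations

* Printed dissimilarity matrices carry only two decimals. Averages of
  such matrices are fine, but *rank-based* statistics can be distorted:
  in the packaged modern-reef matrix eight pairs print as exactly 1.00,
  and the Spearman distance-decay correlation of the full-precision data
  (published as 0.05) is not recoverable from the rounded values (which
  give ≈ 0.00, while the Pearson correlation does reproduce). The
  corresponding check in the test suite is kept at the published value
  and documents this as the cause of its failure.
* Pooled-group dissimilarities are computed on pooled already-reduced
  counts without a second top-n reduction (a `reduce_n` switch exists);
  whether published group values re-reduced after pooling is not
  determinable from the main text.
* The depth-attribute weighting defaults to equal weights (see above).
* PERMANOVA is one-factor only; no strata, no nested designs.
* No incidence-based (Jaccard/Sørensen) indices: the package is
  deliberately abundance-based, and no richness estimators or
  rarefaction are included.
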