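# reefbeta

Abundance-based beta diversity for benthic community samples: pairwise
proportional dissimilarity, a gamma-pool null model for random assembly,
alpha-diversity indices, distance decay, and inference on dissimilarity
matrices (PERMANOVA, NMDS, multivariate dispersion) — with a synthetic
metacommunity generator for validation. Written for quantitative community
ecologists and paleoecologists comparing fossil and modern soft-bottom
assemblages, where sample sizes are wildly uneven and abundance-based
measures are the defensible choice.

## The statistic at the core

Pairwise proportional dissimilarity (PPD; relative Bray–Curtis) between
samples *j* and *k* is

    d_jk = 1 − Σ_i min(x_ij, x_ik)

with *x_ij* the proportional abundance of taxon *i* in sample *j*. It is
invariant to sample size, ranges from 0 (identical composition) to 1 (no
shared taxa), and is a semimetric. Beta diversity is summarised as the mean
of the n(n−1)/2 pairwise values (± standard error). Whether that beta
diversity could arise from random assembly alone is tested with a null
model: all samples are pooled into one regional (gamma) abundance vector,
synthetic datasets are drawn from it by multinomial resampling at the
observed sample sizes, and the observed mean PPD is compared with the
per-iteration null means.

The package ships the published specimen counts, metadata, and pairwise
dissimilarity matrices of a Triassic (Cassian Formation, Dolomites) and a
modern (Northern Bay of Safaga, Red Sea) reef-basin dataset as plain-text
fixtures, and reproduces the headline numbers of those tables in its test
suite.

## Worked example

```r
library(reefbeta)

tab <- cassian_new4()             # four Triassic samples, top-10 counts
d   <- dissimilarity_matrix(tab)  # pairwise PPD
round_half_up(unclass(d), 2)
#>                   Costalaresc Picolbach Rumerlo cliff Rumerlo ski slope
#> Costalaresc              0.00      0.83          1.00              0.99
#> Picolbach                0.83      0.00          0.93              1.00
#> Rumerlo cliff            1.00      0.93          0.00              0.67
#> Rumerlo ski slope        0.99      1.00          0.67              0.00

mean_dissimilarity(cassian_ppd(), "all")   # published 8-sample matrix
#> mean dissimilarity (all): 0.9111 +/- 0.0214 (se), 28 pairs

null_distribution(tab, iterations = 1000, seed = 1)
#> gamma-pool null model (1000 iterations, seed 1)
#>   observed mean PPD: 0.9022
#>   null mean PPD:     0.2437 +/- 0.0008 (se; sd 0.0257)
#>   empirical p (greater): 0.000999   SES: 25.65
```

Reading: the four new samples share almost no taxa (all pairwise PPD ≥
0.67), the full eight-sample dataset has a mean PPD of 0.91 ± 0.02, and
random assembly from the pooled species list at the observed sample sizes
would produce a mean PPD around 0.24 — the observed beta diversity is far
beyond stochastic expectation (standardized effect size ≈ 26).

Downstream: `distance_decay()` correlates PPD with great-circle distance,
`permanova()` partitions squared dissimilarities over depth or age groups,
`nmds()` embeds the samples (Kruskal stress-1), and
`dispersion_of_homogeneity()` measures group spread with the
imaginary-axis correction. `generate_metacommunity()` simulates
metacommunities with tunable depth niches and site idiosyncrasy for
parameter-recovery checks; `run_analysis()` drives the whole pipeline from
a YAML config (see `inst/scripts/reefbeta.R` for a command-line wrapper).
The methods vignette (`vignettes/beta-diversity-methods.Rmd`) documents the
models, conventions, and known limitations.

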