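---
title: "Multi-bin rarefying: testing alpha diversity under unequal library sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-bin rarefying: testing alpha diversity under unequal library sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarebin)
```

## The problem

Observed alpha diversity of a TCR repertoire — the number of distinct
clonotypes and how evenly reads are spread over them — grows with sequencing
effort. In bulk AIRR-seq cohorts, library sizes routinely span three orders
of magnitude, so a naive diversity–phenotype regression largely measures
which phenotype group happened to be sequenced deeper. The common remedy,
rarefying every sample down to one global depth ("overall rarefying"),
discards most reads of deep samples, drops samples below the chosen level
entirely, and — because the depth–diversity relationship is nonlinear — does
not actually remove the correlation between rarefied diversity and the
original library size.

## The multi-bin procedure

`multibin_alpha_test()` implements a stratified alternative:

1. **Bin.** Choose interior thresholds $c_1 < \dots < c_{K-1}$ and set
   $c_0 = \min_i L_i$, $c_K = \max_i L_i$, where $L_i$ is sample $i$'s
   library size. Sample $i$ goes to bin $M_k$ when
   $c_{k-1} \le L_i < c_k$ (top bin closed). `assign_bins()` applies this
   rule, drops empty bins with a warning, and can exclude failed samples via
   `min_depth` so one ultra-shallow library cannot drag the bottom rarefying
   level down.
2. **Rarefy within bins.** Every sample is subsampled without replacement to
   its own bin's lower bound $L^*_k = c_{k-1}$ (`within_bin_alpha()`). Deep
   samples therefore keep a deep standardization level; information loss is
   limited to the within-bin depth spread.
3. **Test within bins.** Alpha diversity is regressed on the covariate by
   univariate OLS within each bin, giving the slope $\hat\tau_k$, its
   squared standard error $V_k$, and a two-sided $t$-test. For a 0/1
   covariate this is exactly the equal-variance two-sample $t$-test.
4. **Pool.** Under the fixed-effect assumption of one common effect $\tau$,
   the bins are combined as
   $\hat\tau = \sum_k \omega_k \hat\tau_k / \sum_k \omega_k$ and tested with
   the Wald statistic
   $$W = \frac{\left(\sum_k \omega_k \hat\tau_k\right)^2}
              {\sum_k \omega_k^2 V_k} \sim \chi^2_1 \text{ under } H_0,$$
   with equal weights ($\omega_k = 1$), sample-size weights
   ($\omega_k = n_k$), or inverse-variance weights ($\omega_k = 1/V_k$,
   optimal for power under homogeneity and the recommended default).

The fixed-effect model is appropriate because library size is a technical
artifact: there is no biological reason for the diversity–phenotype effect
to differ between depth strata. Random-effects pooling is deliberately out
of scope.

### Choosing thresholds

Thresholds are user-chosen, guided by three rules of thumb: bins should be
narrow enough that samples are comparable, each bin needs an adequate sample
count, and within each bin the rarefied diversity should no longer correlate
with library size. `bin_diagnostics()` reports the within-bin and overall
Spearman correlations (average ranks on ties) to support that choice. For
deep human cohorts a layout like cuts at
$10^6, 2\times10^6, 4\times10^6, 8\times10^6, 10^7$ (six bins) is typical;
the package applies whatever cuts are supplied.

## Diversity measures

Four measures are provided (`alpha_diversity()`): observed richness;
bias-corrected Chao1 $S_{obs} + f_1(f_1-1)/(2(f_2+1))$ with $f_1, f_2$ the
singleton/doubleton counts (the $f_2{+}1$ form needs no special case at
$f_2 = 0$); the Shannon index in natural-log units (the base only rescales
and Pielou's ratio is base-invariant); and Pielou's evenness $H/\log S$.
Pielou is undefined on a single-clonotype sample; the package returns `NA`
and excludes such replicates/samples from means and regressions with a
warning rather than silently substituting 0 or 1, which would bias tests.
Bray–Curtis dissimilarity is included for checking that two simulation pools
are effectively disjoint.

## Rarefaction internals

A rarefied sample at depth $m$ is an exact multivariate-hypergeometric draw
of $m$ of the $N$ reads. It is generated category-by-category from the
conditional hypergeometric distributions in compiled code (`src/rarefy.cpp`,
using R's own RNG), so time and memory are $O(\text{clonotypes})$ and
independent of $N$ — libraries of $4\times10^7$ reads rarefy in
microseconds without ever materializing a read vector. The closed-form
expectation $E[S] = \sum_i \left(1 - \binom{N-n_i}{m}/\binom{N}{m}\right)$
(`expected_richness()`) serves as an independent oracle; the test suite
checks the Monte-Carlo mean against it and against `vegan::rarefy()`.

Seeding: one user seed is expanded into per-sample and per-replicate
sub-seeds through a counter-based derivation, so replicate $j$ is
reproducible without generating replicates $1..j{-}1$, and the $K{=}1$
multi-bin analysis reproduces overall rarefying at the minimum depth
*exactly*, seed chain included. `n_rep` (default 1, the base procedure)
averages the metric over repeated draws to damp subsampling noise.

## Baselines

`no_rarefy_alpha()` (raw counts), `overall_rarefy_alpha()` (discard below
$L^*$, rarefy the rest to $L^*$), and `loess_residual_alpha()` (residuals of
a span-0.5, degree-1 LOESS of non-rarefied alpha on library size) mirror the
normalizations the method is compared against. For LOESS the predictor is
$\log_{10} L$ by default: depths span decades, and a tricube window on the
raw scale would be dominated by the deepest samples; the raw-scale variant
is available via `log_scale = FALSE`. Degree 1 guarantees the smoother
reproduces straight-line trends exactly, which the tests exploit.

## The simulation framework

### Simulation B (two pools)

`run_simulation_B()` rebuilds the generative design used to validate the
method. Two clonotype pools of 1000 clonotypes each are constructed; cases
are drawn from Pool A and controls from Pool B, where Pool B is Pool A plus
a proportion $p$ of a second, (nearly) disjoint source pool — $p = 0$ is an
exact null, larger $p$ a larger true diversity difference. Per replicate,
400 samples get library sizes $L_i = 10^{U_i}$, $U_i \sim U(3,5)$, and each
sample is formed by drawing $L_i$ reads *with replacement* from its pool,
weighted by clonotype read counts.

In the confounded scenario two devices couple depth to label and diversity:

* 70% of cases receive library sizes at or below the median (controls
  mirror-imaged), tying label to depth;
* each sample may only draw from the first $\gamma_i$ fraction of its
  pool's fixed order, with $\gamma$ evenly spaced over $(0.80, 0.85]$ for
  $L \in [10^3, 3\times10^3)$, $(0.95, 0.98]$ for $[3\times10^3, 10^4)$,
  $(0.98, 0.99]$ for $[10^4, 3\times10^4)$, and $\gamma = 1$ above —
  tying depth to diversity (`gamma_of()`, `gamma_assign()`).

Unstated details were fixed once as package conventions: the "first
$\gamma$ fraction" is taken along a single random permutation frozen at
pool construction, so larger $\gamma$ always enlarges the sampling space;
reads are drawn weight-proportionally (pools keep their read counts; a
uniform-over-clonotype variant would discard them); $p$ mixes at the
clonotype level, `round(p * 1000)` clonotypes; and at $p = 0$ Pool B *is*
Pool A, order included, keeping the null exact. When real source
repertoires are available, `build_pools_from_repertoires()` applies the
matching filter (drop clonotypes above 1000 reads, sample 1000 of the rest);
by default `synthesize_pools()` provides synthetic pools with log-normal
weights capped at 1000, so nothing needs downloading.

Default analysis settings place the multi-bin cuts at $3\times10^3, 10^4,
3\times10^4$ — aligned with the $\gamma$ intervals — with overall rarefying
at $3\times10^3$.

### Simulation A (permutation null)

`run_simulation_A()` fixes one cohort and permutes half/half labels, so no
method should ever find signal; the replicate-specific Spearman correlation
$\rho$ between labels and library size is recorded, and rejection rates are
reported within increasing $|\rho|$ strata, where depth-sensitive
normalizations inflate. Because the cohort is fixed, per-sample normalized
alphas are computed once and only the association step is repeated, making
hundreds of permutations cheap. The default synthetic cohort (200 samples,
one pool, depths $10^{3..5}$, $\gamma$-coupling applied to all samples)
emulates the depth–diversity coupling of real repertoires.

### Scale, and what the simulations do not emulate

Desk-scale defaults (500 replicates, pools of 1000, depths $10^3$–$10^5$)
keep a full calibration run in the low minutes on one CPU; the original
validation scale (5000+ replicates, depths to $10^7$) is reachable through
the arguments. The generator reproduces the features that matter for the
statistical claims — near-disjoint pools, order-of-magnitude depth spread,
depth–diversity–label coupling — but not other features of real
repertoires: power-law clone-size tails beyond the capped log-normal, V/J
usage structure, PCR noise, or sample-to-sample overlap patterns. Passing
tests therefore demonstrate calibration and power of the testing machinery
under the stated generative model, not performance guarantees on any
particular cohort.

## Numerical and degenerate-input conventions

* Bins with fewer than 3 usable samples, a constant covariate, or constant
  alpha (zero slope variance) are excluded from pooling with a warning; the
  analysis errors only if no bin survives.
* Ties in library size always land in the same bin (the rule depends only on
  $L_i$); Spearman diagnostics use average ranks.
* All p-values are two-sided and unadjusted; no multiplicity correction is
  applied across metrics or covariates.
* The Wald reference is $\chi^2_1$, i.e. a normal approximation to the
  within-bin slope estimates. With very small bins (around 10 samples) the
  estimated-variance weights make IVW mildly anticonservative; calibration
  tests run at the bin sizes the thresholds guidelines call for
  (roughly 100 per bin), where the approximation is excellent.
* Counts are validated as positive integers at the repertoire boundary;
  clonotype identity is the exact (V, CDR3aa, J) string triple, with no
  allele collapsing, since collapsing would change richness.

## Worked example

```{r example, eval = FALSE}
reps <- read_repertoire_table("clonotypes.tsv")           # immunoSEQ-style TSV
meta <- read_sample_metadata("metadata.tsv")              # sample_id + covariates

res <- multibin_alpha_test(reps, meta, covariate = "cmv_status",
                           metric = "shannon",
                           cut_points = c(1e6, 2e6, 4e6, 8e6, 1e7),
                           min_depth = 1e5, seed = 17)
res                      # per-bin slopes and the pooled Wald tests
bin_diagnostics(res$alpha)  # residual depth correlation within bins
```

## Known limitations

Threshold choice remains manual; the diagnostics support but do not automate
it. The within-bin model is univariate OLS — survival models and covariate
adjustment are out of scope. Fixed-effect pooling assumes effect homogeneity
across depth bins; if that is in doubt, sample-size weights are the more
conservative choice among the three offered. Very small bins reduce both
calibration quality and power; merge them via coarser cuts instead.
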