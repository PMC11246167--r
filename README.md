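# rarebin

Multi-bin rarefying for alpha diversity association tests in immune
repertoire (TCR/AIRR-seq) count data.

## The problem

Alpha diversity — clonotype richness, Shannon index, Pielou's evenness,
bias-corrected Chao1 — rises with sequencing depth, and library sizes in
bulk TCR-seq cohorts span orders of magnitude. A diversity–phenotype
regression on such data largely reflects which group was sequenced deeper,
and the standard fix (rarefying every sample to one global depth) both
discards most of the data and fails to remove the depth dependence, because
the depth–diversity relationship is nonlinear.

`rarebin` implements a stratified alternative for anyone running
diversity association tests on repertoire count tables (immunoSEQ exports,
AIRR rearrangement tables, or any TSV of clonotype counts):

1. partition samples into *K* library-size bins by thresholds
   `c_0 = min(L) <= c_1 < ... < c_(K-1) <= c_K = max(L)`, sample *i* in bin
   *k* when `c_(k-1) <= L_i < c_k` (top bin closed);
2. rarefy (subsample without replacement) every sample to the lower bound
   `L*_k = c_(k-1)` of **its own** bin, so deep samples keep a deep
   standardization level;
3. regress alpha diversity on the covariate within each bin: slope
   `tau_hat_k`, squared standard error `V_k` (for a two-level covariate this
   is the equal-variance t-test);
4. pool across bins by fixed-effect meta-analysis with weights `w_k`
   (equal, sample-size `n_k`, or inverse-variance `1/V_k`) and test

   W = (Σ w_k tau_hat_k)² / Σ w_k² V_k  ~  χ²(1) under H₀.

The three baseline normalizations it is usually compared against (no
rarefying, overall rarefying, LOESS residualization of alpha on depth) are
included, along with Spearman depth diagnostics for threshold selection and
a full type-I-error / power simulation framework.

## Worked example

A synthetic cohort with a true effect: 120 samples, cases drawn from a
1000-clonotype pool, controls from the same pool enriched with 30% extra
clonotypes, depths log-uniform over 10³–10⁵:

```r
library(rarebin)

pools  <- synthesize_pools(n_per_pool = 1000, n_shared = 0, seed = 42)
pool_b <- mix_pool_b(pools$pool_a, pools$pool_b, p = 0.3, seed = 43)
l      <- draw_library_sizes(120, seed = 44)
labels <- rep(c(1, 0), each = 60)
reps   <- lapply(seq_len(120), function(i)
  simulate_sample(if (labels[i] == 1) pools$pool_a else pool_b, l[i],
                  sample_id = sprintf("s%03d", i), seed = 100 + i))
names(reps) <- sprintf("s%03d", 1:120)
meta <- data.frame(sample_id = names(reps), group = labels)

res <- multibin_alpha_test(reps, meta, covariate = "group",
                           metric = "richness",
                           cut_points = c(3000, 10000, 30000), seed = 45)
res
```

```
Multi-bin rarefying association test
  metric: richness   covariate: group 

Per-bin results:
 lower upper bin  n    tau_hat         V      p_value degenerate
  1001  3000   1 30  -46.18552  8.062927 8.473826e-16      FALSE
  3000 10000   2 41 -104.79710  7.314812 9.458978e-33      FALSE
 10000 30000   3 24 -185.92857 18.279963 7.863301e-23      FALSE
 30000 99443   4 25 -263.93333  8.705314 9.454084e-31      FALSE

Pooled (fixed-effect meta-analysis):
 weighting   tau_hat        W p_value n_bins
       ivw -140.6999 8518.627       0      4
       ssw -139.5239 7891.345       0      4
     equal -150.2111 8521.918       0      4
```

Every bin sees fewer clonotypes in the cases (negative `tau_hat_k`, at its
own rarefying depth), and the pooled Wald test is overwhelming under all
three weightings. The depth diagnostics show why binning was needed:

```r
bin_diagnostics(res$alpha)
```

```
  bin   n         rho      p_value
1   1  30 -0.05588958 7.692611e-01
2   2  41 -0.04685730 7.711169e-01
3   3  24  0.07105517 7.414510e-01
4   4  25  0.11599251 5.808524e-01
5 all 120  0.90514002 1.178021e-45
```

Across the whole cohort, rarefied richness still correlates 0.91 with
library size; within each bin the correlation is gone.

For real data, replace the generator with
`read_repertoire_table("clonotypes.tsv")` (use
`column_map = airr_columns()` for AIRR field names) and
`read_sample_metadata("metadata.tsv")`.

A command-line front end over the same functions ships in
`inst/cli/multibin-alpha` (subcommands `diversity`, `rarefy`, `multibin`,
`baseline`, `simulate-a`, `simulate-b`, `make-pools`; run any of them with
no options for usage).

## Simulations

`run_simulation_B()` measures type-I error (mixing proportion `p = 0`) and
power (`p > 0`) of the multi-bin test and the baselines on two-pool
synthetic cohorts, optionally with a depth-confounded design in which case
labels follow a 70/30 depth split and shallow samples are restricted to a
fraction gamma of their pool. `run_simulation_A()` measures type-I error
under label permutation, stratified by the chance label–depth correlation.
See the vignette (`vignettes/multibin-rarefying.Rmd`) for the generative
model, its defaults, and what the simulations do and do not emulate.

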