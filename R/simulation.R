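# Simulation framework for type-I error and power under library-size
# confounding.
#
# Two designs are provided. Simulation A permutes case/control labels on a
# fixed cohort (no true effect anywhere) and stratifies type-I error by the
# chance Spearman correlation between labels and library size. Simulation B
# generates samples by weighted with-replacement draws from two near-disjoint
# clonotype pools; the mixing proportion p controls the true diversity
# difference, and a depth-dependent truncation rule (gamma) couples library
# size to diversity in the confounded scenario.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Base-20 amino-acid encoding of an index; guarantees key uniqueness while
# keeping CDR3 strings plausible.
.idx_code <- function(i, width = 4) {
  out <- character(length(i))
  i <- i - 1
  for (k in seq_len(width)) {
    out <- paste0(.aa_alphabet[(i %% 20) + 1], out)
    i <- i %/% 20
  }
  out
}

# Random but unique clonotype keys for synthetic pools.
.synth_keys <- function(n) {
  v <- sprintf("TRBV%02d-01", sample.int(30, n, replace = TRUE))
  j <- sprintf("TRBJ%d-%d", sample.int(2, n, replace = TRUE),
               sample.int(7, n, replace = TRUE))
  mid <- vapply(seq_len(n), function(i) {
    paste(sample(.aa_alphabet, 5, replace = TRUE), collapse = "")
  }, character(1))
  clonotype_key(v, paste0("CASS", mid, .idx_code(seq_len(n)), "F"), j)
}

#' Synthesize a pair of clonotype pools
#'
#' Download-free generator of two sequence pools emulating the two-source
#' design: `n_per_pool` clonotypes each, sharing exactly `n_shared` keys,
#' with heavy-tailed integer weights (discretized log-normal, capped at
#' `max_weight` to mimic the removal of dominating clonotypes). Each pool's
#' clonotype order is randomized once at construction; that fixed order is
#' what the gamma truncation of [simulate_sample()] operates on.
#'
#' @param n_per_pool Clonotypes per pool (default 1000).
#' @param n_shared Clonotypes common to both pools (default 0; with
#'   heavy-tailed weights and `n_shared = 0` the pools have Bray-Curtis
#'   dissimilarity 1).
#' @param meanlog,sdlog Log-normal weight-law parameters (defaults 1.5, 1.5:
#'   median a few reads, upper tail reaching the cap).
#' @param max_weight Weight cap (default 1000, the dominating-clonotype
#'   filter level).
#' @param seed Optional integer seed.
#' @return List with named weight vectors `pool_a` and `pool_b`.
#' @export
synthesize_pools <- function(n_per_pool = 1000, n_shared = 0, meanlog = 1.5,
                             sdlog = 1.5, max_weight = 1000, seed = NULL) {
  if (n_per_pool < 1 || n_shared < 0 || n_shared > n_per_pool) {
    stop("need 0 <= n_shared <= n_per_pool and n_per_pool >= 1")
  }
  with_rng(seed, {
    keys <- .synth_keys(2 * n_per_pool - n_shared)
    shared <- keys[seq_len(n_shared)]
    rest <- keys[seq_len(2 * (n_per_pool - n_shared)) + n_shared]
    a_keys <- c(shared, rest[seq_len(n_per_pool - n_shared)])
    b_keys <- c(shared, rest[seq_len(n_per_pool - n_shared) +
                               (n_per_pool - n_shared)])
    draw <- function(n) {
      pmin(max_weight, pmax(1, round(stats::rlnorm(n, meanlog, sdlog))))
    }
    pool_a <- stats::setNames(draw(n_per_pool), a_keys)
    pool_b <- stats::setNames(draw(n_per_pool), b_keys)
    list(pool_a = pool_a[sample.int(n_per_pool)],
         pool_b = pool_b[sample.int(n_per_pool)])
  })
}

#' Build sequence pools from two real repertoires
#'
#' Reproduces the pool-construction rule used with real source samples:
#' clonotypes with more than `max_count` reads are removed (they would
#' dominate the downstream subsampling), then `n_select` clonotypes are
#' sampled uniformly without replacement from each repertoire; the retained
#' read counts become the pool weights, in a randomized fixed order.
#'
#' @param rep1,rep2 `repertoire` objects (sources for pool A and the pool-B
#'   admixture respectively).
#' @param max_count Read-count filter (default 1000).
#' @param n_select Clonotypes sampled per pool (default 1000).
#' @param seed Optional integer seed.
#' @return List with named weight vectors `pool_a` and `pool_b`.
#' @export
build_pools_from_repertoires <- function(rep1, rep2, max_count = 1000,
                                         n_select = 1000, seed = NULL) {
  pick <- function(r, sub) {
    w <- r$counts[r$counts <= max_count]
    if (length(w) < n_select) {
      stop("sample ", r$sample_id, " has only ", length(w),
           " clonotypes with count <= ", max_count, "; need ", n_select)
    }
    with_rng(sub, w[sample.int(length(w), n_select)])
  }
  list(pool_a = pick(rep1, derive_seed(seed, 1)),
       pool_b = pick(rep2, derive_seed(seed, 2)))
}

#' Mix a proportion of a second pool into the first
#'
#' Pool B of the generative model: all of `source_a` plus
#' `round(p * length(source_b))` clonotypes drawn uniformly without
#' replacement from `source_b` (clonotype-level mixing). Shared keys have
#' their weights summed. At p = 0 the result is `source_a` unchanged --
#' including its order -- so the null hypothesis is exact; for p > 0 the
#' combined pool's order is freshly randomized.
#'
#' @param source_a,source_b Named weight vectors (see [synthesize_pools()]).
#' @param p Mixing proportion in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Named weight vector.
#' @export
mix_pool_b <- function(source_a, source_b, p, seed = NULL) {
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single value in [0, 1]")
  }
  n_add <- round(p * length(source_b))
  if (n_add == 0) return(source_a)
  with_rng(seed, {
    add <- source_b[sample.int(length(source_b), n_add)]
    combined <- c(source_a, add)
    if (anyDuplicated(names(combined))) {
      combined <- vapply(split(combined, factor(names(combined),
                                                levels = unique(names(combined)))),
                         sum, numeric(1))
    }
    combined[sample.int(length(combined))]
  })
}

#' Draw library sizes on a log-uniform scale
#'
#' L_i = round(10^U_i) with U_i i.i.d. Uniform(`lo_exp`, `hi_exp`), spanning
#' two orders of magnitude at the defaults (10^3 to 10^5).
#'
#' @param n Number of samples.
#' @param lo_exp,hi_exp Exponent bounds (defaults 3 and 5).
#' @param seed Optional integer seed.
#' @return Integer-valued numeric vector of length `n`.
#' @export
draw_library_sizes <- function(n, lo_exp = 3, hi_exp = 5, seed = NULL) {
  if (lo_exp >= hi_exp) stop("lo_exp must be smaller than hi_exp")
  with_rng(seed, round(10^stats::runif(n, lo_exp, hi_exp)))
}

#' Depth-confounded case/control assignment
#'
#' Splits the cohort evenly into cases and controls while tying the labels to
#' sequencing depth: a fraction `case_frac_low` of the cases (70% by default)
#' get library sizes at or below the sample median and the rest above, with
#' the mirror-image allocation for controls. Within each depth stratum the
#' specific samples are chosen uniformly at random. With
#' `case_frac_low = 0.5` labels are independent of depth.
#'
#' @param library_sizes Numeric vector (even length).
#' @param case_frac_low Fraction of cases in the at-or-below-median stratum.
#' @param seed Optional integer seed.
#' @return Integer 0/1 labels (1 = case), aligned with `library_sizes`.
#' @export
confounded_label_assignment <- function(library_sizes, case_frac_low = 0.7,
                                        seed = NULL) {
  n <- length(library_sizes)
  if (n %% 2 != 0) stop("an even number of samples is required")
  n_case <- n %/% 2
  med <- stats::median(library_sizes)
  low <- which(library_sizes <= med)
  high <- which(library_sizes > med)
  n_case_low <- round(case_frac_low * n_case)
  n_case_high <- n_case - n_case_low
  if (length(low) < n_case_low || length(high) < n_case_high ||
      length(low) - n_case_low < 0 || length(high) - n_case_high < 0) {
    stop("depth stratum too small to honor case_frac_low = ", case_frac_low)
  }
  with_rng(seed, {
    cases <- c(low[sample.int(length(low), n_case_low)],
               high[sample.int(length(high), n_case_high)])
    labels <- integer(n)
    labels[cases] <- 1L
    labels
  })
}

.gamma_rule <- data.frame(
  lower = c(1e3, 3e3, 1e4, 3e4),
  upper = c(3e3, 1e4, 3e4, 1e5),
  base = c(0.80, 0.95, 0.98, 1.00),
  slope = c(0.05, 0.03, 0.01, 0.00)
)

#' Depth-dependent pool-usable fraction gamma
#'
#' The truncation rule coupling library size to diversity: samples are
#' grouped into four fixed depth intervals M1 = \[1e3, 3e3), M2 = \[3e3,
#' 1e4), M3 = \[1e4, 3e4), M4 = \[3e4, 1e5\], and within bin b the sample with
#' ascending-depth rank i of n_b gets gamma = base_b + slope_b * i / n_b:
#' evenly spaced over (0.80, 0.85\] in M1, (0.95, 0.98\] in M2, (0.98, 0.99\]
#' in M3, and exactly 1 in M4. A sample with gamma may only be drawn from the
#' first gamma fraction of its pool, so shallower samples see fewer
#' clonotypes.
#'
#' @param library_size Library sizes within \[1000, 100000\].
#' @param rank_in_bin Ascending depth rank(s) within the sample's bin, in
#'   1..n_bin.
#' @param n_bin Number of samples in that bin.
#' @return gamma value(s) in (0, 1\].
#' @seealso [gamma_assign()] for whole-cohort assignment.
#' @export
#' @examples
#' gamma_of(2000, 4, 4) # 0.85: top-ranked sample of M1
gamma_of <- function(library_size, rank_in_bin, n_bin) {
  if (any(library_size < 1e3 | library_size > 1e5)) {
    stop("library size outside [1000, 100000]; the gamma rule is undefined")
  }
  if (any(rank_in_bin < 1 | rank_in_bin > n_bin)) {
    stop("rank_in_bin must lie in 1..n_bin")
  }
  b <- findInterval(library_size, c(.gamma_rule$lower, 1e5),
                    rightmost.closed = TRUE)
  .gamma_rule$base[b] + .gamma_rule$slope[b] * rank_in_bin / n_bin
}

#' Assign gamma values across a cohort
#'
#' Vectorized application of [gamma_of()]: bins every sample into the four
#' fixed depth intervals, ranks samples by library size within each bin
#' (ties broken by position), and returns the per-sample gamma.
#'
#' @param library_sizes Numeric vector within \[1000, 100000\].
#' @return Numeric gamma vector aligned with `library_sizes`.
#' @export
gamma_assign <- function(library_sizes) {
  if (any(library_sizes < 1e3 | library_sizes > 1e5)) {
    stop("library size outside [1000, 100000]; the gamma rule is undefined")
  }
  b <- findInterval(library_sizes, c(.gamma_rule$lower, 1e5),
                    rightmost.closed = TRUE)
  g <- numeric(length(library_sizes))
  for (k in seq_len(4)) {
    idx <- which(b == k)
    if (!length(idx)) next
    r <- rank(library_sizes[idx], ties.method = "first")
    g[idx] <- .gamma_rule$base[k] + .gamma_rule$slope[k] * r / length(idx)
  }
  g
}

# Fast core of simulate_sample: weighted with-replacement draw of `l` reads
# over the first floor(gamma * pool size) clonotypes (minimum 1) of the
# pool's fixed order; returns positive counts only.
.sim_counts <- function(pool, l, gamma = 1) {
  m <- max(1L, floor(gamma * length(pool)))
  w <- pool[seq_len(m)]
  cnt <- stats::rmultinom(1, size = l, prob = w)[, 1]
  names(cnt) <- names(w)
  cnt[cnt > 0]
}

#' Simulate a sample from a clonotype pool
#'
#' Draws `library_size` reads with replacement from the pool, each read
#' choosing a clonotype with probability proportional to its weight, with
#' the sampling space restricted to the first `floor(gamma * pool size)`
#' clonotypes of the pool's fixed order (at least 1). The output library
#' size equals `library_size` exactly. Expected richness obeys the
#' occupancy formula sum_j (1 - (1 - w_j / W)^L) over the sampling space.
#'
#' @param pool Named weight vector (see [synthesize_pools()]).
#' @param library_size Number of reads to draw.
#' @param gamma Usable pool fraction in (0, 1\] (see [gamma_of()]).
#' @param sample_id Sample identifier for the returned repertoire.
#' @param seed Optional integer seed.
#' @return A [repertoire()].
#' @export
simulate_sample <- function(pool, library_size, gamma = 1, sample_id = "sim",
                            seed = NULL) {
  if (!length(pool)) stop("pool is empty")
  if (length(gamma) != 1 || is.na(gamma) || gamma <= 0 || gamma > 1) {
    stop("gamma must be a single value in (0, 1]")
  }
  if (length(library_size) != 1 || library_size < 1) {
    stop("library_size must be a positive integer")
  }
  counts <- with_rng(seed, .sim_counts(pool, library_size, gamma))
  repertoire(counts, sample_id)
}

# Per-dataset analysis shared by both simulation designs: p-values for every
# requested method on one simulated cohort. counts_list is a named list of
# counts vectors aligned with l (named library sizes) and labels.
.sim_methods <- c("multibin_ivw", "multibin_ssw", "multibin_equal",
                  "no_rarefying", "overall_rarefying", "loess")

.analyze_dataset <- function(counts_list, l, labels, methods, metric,
                             cut_points, overall_level, loess_span, n_rep) {
  f <- metric_function(metric)
  pvals <- stats::setNames(rep(NA_real_, length(methods)), methods)
  raw_needed <- any(c("no_rarefying", "loess") %in% methods)
  if (raw_needed) a_raw <- vapply(counts_list, f, numeric(1))
  if ("no_rarefying" %in% methods) {
    pvals[["no_rarefying"]] <- ols_assoc(a_raw, labels)$p_value
  }
  if ("loess" %in% methods) {
    res <- loess_residual_alpha(a_raw, l, span = loess_span)
    pvals[["loess"]] <- ols_assoc(res, labels)$p_value
  }
  if ("overall_rarefying" %in% methods) {
    keep <- l >= overall_level
    a_o <- .rarefied_alpha(counts_list[keep],
                           rep(overall_level, sum(keep)), metric,
                           n_rep = n_rep, seed = NULL)
    pvals[["overall_rarefying"]] <- ols_assoc(a_o, labels[keep])$p_value
  }
  mb <- intersect(c("multibin_ivw", "multibin_ssw", "multibin_equal"), methods)
  if (length(mb)) {
    partition <- assign_bins(l, cut_points)
    alpha_df <- within_bin_alpha(counts_list, partition, metric,
                                 n_rep = n_rep, seed = NULL)
    # degenerate bins are dropped quietly inside the replicate loop
    mm <- suppressWarnings(
      multibin_meta(alpha_df, stats::setNames(labels, names(l)),
                    weighting = sub("multibin_", "", mb)))
    pvals[mb] <- mm$meta$p_value[match(sub("multibin_", "", mb),
                                       mm$meta$weighting)]
  }
  pvals
}

#' Simulation B: two-pool generative study of type-I error and power
#'
#' Per replicate, 400 samples (by default) are split evenly into cases drawn
#' from Pool A and controls drawn from Pool B, where Pool B is Pool A plus a
#' proportion `p` of a second, nearly disjoint source pool: `p = 0` is the
#' null, larger `p` a larger true diversity difference. Library sizes are
#' log-uniform over \[10^`lo_exp`, 10^`hi_exp`\]. In the `"no_confounding"`
#' scenario labels are independent of depth and every sample uses its whole
#' pool (gamma = 1); in the `"confounded"` scenario labels follow the 70/30
#' depth-stratified assignment ([confounded_label_assignment()]) and
#' shallower samples are restricted to a fraction gamma of their pool
#' ([gamma_assign()]), coupling depth to both label and diversity. Each
#' requested method is run on every replicate and its rejection fraction at
#' `alpha_level` is reported.
#'
#' @param p Mixing proportion in \[0, 1\].
#' @param scenario `"no_confounding"` or `"confounded"`.
#' @param n_samples Samples per replicate (even; default 400).
#' @param n_replicates Number of replicates (default 500).
#' @param methods Subset of `"multibin_ivw"`, `"multibin_ssw"`,
#'   `"multibin_equal"`, `"no_rarefying"`, `"overall_rarefying"`, `"loess"`.
#' @param metric Diversity metric name.
#' @param cut_points Interior bin thresholds for the multi-bin methods
#'   (default 3000/10000/30000, aligned with the gamma-rule intervals).
#' @param pool_size,n_shared Synthetic pool parameters (ignored when `pools`
#'   is given).
#' @param lo_exp,hi_exp Library-size exponent bounds (defaults 3 and 5).
#' @param case_frac_low Confounded-scenario case fraction at or below the
#'   median depth (default 0.7).
#' @param overall_level Overall-rarefying level (default 3000).
#' @param loess_span LOESS span (default 0.5).
#' @param alpha_level Nominal significance level (default 0.05).
#' @param n_rep Rarefying replicates per sample (default 1).
#' @param pools Optional list with `pool_a` and `pool_b` source weight
#'   vectors (e.g. from [build_pools_from_repertoires()]); by default a pair
#'   of synthetic pools is generated from `seed`.
#' @param seed Master seed; the whole run is reproducible from it.
#' @return Data frame with one row per method: `method`, `scenario`, `p`,
#'   `metric`, `n_replicates`, `rejections`, `rejection_rate`, `mc_se`.
#' @export
run_simulation_B <- function(p = 0,
                             scenario = c("no_confounding", "confounded"),
                             n_samples = 400, n_replicates = 500,
                             methods = .sim_methods,
                             metric = "richness",
                             cut_points = c(3000, 10000, 30000),
                             pool_size = 1000, n_shared = 0,
                             lo_exp = 3, hi_exp = 5, case_frac_low = 0.7,
                             overall_level = 3000, loess_span = 0.5,
                             alpha_level = 0.05, n_rep = 1, pools = NULL,
                             seed = NULL) {
  scenario <- match.arg(scenario)
  methods <- match.arg(methods, .sim_methods, several.ok = TRUE)
  if (n_samples %% 2 != 0) stop("n_samples must be even")
  if (is.null(pools)) {
    pools <- synthesize_pools(pool_size, n_shared, seed = derive_seed(seed, 0))
  }
  ids <- sprintf("sim%04d", seq_len(n_samples))
  labels_fixed <- rep(c(1L, 0L), each = n_samples / 2)
  rej <- stats::setNames(numeric(length(methods)), methods)
  for (r in seq_len(n_replicates)) {
    pvals <- with_rng(derive_seed(seed, r), {
      pool_b <- mix_pool_b(pools$pool_a, pools$pool_b, p)
      l <- stats::setNames(draw_library_sizes(n_samples, lo_exp, hi_exp), ids)
      if (scenario == "confounded") {
        labels <- confounded_label_assignment(l, case_frac_low)
        gammas <- gamma_assign(l)
      } else {
        labels <- labels_fixed
        gammas <- rep(1, n_samples)
      }
      counts_list <- lapply(seq_len(n_samples), function(i) {
        .sim_counts(if (labels[i] == 1L) pools$pool_a else pool_b,
                    l[i], gammas[i])
      })
      names(counts_list) <- ids
      .analyze_dataset(counts_list, l, labels, methods, metric, cut_points,
                       overall_level, loess_span, n_rep)
    })
    rej <- rej + as.numeric(!is.na(pvals) & pvals <= alpha_level)
  }
  rate <- rej / n_replicates
  data.frame(method = methods, scenario = scenario, p = p, metric = metric,
             n_replicates = n_replicates, rejections = as.numeric(rej),
             rejection_rate = as.numeric(rate),
             mc_se = sqrt(rate * (1 - rate) / n_replicates),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulation A: permutation null on a fixed cohort
#'
#' Labels are repeatedly permuted half/half over a fixed cohort, so no method
#' should detect an association; chance correlation between labels and
#' library size nevertheless produces confounded realizations. Each
#' replicate's Spearman correlation rho between label and library size is
#' recorded and rejection rates are reported within increasing
#' |rho|-exceedance strata, where depth-sensitive normalizations inflate.
#' Per-sample normalized alpha values are computed once (the cohort is
#' fixed); only the label-dependent association step is repeated.
#'
#' By default a synthetic cohort is generated: one synthetic pool, library
#' sizes log-uniform over \[10^`lo_exp`, 10^`hi_exp`\], and the gamma
#' truncation applied to every sample so that diversity is monotonically
#' coupled to depth (emulating the depth-diversity coupling of real
#' repertoires). Supply `reps` to run on real data instead.
#'
#' @param reps Optional named list of `repertoire` objects; `NULL` (default)
#'   generates the synthetic cohort.
#' @param n_samples Synthetic cohort size (even; default 200).
#' @param n_replicates Label permutations (default 500).
#' @inheritParams run_simulation_B
#' @param rho_thresholds Increasing |rho| thresholds defining the strata
#'   (default 0, 0.02, ..., 0.1).
#' @return Data frame with one row per (method, threshold): `method`,
#'   `rho_threshold`, `n_datasets`, `rejections`, `rejection_rate`, `mc_se`.
#'   Strata with no replicates get `NA` rates.
#' @export
run_simulation_A <- function(reps = NULL, n_samples = 200, n_replicates = 500,
                             methods = .sim_methods, metric = "richness",
                             cut_points = c(3000, 10000, 30000),
                             overall_level = 3000, loess_span = 0.5,
                             rho_thresholds = seq(0, 0.1, by = 0.02),
                             alpha_level = 0.05, n_rep = 1, pool_size = 1000,
                             lo_exp = 3, hi_exp = 5, seed = NULL) {
  methods <- match.arg(methods, .sim_methods, several.ok = TRUE)
  if (is.null(reps)) {
    if (n_samples %% 2 != 0) stop("n_samples must be even")
    counts_list <- with_rng(derive_seed(seed, 0), {
      pool <- synthesize_pools(pool_size, 0)$pool_a
      l <- draw_library_sizes(n_samples, lo_exp, hi_exp)
      g <- gamma_assign(l)
      cl <- lapply(seq_len(n_samples), function(i) .sim_counts(pool, l[i], g[i]))
      names(cl) <- sprintf("sim%04d", seq_len(n_samples))
      cl
    })
  } else {
    counts_list <- .counts_by_id(reps)
    n_samples <- length(counts_list)
    if (n_samples %% 2 != 0) stop("an even number of samples is required")
  }
  l <- stats::setNames(vapply(counts_list, sum, numeric(1)),
                       names(counts_list))
  f <- metric_function(metric)

  # Cohort-level quantities, computed once.
  a_raw <- if (any(c("no_rarefying", "loess") %in% methods)) {
    vapply(counts_list, f, numeric(1))
  }
  a_loess <- if ("loess" %in% methods) {
    loess_residual_alpha(a_raw, l, span = loess_span)
  }
  if ("overall_rarefying" %in% methods) {
    keep_o <- l >= overall_level
    a_over <- .rarefied_alpha(counts_list[keep_o],
                              rep(overall_level, sum(keep_o)), metric,
                              n_rep = n_rep, seed = derive_seed(seed, 1))
  }
  mb <- intersect(c("multibin_ivw", "multibin_ssw", "multibin_equal"), methods)
  if (length(mb)) {
    partition <- assign_bins(l, cut_points)
    alpha_df <- within_bin_alpha(counts_list, partition, metric,
                                 n_rep = n_rep, seed = derive_seed(seed, 2))
  }

  pmat <- matrix(NA_real_, nrow = n_replicates, ncol = length(methods),
                 dimnames = list(NULL, methods))
  rho <- numeric(n_replicates)
  half <- rep(c(1L, 0L), each = n_samples / 2)
  for (r in seq_len(n_replicates)) {
    labels <- with_rng(derive_seed(seed, 10 + r), sample(half))
    rho[r] <- suppressWarnings(stats::cor(labels, l, method = "spearman"))
    if ("no_rarefying" %in% methods) {
      pmat[r, "no_rarefying"] <- ols_assoc(a_raw, labels)$p_value
    }
    if ("loess" %in% methods) {
      pmat[r, "loess"] <- ols_assoc(a_loess, labels)$p_value
    }
    if ("overall_rarefying" %in% methods) {
      pmat[r, "overall_rarefying"] <- ols_assoc(a_over, labels[keep_o])$p_value
    }
    if (length(mb)) {
      mm <- suppressWarnings(
        multibin_meta(alpha_df, stats::setNames(labels, names(l)),
                      weighting = sub("multibin_", "", mb)))
      pmat[r, mb] <- mm$meta$p_value[match(sub("multibin_", "", mb),
                                           mm$meta$weighting)]
    }
  }

  rows <- lapply(rho_thresholds, function(t) {
    sel <- abs(rho) > t
    n_sel <- sum(sel)
    rate <- if (n_sel > 0) {
      colMeans(pmat[sel, , drop = FALSE] <= alpha_level, na.rm = TRUE)
    } else {
      stats::setNames(rep(NA_real_, length(methods)), methods)
    }
    data.frame(method = methods, rho_threshold = t, n_datasets = n_sel,
               rejections = if (n_sel > 0) round(rate * n_sel) else NA_real_,
               rejection_rate = as.numeric(rate),
               mc_se = if (n_sel > 0) sqrt(rate * (1 - rate) / n_sel) else NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
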