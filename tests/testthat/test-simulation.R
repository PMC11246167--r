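test_that("synthetic pools have the requested sizes, overlap and weights", {
  p <- synthesize_pools(500, 25, seed = 1)
  expect_length(p$pool_a, 500)
  expect_length(p$pool_b, 500)
  expect_length(intersect(names(p$pool_a), names(p$pool_b)), 25)
  expect_true(all(p$pool_a >= 1 & p$pool_a <= 1000))
  # disjoint pools are maximally dissimilar
  d <- synthesize_pools(200, 0, seed = 2)
  expect_equal(bray_curtis(d$pool_a, d$pool_b), 1)
  # a single shared clonotype with heavy-tailed weights stays near 1
  s <- synthesize_pools(1000, 1, seed = 3)
  expect_gt(bray_curtis(s$pool_a, s$pool_b), 0.99)
  expect_error(synthesize_pools(10, 11), "n_shared")
})

test_that("pool construction from repertoires filters dominating clonotypes", {
  r1 <- fix_repertoire(c(1500, 800, 2, 5, 9), "big")
  r2 <- fix_repertoire(rep(10, 6), "flat", prefix = "Z")
  pools <- build_pools_from_repertoires(r1, r2, max_count = 1000,
                                        n_select = 2, seed = 4)
  expect_false(any(grepl("Cbig0001", names(pools$pool_a)))) # the 1500-read key
  expect_length(pools$pool_a, 2)
  # n_select equal to the post-filter size retains everything
  all4 <- build_pools_from_repertoires(r1, r2, max_count = 1000,
                                       n_select = 4, seed = 4)
  expect_setequal(names(all4$pool_a), setdiff(names(r1$counts),
                                              names(r1$counts)[r1$counts > 1000]))
  expect_error(build_pools_from_repertoires(r1, r2, n_select = 5),
               "only 4 clonotypes")
})

test_that("pool B mixing is clonotype-level with p = 0 an exact no-op", {
  pools <- synthesize_pools(1000, 0, seed = 5)
  expect_identical(mix_pool_b(pools$pool_a, pools$pool_b, 0), pools$pool_a)
  b05 <- mix_pool_b(pools$pool_a, pools$pool_b, 0.5, seed = 6)
  expect_length(b05, 1500) # 1000 + round(0.5 * 1000), disjoint sources
  b1 <- mix_pool_b(pools$pool_a, pools$pool_b, 1, seed = 6)
  expect_setequal(names(b1), union(names(pools$pool_a), names(pools$pool_b)))
  expect_error(mix_pool_b(pools$pool_a, pools$pool_b, 1.2), "in \\[0, 1\\]")
})

test_that("library sizes are log-uniform over the requested decades", {
  l <- draw_library_sizes(5000, seed = 7)
  expect_true(all(l >= 1000 & l <= 100000))
  expect_lt(abs(median(log10(l)) - 4), 0.05)
  expect_identical(l, draw_library_sizes(5000, seed = 7))
  expect_error(draw_library_sizes(10, 5, 3), "smaller")
})

test_that("the 70/30 assignment ties cases to shallow depths", {
  l <- draw_library_sizes(400, seed = 8)
  lab <- confounded_label_assignment(l, 0.7, seed = 9)
  expect_equal(sum(lab), 200)
  expect_equal(sum(lab == 1 & l <= median(l)), 140)
  expect_equal(sum(lab == 1 & l > median(l)), 60)
  expect_lt(suppressWarnings(cor(lab, l, method = "spearman")), 0)
  # 0.5 gives a depth-balanced assignment
  lab50 <- confounded_label_assignment(l, 0.5, seed = 10)
  expect_equal(sum(lab50 == 1 & l <= median(l)), 100)
  expect_error(confounded_label_assignment(l[1:399]), "even number")
})

test_that("the gamma rule is piecewise linear over the four depth bins", {
  expect_equal(gamma_of(5e4, 3, 7), 1) # M4
  expect_equal(gamma_of(2000, 4, 4), 0.85) # top of M1
  expect_equal(gamma_of(2000, 2, 4), 0.825) # halfway up M1
  expect_equal(gamma_of(5000, 10, 10), 0.98) # top of M2
  expect_equal(gamma_of(20000, 5, 5), 0.99) # top of M3
  expect_error(gamma_of(500, 1, 1), "outside")
  expect_error(gamma_of(2000, 5, 4), "rank_in_bin")

  l <- c(1200, 2900, 1500, 35000, 9000, 4000, 15000)
  g <- gamma_assign(l)
  expect_equal(g[4], 1)
  # within M1 the ranks follow depth order: 1200 < 1500 < 2900
  expect_equal(g[c(1, 3, 2)], 0.8 + 0.05 * (1:3) / 3)
  expect_true(all(g > 0 & g <= 1))
})

test_that("simulated samples conserve library size and follow the occupancy law", {
  pool <- synthesize_pools(50, 0, seed = 11)$pool_a
  r <- simulate_sample(pool, 500, gamma = 1, seed = 12)
  expect_s3_class(r, "repertoire")
  expect_equal(library_size(r), 500)
  one <- simulate_sample(stats::setNames(5, "V|C|J"), 100, seed = 13)
  expect_equal(unname(one$counts), 100)

  # occupancy oracle: E[S] = sum(1 - (1 - w/W)^L) on the truncated space
  for (gamma in c(1, 0.5)) {
    m <- max(1, floor(gamma * length(pool)))
    w <- pool[seq_len(m)]
    expect_s <- sum(1 - (1 - w / sum(w))^200)
    rich <- withr::with_seed(14, {
      replicate(1000, richness(rarebin:::.sim_counts(pool, 200, gamma)))
    })
    se <- sd(rich) / sqrt(length(rich))
    expect_lt(abs(mean(rich) - expect_s), 3 * se + 1e-9)
  }
})

test_that("simulation B is reproducible and reports all requested methods", {
  args <- list(p = 0.2, scenario = "confounded", n_samples = 60,
               n_replicates = 8, pool_size = 150, metric = "shannon",
               methods = c("multibin_ivw", "no_rarefying", "loess",
                           "overall_rarefying"),
               cut_points = c(3000, 10000, 30000), seed = 15)
  r1 <- do.call(run_simulation_B, args)
  r2 <- do.call(run_simulation_B, args)
  expect_identical(r1, r2)
  expect_setequal(r1$method, args$methods)
  expect_true(all(r1$rejection_rate >= 0 & r1$rejection_rate <= 1))
  expect_true(all(r1$n_replicates == 8))
})

test_that("simulation A permutation nulls center rho at zero", {
  res <- run_simulation_A(n_samples = 100, n_replicates = 60,
                          methods = c("multibin_ivw", "no_rarefying"),
                          metric = "shannon", pool_size = 150,
                          rho_thresholds = c(0, 0.05), seed = 16)
  expect_equal(nrow(res), 4) # 2 methods x 2 thresholds
  expect_equal(res$n_datasets[res$rho_threshold == 0][1], 60)
  expect_true(all(res$rejection_rate >= 0 & res$rejection_rate <= 1,
                  na.rm = TRUE))
  # the |rho| > 0.05 stratum is a subset of all datasets
  expect_lte(res$n_datasets[res$rho_threshold == 0.05][1], 60)
})
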