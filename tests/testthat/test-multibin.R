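test_that("assign_bins follows the half-open rule with a closed top bin", {
  p <- assign_bins(c(a = 5, b = 10, c = 25), c(10, 20))
  expect_equal(p$samples$bin, c(1L, 2L, 3L)) # boundary 10 goes up
  expect_equal(p$bins$rarefy_level, c(5, 10, 20))
  expect_equal(p$bins$n, c(1L, 1L, 1L))

  # the published six-bin layout on a cohort spanning the cuts
  l <- stats::setNames(c(5e5, 1.5e6, 3e6, 5e6, 9e6, 2e7, 4e7),
                       paste0("s", 1:7))
  p6 <- assign_bins(l, c(1e6, 2e6, 4e6, 8e6, 1e7))
  expect_equal(nrow(p6$bins), 6)
  expect_equal(p6$bins$rarefy_level, c(5e5, 1e6, 2e6, 4e6, 8e6, 1e7))

  expect_error(assign_bins(c(a = 5, b = 25), c(20, 10)), "strictly increasing")
})

test_that("bins partition the retained samples and rarefying is feasible", {
  reps <- fix_cohort(n = 30)
  l <- vapply(reps, library_size, numeric(1))
  p <- assign_bins(l, c(3000, 10000, 30000))
  expect_setequal(p$samples$sample_id, names(l))
  expect_false(anyNA(p$samples$bin))
  lev <- p$bins$rarefy_level[p$samples$bin]
  expect_true(all(lev <= p$samples$library_size))
})

test_that("min_depth excludes shallow samples and reports them", {
  l <- c(a = 50, b = 2000, c = 9000, d = 40000)
  p <- assign_bins(l, c(5000), min_depth = 1000)
  expect_equal(p$excluded, "a")
  expect_equal(p$bins$rarefy_level[1], 2000) # bottom level is min retained
  expect_error(assign_bins(l, c(5000), min_depth = 1e6), "excludes every")
})

test_that("out-of-range cuts and empty bins are dropped with a warning", {
  l <- c(a = 100, b = 150, c = 5000)
  expect_warning(p <- assign_bins(l, c(50, 1000)), "outside the observed")
  expect_equal(nrow(p$bins), 2)
  expect_warning(p2 <- assign_bins(c(a = 10, b = 1000), c(200, 500)),
                 "empty bin")
  expect_equal(nrow(p2$bins), 2)
  expect_equal(p2$samples$bin, c(1L, 2L))
})

test_that("each sample is rarefied to its own bin's lower bound", {
  reps <- list(s1 = fix_repertoire(rep(2, 50), "s1"),    # L = 100
               s2 = fix_repertoire(rep(10, 100), "s2"),  # L = 1000
               s3 = fix_repertoire(rep(50, 100), "s3"))  # L = 5000
  p <- assign_bins(vapply(reps, library_size, numeric(1)), c(1000))
  a <- within_bin_alpha(reps, p, "richness", seed = 1)
  expect_equal(a$rarefy_level, c(100, 1000, 1000))
  # a sample sitting exactly at its bin's level keeps its raw counts
  expect_equal(a$alpha[a$sample_id == "s2"], richness(reps$s2))
  expect_equal(a$alpha[a$sample_id == "s1"], richness(reps$s1))
})

test_that("within-bin OLS matches its closed form and lm()", {
  b <- within_bin_association(c(1, 2, 3, 4), c(0, 0, 1, 1), bin = 1)
  expect_equal(b$tau_hat, 2)
  expect_equal(b$V, 0.5)
  # against lm() on random data
  set.seed(31)
  for (i in 1:10) {
    y <- rnorm(12)
    x <- rnorm(12)
    fit <- summary(lm(y ~ x))$coefficients
    b <- within_bin_association(y, x)
    expect_equal(b$tau_hat, fit[2, 1])
    expect_equal(b$se, fit[2, 2])
    expect_equal(b$p_value, fit[2, 4])
  }
  # two-level covariate equals the equal-variance t-test
  y <- c(1.2, 0.8, 1.9, 2.4, 2.2, 3.1)
  g <- c("ctl", "ctl", "ctl", "case", "case", "case")
  tt <- t.test(y[g == "ctl"], y[g == "case"], var.equal = TRUE)
  expect_equal(within_bin_association(y, g)$p_value, tt$p.value)

  expect_error(within_bin_association(c(1, 2, 3), c(1, 1, 1)), "constant")
  expect_error(within_bin_association(c(1, 2), c(0, 1)), "usable samples")
  d <- within_bin_association(c(2, 2, 2, 2), c(0, 0, 1, 1))
  expect_true(d$degenerate)
  expect_equal(d$tau_hat, 0)
  expect_equal(d$V, 0)
})

test_that("pooled effects and Wald statistics match their formulas", {
  two <- data.frame(bin = 1:2, n = c(10, 20), tau_hat = c(2, 2), V = c(1, 1))
  w <- wald_test(two, "equal")
  expect_equal(w$W, 8)
  expect_equal(w$tau_hat, 2)
  expect_equal(w$p_value, pchisq(8, 1, lower.tail = FALSE))

  expect_equal(pooled_effect(data.frame(bin = 1:2, n = c(5, 5),
                                        tau_hat = c(1, 3), V = c(1, 1)),
                             "equal")$tau_hat, 2)
  expect_equal(pooled_effect(data.frame(bin = 1:2, n = c(5, 5),
                                        tau_hat = c(0, 2), V = c(1, 3)),
                             "ivw")$tau_hat, 0.5)

  one <- data.frame(bin = 1, n = 8, tau_hat = 3, V = 1)
  for (wt in c("ivw", "ssw", "equal")) {
    m <- wald_test(one, wt)
    expect_equal(m$W, 9) # squared z-score
    expect_equal(m$tau_hat, 3)
  }
})

test_that("IVW Wald reduces to tau^2 * sum(1/V) and weights are scale-free", {
  set.seed(41)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    df <- data.frame(bin = seq_len(k), n = sample(5:50, k, replace = TRUE),
                     tau_hat = rnorm(k), V = rexp(k) + 0.1)
    m <- wald_test(df, "ivw")
    tau <- sum(df$tau_hat / df$V) / sum(1 / df$V)
    expect_equal(m$tau_hat, tau)
    expect_equal(m$W, tau^2 * sum(1 / df$V))
    # generic formula with weights w and with 10w agree (scaling invariance)
    w <- runif(k, 0.5, 2)
    W1 <- sum(w * df$tau_hat)^2 / sum(w^2 * df$V)
    W10 <- sum(10 * w * df$tau_hat)^2 / sum(100 * w^2 * df$V)
    expect_equal(W1, W10)
    # ssw is the n-weighted instance of the same formula
    ms <- wald_test(df, "ssw")
    expect_equal(ms$W, sum(df$n * df$tau_hat)^2 / sum(df$n^2 * df$V))
  }
})

test_that("with a single bin the full test is identical for all weightings", {
  reps <- fix_cohort(n = 16)
  meta <- data.frame(sample_id = names(reps),
                     group = rep(c(0, 1), 8))
  res <- multibin_alpha_test(reps, meta, "group", metric = "shannon",
                             cut_points = numeric(0), seed = 5)
  expect_equal(nrow(res$partition$bins), 1)
  expect_equal(length(unique(res$meta$tau_hat)), 1)
  expect_equal(length(unique(res$meta$W)), 1)
  expect_equal(length(unique(res$meta$p_value)), 1)

  # and it reproduces overall rarefying at the minimum depth exactly:
  # identical per-sample alphas and effect estimate; the pooled test refers
  # (tau/se)^2 to chi-squared(1) while the baseline reports the OLS t-test
  l <- vapply(reps, library_size, numeric(1))
  ov <- overall_rarefy_alpha(reps, "shannon", level = min(l), seed = 5)
  expect_equal(res$alpha$alpha, ov$alpha$alpha)
  ba <- baseline_association(ov$alpha$alpha, meta$group)
  expect_equal(res$meta$tau_hat[1], ba$estimate)
  expect_equal(res$meta$W[1], (ba$estimate / ba$se)^2)
})

test_that("degenerate bins are excluded from the meta-analysis with a warning", {
  # bin 1 has constant alpha; bins 2-3 are fine
  alpha_df <- data.frame(
    sample_id = sprintf("s%02d", 1:12),
    bin = rep(1:3, each = 4),
    library_size = rep(c(100, 1000, 10000), each = 4),
    rarefy_level = rep(c(100, 1000, 10000), each = 4),
    alpha = c(5, 5, 5, 5, rnorm(8, 10)))
  cov <- rep(c(0, 0, 1, 1), 3)
  expect_warning(mm <- rarebin:::multibin_meta(alpha_df, cov), "degenerate")
  expect_equal(mm$meta$n_bins, c(2L, 2L, 2L))
  expect_true(mm$bin_results$degenerate[1])
})

test_that("meta p-values are uniform under the null at adequate bin sizes", {
  # fresh alphas and labels each replicate; labels independent of everything;
  # bins of 100 samples, the regime the binning guidelines call for
  set.seed(61)
  nk <- 100
  pvals <- replicate(600, {
    n <- 3 * nk
    alpha_df <- data.frame(sample_id = sprintf("s%03d", 1:n),
                           bin = rep(1:3, each = nk),
                           library_size = rep(c(1e2, 1e3, 1e4), each = nk),
                           rarefy_level = rep(c(1e2, 1e3, 1e4), each = nk),
                           alpha = rnorm(n))
    labels <- rbinom(n, 1, 0.5)
    rarebin:::multibin_meta(alpha_df, labels,
                            weighting = "ivw")$meta$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pvals <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 600))
})

test_that("bin_diagnostics reports Spearman correlations per bin", {
  alpha_df <- data.frame(
    bin = rep(1:2, each = 5),
    library_size = c(1:5 * 100, 1:5 * 1000),
    alpha = c(1:5, rep(2, 5))) # bin 1 perfectly increasing, bin 2 constant
  d <- bin_diagnostics(alpha_df)
  expect_equal(d$rho[d$bin == "1"], 1)
  expect_true(is.na(d$rho[d$bin == "2"]))
  expect_equal(d$n[d$bin == "all"], 10)
  small <- data.frame(bin = 1, library_size = c(1, 2), alpha = c(1, 2))
  expect_true(is.na(bin_diagnostics(small)$rho[1]))
})
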