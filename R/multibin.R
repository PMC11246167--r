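# The multi-bin rarefying test: depth binning, within-bin rarefying and
# association, and fixed-effect meta-analysis across bins.

# Extract a named library-size vector from a cohort data frame, a named list
# of repertoires, or a named numeric vector.
.library_sizes <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("sample_id", "library_size") %in% names(x))) {
      stop("cohort data frame needs sample_id and library_size columns")
    }
    return(stats::setNames(as.numeric(x$library_size), x$sample_id))
  }
  if (is.list(x)) {
    return(stats::setNames(vapply(x, library_size, numeric(1)),
                           vapply(x, function(r) r$sample_id, character(1))))
  }
  l <- as.numeric(x)
  names(l) <- if (is.null(names(x))) paste0("sample_", seq_along(x)) else names(x)
  l
}

#' Partition samples into library-size bins
#'
#' Assigns each sample to a bin by the half-open rule: sample i belongs to
#' bin k when c_(k-1) <= L_i < c_k, with c_0 the minimum retained library
#' size, c_K the maximum (top bin closed), and the interior thresholds given
#' by `cut_points`. Each bin's rarefying level is its own lower bound
#' L*_k = c_(k-1), so rarefying is always feasible within a bin. Cut points
#' outside the observed range, and bins left without samples, are dropped
#' with a warning.
#'
#' @param library_sizes Named numeric vector of library sizes, a cohort data
#'   frame (`sample_id`, `library_size`), or a named list of `repertoire`
#'   objects.
#' @param cut_points Strictly increasing positive interior thresholds
#'   c_1 < ... < c_(K-1).
#' @param min_depth Optional minimum library size; shallower samples are
#'   excluded (and reported in the result) before binning, so that a single
#'   failed sample cannot drag the bottom rarefying level down to a useless
#'   depth. Default: no exclusion.
#' @return A `bin_partition`: list with `samples` (sample_id, library_size,
#'   bin), `bins` (bin, lower, upper, n, rarefy_level) and `excluded`
#'   (sample ids dropped by `min_depth`).
#' @export
#' @examples
#' assign_bins(c(a = 5, b = 10, c = 25), c(10, 20))
assign_bins <- function(library_sizes, cut_points, min_depth = NULL) {
  l <- .library_sizes(library_sizes)
  if (anyNA(l) || any(l < 1)) stop("library sizes must be positive")
  cut_points <- as.numeric(cut_points)
  if (length(cut_points) && (anyNA(cut_points) || any(cut_points <= 0) ||
                             is.unsorted(cut_points, strictly = TRUE))) {
    stop("cut_points must be strictly increasing and positive")
  }
  excluded <- character(0)
  if (!is.null(min_depth)) {
    drop <- l < min_depth
    excluded <- names(l)[drop]
    l <- l[!drop]
    if (!length(l)) stop("min_depth = ", min_depth, " excludes every sample")
  }
  c0 <- min(l)
  ck <- max(l)
  usable <- cut_points[cut_points > c0 & cut_points <= ck]
  if (length(usable) < length(cut_points)) {
    warning("dropping cut point(s) outside the observed library-size range: ",
            paste(setdiff(cut_points, usable), collapse = ", "))
  }
  edges <- c(c0, usable, ck)
  if (c0 == ck) {
    k <- rep(1L, length(l))
    edges <- c(c0, ck)
  } else {
    k <- findInterval(l, edges, rightmost.closed = TRUE)
  }
  nbin <- length(edges) - 1
  tab <- tabulate(k, nbins = nbin)
  keep <- which(tab > 0)
  if (length(keep) < nbin) {
    warning("dropping empty bin(s): ",
            paste(sprintf("[%g, %g)", edges[setdiff(seq_len(nbin), keep)],
                          edges[setdiff(seq_len(nbin), keep) + 1]),
                  collapse = ", "))
  }
  bins <- data.frame(bin = seq_along(keep), lower = edges[keep],
                     upper = edges[keep + 1], n = tab[keep],
                     rarefy_level = edges[keep], row.names = NULL)
  samples <- data.frame(sample_id = names(l), library_size = as.numeric(l),
                        bin = match(k, keep), row.names = NULL,
                        stringsAsFactors = FALSE)
  structure(list(samples = samples, bins = bins, excluded = excluded,
                 cut_points = cut_points, min_depth = min_depth),
            class = "bin_partition")
}

#' @export
print.bin_partition <- function(x, ...) {
  cat("<bin_partition>", nrow(x$bins), "bin(s),", nrow(x$samples),
      "samples")
  if (length(x$excluded)) cat(",", length(x$excluded), "excluded by min_depth")
  cat("\n")
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Within-bin rarefied alpha diversity
#'
#' Rarefies every sample to the lower bound of its own bin (the defining step
#' of the multi-bin approach: deep samples keep a deep rarefying level) and
#' computes the requested diversity metric, optionally averaged over repeated
#' draws.
#'
#' @param reps Named list of `repertoire` objects (or of named counts
#'   vectors) covering every sample in the partition.
#' @param partition A [assign_bins()] result.
#' @inheritParams mean_rarefied_alpha
#' @return Data frame with columns `sample_id`, `bin`, `library_size`,
#'   `rarefy_level`, `alpha`, in partition order.
#' @export
within_bin_alpha <- function(reps, partition, metric, n_rep = 1, seed = NULL) {
  stopifnot(inherits(partition, "bin_partition"))
  counts_list <- lapply(reps, abund)
  nms <- names(reps)
  if (is.null(nms) || any(!nzchar(nms))) {
    if (all(vapply(reps, inherits, logical(1), "repertoire"))) {
      nms <- vapply(reps, function(r) r$sample_id, character(1))
    } else {
      stop("reps must be named by sample id")
    }
  }
  names(counts_list) <- nms
  ids <- partition$samples$sample_id
  miss <- setdiff(ids, nms)
  if (length(miss)) stop("repertoires missing for: ", paste(miss, collapse = ", "))
  counts_list <- counts_list[ids]
  sums <- vapply(counts_list, sum, numeric(1))
  if (any(sums != partition$samples$library_size)) {
    stop("partition library sizes do not match the supplied repertoires")
  }
  depths <- partition$bins$rarefy_level[partition$samples$bin]
  alpha <- .rarefied_alpha(counts_list, depths, metric, n_rep = n_rep,
                           seed = seed)
  data.frame(sample_id = ids, bin = partition$samples$bin,
             library_size = partition$samples$library_size,
             rarefy_level = depths, alpha = alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Association between alpha diversity and a covariate within one bin
#'
#' Ordinary least squares of alpha on the covariate within a bin: the effect
#' estimate tau_hat is the slope, V its squared standard error, and the
#' p-value the two-sided t-test of a zero slope. For a 0/1 covariate this is
#' the equal-variance two-sample t-test. Constant alpha yields a degenerate
#' result (tau_hat = 0, V = 0) flagged for exclusion from the meta-analysis.
#'
#' @param alpha Numeric alpha values for the bin's samples (`NA` dropped
#'   pairwise with the covariate).
#' @param covariate Numeric or two-level covariate, same length as `alpha`;
#'   must be non-constant.
#' @param bin Bin index recorded in the result.
#' @param min_bin_size Minimum usable number of complete pairs (default 3).
#' @return A `bin_result`: list with `bin`, `n`, `tau_hat`, `V`, `se`,
#'   `p_value`, `degenerate`.
#' @export
#' @examples
#' within_bin_association(c(1, 2, 3, 4), c(0, 0, 1, 1)) # tau 2, V 0.5
within_bin_association <- function(alpha, covariate, bin = NA_integer_,
                                   min_bin_size = 3) {
  covariate <- covariate_numeric(covariate)
  n_complete <- sum(stats::complete.cases(alpha, covariate))
  if (n_complete < min_bin_size) {
    stop("bin ", bin, " has ", n_complete, " usable samples; minimum is ",
         min_bin_size)
  }
  res <- ols_assoc(alpha, covariate)
  structure(list(bin = bin, n = res$n, tau_hat = res$estimate, V = res$V,
                 se = res$se, p_value = res$p_value,
                 degenerate = res$degenerate),
            class = "bin_result")
}

# Normalize a list of bin_result objects (or an equivalent data frame) to a
# data frame with one row per bin.
.bin_results_df <- function(bins) {
  if (is.data.frame(bins)) {
    need <- c("bin", "n", "tau_hat", "V")
    if (!all(need %in% names(bins))) {
      stop("bin results need columns: ", paste(need, collapse = ", "))
    }
    if (is.null(bins$degenerate)) bins$degenerate <- !(bins$V > 0)
    return(bins)
  }
  if (inherits(bins, "bin_result")) bins <- list(bins)
  do.call(rbind, lapply(bins, function(b) {
    data.frame(bin = b$bin, n = b$n, tau_hat = b$tau_hat, V = b$V,
               p_value = if (is.null(b$p_value)) NA_real_ else b$p_value,
               degenerate = isTRUE(b$degenerate), row.names = NULL)
  }))
}

.meta_weights <- function(df, weighting) {
  switch(weighting,
         equal = rep(1, nrow(df)),
         ssw = as.numeric(df$n),
         ivw = {
           if (any(df$V <= 0)) stop("inverse-variance weights need V > 0 in every bin")
           1 / df$V
         },
         stop("unknown weighting: ", weighting))
}

.usable_bins <- function(bins) {
  df <- .bin_results_df(bins)
  df <- df[!df$degenerate, , drop = FALSE]
  if (!nrow(df)) stop("no usable (non-degenerate) bins to pool")
  df
}

#' Pooled effect across bins
#'
#' Fixed-effect meta-analytic estimate tau_hat = sum(w_k tau_hat_k) /
#' sum(w_k), assuming a single true effect common to all bins, under one of
#' three weighting schemes: `equal` (w_k = 1), `ssw` (sample-size weights,
#' w_k = n_k) or `ivw` (inverse-variance weights, w_k = 1/V_k; optimal for
#' power under homogeneity).
#'
#' @param bins List of [within_bin_association()] results (or a data frame
#'   with columns `bin`, `n`, `tau_hat`, `V`); degenerate bins are ignored.
#' @param weighting `"ivw"`, `"ssw"` or `"equal"`.
#' @return List with `weighting`, `tau_hat`, `weights`, `bins_used`.
#' @export
pooled_effect <- function(bins, weighting = c("ivw", "ssw", "equal")) {
  weighting <- match.arg(weighting)
  df <- .usable_bins(bins)
  w <- .meta_weights(df, weighting)
  list(weighting = weighting, tau_hat = sum(w * df$tau_hat) / sum(w),
       weights = w, bins_used = df$bin)
}

#' Wald test of the pooled effect
#'
#' The pooled Wald statistic W = (sum w_k tau_hat_k)^2 / sum(w_k^2 V_k),
#' referred to a chi-squared distribution with one degree of freedom under
#' the null of no common effect. Invariant to rescaling all weights by a
#' constant; with inverse-variance weights it reduces to tau_hat^2 *
#' sum(1/V_k).
#'
#' @inheritParams pooled_effect
#' @return A `meta_result`: list with `weighting`, `tau_hat`, `W`,
#'   `p_value`, `weights`, `bins_used`.
#' @export
#' @examples
#' b <- list(within_bin_association(c(0, 1, 2, 5), c(0, 0, 1, 1), bin = 1))
#' wald_test(b, "equal")
wald_test <- function(bins, weighting = c("ivw", "ssw", "equal")) {
  weighting <- match.arg(weighting)
  df <- .usable_bins(bins)
  w <- .meta_weights(df, weighting)
  denom <- sum(w^2 * df$V)
  if (denom <= 0) stop("Wald denominator is zero; all bin variances vanish")
  wstat <- sum(w * df$tau_hat)^2 / denom
  structure(list(weighting = weighting,
                 tau_hat = sum(w * df$tau_hat) / sum(w),
                 W = wstat,
                 p_value = stats::pchisq(wstat, df = 1, lower.tail = FALSE),
                 weights = w, bins_used = df$bin),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %s: tau_hat = %.4g, W = %.4g, p = %.3g (%d bins)\n",
              x$weighting, x$tau_hat, x$W, x$p_value, length(x$bins_used)))
  invisible(x)
}

# Per-bin associations + meta-analysis from a within_bin_alpha table.
# Degenerate or failing bins are excluded from the pooling with one warning.
multibin_meta <- function(alpha_df, covariate, weighting = c("ivw", "ssw", "equal"),
                          min_bin_size = 3) {
  weighting <- match.arg(weighting, several.ok = TRUE)
  if (!is.null(names(covariate))) {
    covariate <- covariate[alpha_df$sample_id]
  } else if (length(covariate) != nrow(alpha_df)) {
    stop("covariate length does not match the alpha table")
  }
  cov_num <- covariate_numeric(covariate)
  bins <- sort(unique(alpha_df$bin))
  notes <- character(0)
  results <- lapply(bins, function(k) {
    idx <- alpha_df$bin == k
    tryCatch(
      within_bin_association(alpha_df$alpha[idx], cov_num[idx], bin = k,
                             min_bin_size = min_bin_size),
      error = function(e) {
        notes[[length(notes) + 1]] <<- paste0("bin ", k, ": ", conditionMessage(e))
        NULL
      })
  })
  results <- results[!vapply(results, is.null, logical(1))]
  if (!length(results)) stop("no bin could be analyzed: ",
                             paste(notes, collapse = "; "))
  bin_df <- .bin_results_df(results)
  if (any(bin_df$degenerate)) {
    notes <- c(notes, paste0("bin ", bin_df$bin[bin_df$degenerate],
                             ": degenerate (zero variance)"))
  }
  if (length(notes)) {
    warning("excluded from meta-analysis -- ", paste(notes, collapse = "; "))
  }
  meta <- do.call(rbind, lapply(weighting, function(w) {
    m <- wald_test(bin_df, w)
    data.frame(weighting = w, tau_hat = m$tau_hat, W = m$W,
               p_value = m$p_value, n_bins = length(m$bins_used),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(bin_results = bin_df, meta = meta)
}

#' Multi-bin rarefying association test
#'
#' The full pipeline: partition samples into library-size bins
#' ([assign_bins()]), rarefy each sample to its bin's lower bound and compute
#' alpha diversity ([within_bin_alpha()]), test the diversity--covariate
#' association within every bin by linear regression, and pool the per-bin
#' effects by fixed-effect meta-analysis with a Wald test ([wald_test()]).
#' Bins that are too small, have a constant covariate, or constant alpha are
#' excluded from the pooling with a warning. With no interior cut points the
#' procedure reduces exactly to overall rarefying at the minimum retained
#' depth.
#'
#' @param reps Named list of `repertoire` objects.
#' @param metadata Data frame with `sample_id` and the covariate column.
#' @param covariate Name of the covariate column in `metadata` (numeric or
#'   two-level).
#' @inheritParams within_bin_alpha
#' @inheritParams assign_bins
#' @param metric Diversity metric name (see [alpha_diversity()]).
#' @param weighting Character vector of weighting schemes to report (any of
#'   `"ivw"`, `"ssw"`, `"equal"`; all three by default).
#' @param min_bin_size Minimum usable samples per bin (default 3).
#' @return A `multibin_test`: list with `partition`, `alpha` (per-sample
#'   table), `bin_results`, `meta` (one row per weighting), plus the metric,
#'   covariate name, seed and excluded sample ids.
#' @export
multibin_alpha_test <- function(reps, metadata, covariate, metric = "richness",
                                cut_points = numeric(0),
                                weighting = c("ivw", "ssw", "equal"),
                                n_rep = 1, seed = NULL, min_depth = NULL,
                                min_bin_size = 3) {
  weighting <- match.arg(weighting, several.ok = TRUE)
  cohort <- cohort_table(reps, metadata)
  if (!covariate %in% names(cohort)) {
    stop("covariate '", covariate, "' not found in metadata")
  }
  partition <- assign_bins(stats::setNames(cohort$library_size, cohort$sample_id),
                           cut_points, min_depth = min_depth)
  alpha_df <- within_bin_alpha(reps, partition, metric, n_rep = n_rep,
                               seed = seed)
  cov_vec <- stats::setNames(cohort[[covariate]], cohort$sample_id)
  mm <- multibin_meta(alpha_df, cov_vec, weighting = weighting,
                      min_bin_size = min_bin_size)
  structure(list(partition = partition, alpha = alpha_df,
                 bin_results = mm$bin_results, meta = mm$meta,
                 metric = metric, covariate = covariate, n_rep = n_rep,
                 seed = seed, excluded = partition$excluded),
            class = "multibin_test")
}

#' @export
print.multibin_test <- function(x, ...) {
  cat("Multi-bin rarefying association test\n")
  cat("  metric:", x$metric, "  covariate:", x$covariate, "\n")
  if (length(x$excluded)) {
    cat("  excluded by min_depth:", length(x$excluded), "sample(s)\n")
  }
  cat("\nPer-bin results:\n")
  print(cbind(x$partition$bins[x$bin_results$bin, c("lower", "upper")],
              x$bin_results), row.names = FALSE)
  cat("\nPooled (fixed-effect meta-analysis):\n")
  print(x$meta, row.names = FALSE)
  invisible(x)
}

#' Depth diagnostics: Spearman correlation of alpha with library size
#'
#' For threshold selection: within well-chosen bins there should be little or
#' no residual correlation between rarefied alpha diversity and library size.
#' Computes the Spearman rank correlation (average ranks on ties) and its
#' p-value within each bin and across all samples.
#'
#' @param alpha_df A [within_bin_alpha()] table (columns `bin`,
#'   `library_size`, `alpha`).
#' @return Data frame with one row per bin plus an `"all"` row: `bin`, `n`,
#'   `rho`, `p_value`. Bins with fewer than 3 samples, or with constant
#'   alpha, get `NA` diagnostics.
#' @export
bin_diagnostics <- function(alpha_df) {
  need <- c("bin", "library_size", "alpha")
  if (!all(need %in% names(alpha_df))) {
    stop("alpha_df needs columns: ", paste(need, collapse = ", "))
  }
  one <- function(a, l) {
    keep <- stats::complete.cases(a, l)
    a <- a[keep]
    l <- l[keep]
    if (length(a) < 3 || stats::var(a) == 0 || stats::var(l) == 0) {
      return(c(NA_real_, NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(a, l, method = "spearman",
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }
  bins <- sort(unique(alpha_df$bin))
  rows <- lapply(bins, function(k) {
    idx <- alpha_df$bin == k
    v <- one(alpha_df$alpha[idx], alpha_df$library_size[idx])
    data.frame(bin = as.character(k), n = sum(idx), rho = v[1], p_value = v[2],
               stringsAsFactors = FALSE)
  })
  v <- one(alpha_df$alpha, alpha_df$library_size)
  rows[[length(rows) + 1]] <- data.frame(bin = "all", n = nrow(alpha_df),
                                         rho = v[1], p_value = v[2],
                                         stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
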