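# Comparison normalizations: no rarefying, overall rarefying, and LOESS
# residualization of alpha diversity on library size.

.counts_by_id <- function(reps) {
  if (inherits(reps, "repertoire")) reps <- list(reps)
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
  counts_list
}

#' Alpha diversity without normalization
#'
#' The "no rarefying" baseline: the diversity metric applied directly to the
#' raw counts of every sample, with no depth adjustment.
#'
#' @param reps Named list of `repertoire` objects (or named counts vectors).
#' @param metric Metric name, see [alpha_diversity()].
#' @return Data frame with columns `sample_id`, `library_size`, `alpha`.
#' @export
no_rarefy_alpha <- function(reps, metric) {
  if (!length(reps)) {
    return(data.frame(sample_id = character(0), library_size = numeric(0),
                      alpha = numeric(0), stringsAsFactors = FALSE))
  }
  counts_list <- .counts_by_id(reps)
  f <- metric_function(metric)
  data.frame(sample_id = names(counts_list),
             library_size = vapply(counts_list, sum, numeric(1)),
             alpha = vapply(counts_list, f, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Alpha diversity after overall rarefying
#'
#' The standard single-level normalization: samples with library size below
#' the level L* are discarded (strict inequality), the remainder are
#' subsampled without replacement to exactly L*, and the metric is computed
#' on the rarefied counts.
#'
#' @inheritParams no_rarefy_alpha
#' @param level Rarefying level L* (positive integer).
#' @inheritParams mean_rarefied_alpha
#' @return List with `alpha` (data frame `sample_id`, `library_size`,
#'   `alpha` for retained samples) and `excluded` (dropped sample ids).
#' @export
overall_rarefy_alpha <- function(reps, metric, level, n_rep = 1, seed = NULL) {
  if (length(level) != 1 || is.na(level) || level < 1) {
    stop("level must be a single positive integer")
  }
  counts_list <- .counts_by_id(reps)
  l <- vapply(counts_list, sum, numeric(1))
  keep <- l >= level
  excluded <- names(counts_list)[!keep]
  if (!any(keep)) stop("rarefying level ", level, " excludes every sample")
  counts_list <- counts_list[keep]
  alpha <- .rarefied_alpha(counts_list, rep(level, length(counts_list)),
                           metric, n_rep = n_rep, seed = seed)
  list(alpha = data.frame(sample_id = names(counts_list),
                          library_size = as.numeric(l[keep]), alpha = alpha,
                          row.names = NULL, stringsAsFactors = FALSE),
       excluded = excluded)
}

#' LOESS residualization of alpha diversity on library size
#'
#' Fits a locally weighted regression (degree-1 local polynomial, tricube
#' weights) of non-rarefied alpha diversity on library size and returns the
#' residuals, which are then used in place of the raw diversity in
#' association tests. By default the predictor is log10(library size), since
#' depths span several orders of magnitude; the raw scale is available via
#' `log_scale = FALSE`.
#'
#' @param alpha Numeric per-sample alpha values (optionally named).
#' @param library_sizes Positive library sizes, same length as `alpha`.
#' @param span LOESS span parameter in (0, 1\]; default 0.5.
#' @param log_scale Use log10(library size) as the predictor (default TRUE).
#' @return Numeric residual vector aligned with (and named like) `alpha`;
#'   entries with missing alpha stay `NA`.
#' @export
loess_residual_alpha <- function(alpha, library_sizes, span = 0.5,
                                 log_scale = TRUE) {
  if (length(alpha) != length(library_sizes)) {
    stop("alpha and library_sizes must have equal length")
  }
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  keep <- stats::complete.cases(alpha, library_sizes)
  if (sum(keep) < 10) {
    stop("LOESS residualization needs at least 10 complete samples")
  }
  x <- if (log_scale) log10(library_sizes[keep]) else library_sizes[keep]
  fit <- stats::loess(a ~ x, data = data.frame(a = alpha[keep], x = x),
                      span = span, degree = 1, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  out <- rep(NA_real_, length(alpha))
  out[keep] <- stats::residuals(fit)
  names(out) <- names(alpha)
  out
}

#' Association test for a baseline-normalized alpha diversity
#'
#' Univariate linear regression with the (normalized) alpha diversity as the
#' outcome: slope, standard error and two-sided p-value.
#'
#' @param values Per-sample normalized alpha values.
#' @param covariate Numeric or two-level covariate, same length (named
#'   vectors are aligned by name).
#' @return List with `estimate`, `se`, `p_value`, `n`.
#' @export
#' @examples
#' baseline_association(c(1, 2, 3, 4), c(0, 0, 1, 1)) # slope 2
baseline_association <- function(values, covariate) {
  if (!is.null(names(values)) && !is.null(names(covariate))) {
    covariate <- covariate[names(values)]
  }
  res <- ols_assoc(values, covariate_numeric(covariate))
  if (res$degenerate) {
    stop("association is degenerate: alpha values are constant given the covariate")
  }
  list(estimate = res$estimate, se = res$se, p_value = res$p_value, n = res$n)
}
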