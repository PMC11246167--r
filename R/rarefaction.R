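# Rarefaction: subsampling reads without replacement.
#
# A rarefied sample at depth m is an exact multivariate-hypergeometric draw
# of m reads from the sample's N reads. The draw is implemented by sampling
# m read indices from 1..N (no token vector is ever materialized) and mapping
# them to clonotypes through the cumulative counts, so memory stays
# O(m + #clonotypes) even at library sizes of 4e7.

# Core draw on a validated counts vector; assumes 1 <= depth < sum(counts).
# Sequential conditional hypergeometric draws in compiled code: no read
# token vector is ever materialized, so memory and time are O(#clonotypes)
# regardless of library size.
.rarefy_draw <- function(counts, depth) {
  out <- .rarefy_hyper_cpp(counts, depth)
  names(out) <- names(counts)
  out
}

# Rarefy pre-validated counts (depth known feasible), skipping input checks.
.rarefy_core <- function(counts, depth, n = sum(counts)) {
  if (depth == n) counts else .rarefy_draw(counts, depth)
}

#' Rarefy a sample to a fixed depth
#'
#' Draws `depth` reads uniformly without replacement from the sample's reads
#' (a multivariate hypergeometric sample), returning the subsampled counts.
#' The result always sums exactly to `depth` and is entrywise at most the
#' original counts. With `depth` equal to the library size the counts are
#' returned unchanged.
#'
#' @param x Abundance vector or `repertoire`.
#' @param depth Target depth, a positive integer at most `library_size(x)`.
#' @param seed Optional integer seed making the draw deterministic; with
#'   `NULL` the current RNG stream is used.
#' @return Numeric vector of rarefied counts, same length/names as the input
#'   abundances.
#' @export
#' @examples
#' rarefy(c(10, 0), 5) # c(5, 0)
rarefy <- function(x, depth, seed = NULL) {
  counts <- abund(x)
  n <- sum(counts)
  .check_depth(depth, n)
  if (depth == n) return(counts)
  with_rng(seed, .rarefy_draw(counts, depth))
}

# Depth validation shared by rarefy() and expected_richness().
.check_depth <- function(depth, n) {
  if (length(depth) != 1 || is.na(depth) || depth < 1 || depth != round(depth)) {
    stop("depth must be a single positive integer")
  }
  if (depth > n) {
    stop("cannot rarefy to depth ", depth, ": sample has only ", n, " reads")
  }
  invisible(depth)
}

#' Mean alpha diversity over repeated rarefying
#'
#' Averages a diversity metric over `n_rep` independent rarefying draws at
#' the same depth, damping the subsampling noise of a single draw. Replicate
#' seeds are derived from `seed` by a counter, so replicate j is reproducible
#' on its own. Replicates on which the metric is undefined (Pielou with a
#' single observed clonotype) are excluded from the mean with a warning.
#'
#' @inheritParams rarefy
#' @param metric Metric name, see [alpha_diversity()].
#' @param n_rep Number of rarefying replicates (default 1, the base
#'   procedure; averaging is opt-in).
#' @return Mean metric value, or `NA` if it was undefined on every replicate.
#' @export
#' @examples
#' mean_rarefied_alpha(c(5, 5), 4, "richness", n_rep = 3, seed = 1)
mean_rarefied_alpha <- function(x, depth, metric, n_rep = 1, seed = NULL) {
  counts <- abund(x)
  n <- sum(counts)
  .check_depth(depth, n)
  f <- metric_function(metric)
  if (n_rep < 1) stop("n_rep must be at least 1")
  vals <- vapply(seq_len(n_rep), function(j) {
    f(with_rng(derive_seed(seed, j), .rarefy_core(counts, depth, n)))
  }, numeric(1))
  if (anyNA(vals)) {
    warning("excluding ", sum(is.na(vals)), " of ", n_rep,
            " rarefying replicates on which '", metric, "' is undefined")
    if (all(is.na(vals))) return(NA_real_)
  }
  mean(vals, na.rm = TRUE)
}

#' Expected richness under rarefaction (closed form)
#'
#' The exact expectation of observed richness after rarefying to depth m:
#' E\[S\] = sum_i (1 - C(N - n_i, m) / C(N, m)), the classical hypergeometric
#' (Hurlbert) form. Serves as an analytic oracle for the random draw in
#' [rarefy()] and for exact rarefaction curves.
#'
#' @inheritParams rarefy
#' @return Real expected richness; equals the observed richness at
#'   `depth = library_size(x)`.
#' @export
#' @examples
#' expected_richness(c(2, 2), 2) # 5/3
expected_richness <- function(x, depth) {
  counts <- abund(x)
  n <- sum(counts)
  .check_depth(depth, n)
  pos <- counts[counts > 0]
  sum(1 - exp(lchoose(n - pos, depth) - lchoose(n, depth)))
}


#' Rarefaction curve
#'
#' Richness as a function of rarefying depth, either as the exact expectation
#' ([expected_richness()]; nondecreasing in depth) or as a Monte-Carlo mean
#' over `n_rep` draws per depth. Used to locate the saturation "elbow" when
#' choosing an overall rarefying level.
#'
#' @inheritParams mean_rarefied_alpha
#' @param depths Strictly increasing positive integers, all at most the
#'   library size.
#' @param method `"expected"` (default) or `"monte_carlo"`.
#' @return Data frame with columns `depth` and `richness`.
#' @export
#' @examples
#' rarefaction_curve(c(2, 2), c(1, 2)) # richness 1, 5/3
rarefaction_curve <- function(x, depths, n_rep = 1, seed = NULL,
                              method = c("expected", "monte_carlo")) {
  method <- match.arg(method)
  if (length(depths) == 0 || is.unsorted(depths, strictly = TRUE)) {
    stop("depths must be strictly increasing")
  }
  counts <- abund(x)
  vals <- vapply(seq_along(depths), function(i) {
    if (method == "expected") {
      expected_richness(counts, depths[i])
    } else {
      mean_rarefied_alpha(counts, depths[i], "richness", n_rep = n_rep,
                          seed = derive_seed(seed, i))
    }
  }, numeric(1))
  data.frame(depth = as.numeric(depths), richness = vals)
}

# Rarefied alpha for a list of counts vectors at per-sample depths, with
# per-sample sub-seeds derived by position. Shared by the multi-bin and
# overall-rarefying paths so that the K = 1 multi-bin analysis reproduces
# overall rarefying at the minimum depth exactly (same seed chain).
.rarefied_alpha <- function(counts_list, depths, metric, n_rep = 1,
                            seed = NULL) {
  vapply(seq_along(counts_list), function(i) {
    mean_rarefied_alpha(counts_list[[i]], depths[i], metric, n_rep = n_rep,
                        seed = derive_seed(seed, i))
  }, numeric(1))
}
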