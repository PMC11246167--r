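# Alpha diversity measures and Bray-Curtis dissimilarity.
#
# Four measures are supported: observed richness (unique clonotype count),
# bias-corrected Chao1, the Shannon index (natural log), and Pielou's
# evenness. Shannon and Bray-Curtis are computed through vegan; the others
# are closed-form one-liners on the singleton/doubleton counts.

# Coerce input to a validated abundance vector (zeros allowed transiently).
abund <- function(x) {
  if (inherits(x, "repertoire")) x <- x$counts
  if (!is.numeric(x) || length(x) == 0) {
    stop("expected a non-empty numeric abundance vector or a repertoire")
  }
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stop("abundances must be nonnegative integer counts")
  }
  x
}

.check_nonempty <- function(x) {
  if (sum(x) < 1) stop("abundance vector must contain at least one read")
  x
}

#' Observed richness
#'
#' The number of distinct clonotypes with a positive count ("unique sequence
#' count"); takes no account of relative frequencies.
#'
#' @param x Abundance vector (nonnegative integer counts) or `repertoire`.
#' @return Nonnegative integer.
#' @export
#' @examples
#' richness(c(3, 1, 0)) # 2
richness <- function(x) sum(abund(x) > 0)

#' Shannon index
#'
#' H = -sum p_i log p_i in natural-log units (nats), with p_i the relative
#' abundances. Ranges from 0 (single clonotype) to log(richness) (perfectly
#' even repertoire).
#'
#' @inheritParams richness
#' @return Nonnegative real.
#' @export
#' @examples
#' shannon(c(1, 1, 1, 1)) # log(4)
shannon <- function(x) {
  x <- .check_nonempty(abund(x))
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' Pielou's evenness
#'
#' J = H / log(S), the Shannon index relative to its maximum at the observed
#' richness S. Undefined for S = 1 (division by zero); the missing value `NA`
#' is returned and propagated so that downstream association tests drop, not
#' silently impute, such samples.
#'
#' @inheritParams richness
#' @return Real in \[0, 1\], or `NA` when only one clonotype is observed.
#' @export
#' @examples
#' pielou(c(7, 7, 7)) # 1
pielou <- function(x) {
  x <- .check_nonempty(abund(x))
  s <- sum(x > 0)
  if (s == 1) return(NA_real_)
  shannon(x) / log(s)
}

#' Bias-corrected Chao1 richness estimator
#'
#' S_obs + f1 (f1 - 1) / (2 (f2 + 1)), where f1 and f2 are the singleton and
#' doubleton counts. The (f2 + 1) denominator is the bias-corrected form and
#' needs no special case at f2 = 0. Always at least the observed richness,
#' with equality exactly when f1 <= 1.
#'
#' @inheritParams richness
#' @return Real >= `richness(x)`.
#' @export
#' @examples
#' chao1_bc(c(1, 1, 2)) # 3.5
chao1_bc <- function(x) {
  x <- .check_nonempty(abund(x))
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  sum(x > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Bray-Curtis dissimilarity
#'
#' BC = 1 - 2 sum min(x_i, y_i) / (N_x + N_y); 0 for identical profiles and 1
#' when no clonotype is shared. Named vectors (or repertoires) are aligned on
#' the union of their clonotype keys; unnamed vectors must have equal length.
#'
#' @param x,y Abundance vectors or `repertoire` objects, each with at least
#'   one read.
#' @return Real in \[0, 1\].
#' @export
#' @examples
#' bray_curtis(c(a = 2), c(a = 1, b = 1)) # 0.5
bray_curtis <- function(x, y) {
  x <- .check_nonempty(abund(x))
  y <- .check_nonempty(abund(y))
  if (!is.null(names(x)) && !is.null(names(y))) {
    keys <- union(names(x), names(y))
    xx <- yy <- stats::setNames(numeric(length(keys)), keys)
    xx[names(x)] <- x
    yy[names(y)] <- y
    x <- xx
    y <- yy
  } else if (length(x) != length(y)) {
    stop("unnamed abundance vectors must have equal length")
  }
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

# Look up a metric by name.
metric_function <- function(metric) {
  switch(match.arg(metric, c("richness", "chao1_bc", "shannon", "pielou")),
         richness = richness, chao1_bc = chao1_bc,
         shannon = shannon, pielou = pielou)
}

#' Alpha diversity by metric name
#'
#' Dispatch wrapper over [richness()], [chao1_bc()], [shannon()] and
#' [pielou()].
#'
#' @inheritParams richness
#' @param metric One of `"richness"`, `"chao1_bc"`, `"shannon"`, `"pielou"`.
#' @return The corresponding diversity value.
#' @export
#' @examples
#' alpha_diversity(c(1, 1), "shannon") # log(2)
alpha_diversity <- function(x, metric) {
  metric_function(metric)(x)
}
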