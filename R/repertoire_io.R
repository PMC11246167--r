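# Reading, writing and validating clonotype count tables.

.default_columns <- c(sample_id = "sample_id", v_gene = "v_gene",
                      cdr3_aa = "cdr3_aa", j_gene = "j_gene", count = "count")

#' Column mapping for AIRR rearrangement exports
#'
#' Convenience mapping from the package's canonical column roles to the AIRR
#' rearrangement schema field names, for use as the `column_map` argument of
#' [read_repertoire_table()].
#'
#' @return Named character vector mapping
#'   `sample_id, v_gene, cdr3_aa, j_gene, count` to
#'   `repertoire_id, v_call, junction_aa, j_call, duplicate_count`.
#' @export
#' @examples
#' airr_columns()
airr_columns <- function() {
  c(sample_id = "repertoire_id", v_gene = "v_call", cdr3_aa = "junction_aa",
    j_gene = "j_call", count = "duplicate_count")
}

#' Build the clonotype key from its defining triple
#'
#' A clonotype is identified by the exact triple (V gene, CDR3 amino-acid
#' sequence, J gene); no allele collapsing or CDR3 normalization is applied,
#' since any collapsing would change richness.
#'
#' @param v_gene,cdr3_aa,j_gene Character vectors (recycled to equal length).
#' @return Character vector of keys `"v|cdr3|j"`.
#' @export
#' @examples
#' clonotype_key("TRBV9", "CASSGLAGGYNEQFF", "TRBJ2-1")
clonotype_key <- function(v_gene, cdr3_aa, j_gene) {
  fields <- c(v_gene, cdr3_aa, j_gene)
  if (any(grepl("|", fields, fixed = TRUE))) {
    stop("clonotype fields must not contain the '|' key separator")
  }
  if (any(!nzchar(cdr3_aa))) stop("cdr3_aa must be non-empty")
  paste(v_gene, cdr3_aa, j_gene, sep = "|")
}

#' Construct a repertoire
#'
#' A repertoire is one sample's clonotype-to-count map. Counts must be
#' positive integers (zero-count clonotypes are not stored); the sum of the
#' counts is the sample's library size.
#'
#' @param counts Named numeric vector of positive integer read/template
#'   counts; names are clonotype keys (see [clonotype_key()]). Duplicated
#'   names are aggregated by summing.
#' @param sample_id Single character sample identifier.
#' @return An object of class `repertoire`: a list with elements `sample_id`
#'   and `counts` (sorted by clonotype key).
#' @export
#' @examples
#' repertoire(c("TRBV9|CASSF|TRBJ2-1" = 4), "s1")
repertoire <- function(counts, sample_id) {
  if (!is.character(sample_id) || length(sample_id) != 1 || is.na(sample_id)) {
    stop("sample_id must be a single character string")
  }
  if (length(counts) == 0) stop("a repertoire must contain at least one clonotype")
  nm <- names(counts)
  if (is.null(nm) || any(!nzchar(nm)) || anyNA(nm)) {
    stop("counts must be named by clonotype key")
  }
  if (anyNA(counts) || any(counts < 1) || any(counts != round(counts))) {
    stop("clonotype counts must be positive integers")
  }
  if (anyDuplicated(nm)) {
    counts <- vapply(split(as.numeric(counts), nm), sum, numeric(1))
  } else {
    counts <- as.numeric(counts)
    names(counts) <- nm
  }
  counts <- counts[order(names(counts), method = "radix")]
  structure(list(sample_id = sample_id, counts = counts), class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat("<repertoire> sample", x$sample_id, "-", length(x$counts),
      "clonotypes,", format(sum(x$counts), big.mark = ","), "reads\n")
  invisible(x)
}

#' Library size of a sample
#'
#' The library size L is the total read/template count of a sample, the
#' technical covariate whose variation across samples confounds observed
#' alpha diversity.
#'
#' @param x A `repertoire` or a numeric abundance vector.
#' @return The sum of all counts.
#' @export
#' @examples
#' library_size(repertoire(c("a|C|b" = 3, "a|D|b" = 1), "s1")) # 4
library_size <- function(x) UseMethod("library_size")

#' @export
library_size.repertoire <- function(x) sum(x$counts)

#' @export
library_size.default <- function(x) {
  if (!is.numeric(x)) stop("library_size expects a repertoire or numeric counts")
  sum(x)
}

#' Read a clonotype count table
#'
#' Reads a tab-separated table with one row per (sample, V gene, CDR3
#' amino-acid, J gene) observation and a positive integer count column, and
#' returns one [repertoire()] per distinct sample. Rows sharing a sample and
#' clonotype triple are aggregated by summing counts (exports commonly split
#' rows by nucleotide sequence), and the result is independent of the input
#' row order.
#'
#' @param path Path to a TSV file with a header.
#' @param column_map Optional named character vector remapping any of the
#'   canonical roles `sample_id, v_gene, cdr3_aa, j_gene, count` to the file's
#'   column names; see [airr_columns()] for AIRR exports.
#' @return Named list of `repertoire` objects, sorted by sample id.
#' @export
read_repertoire_table <- function(path, column_map = NULL) {
  cols <- .default_columns
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cols))
    if (length(bad)) stop("unknown column roles in column_map: ",
                          paste(bad, collapse = ", "))
    cols[names(column_map)] <- column_map
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  missing <- cols[!cols %in% names(tab)]
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0) stop("no data rows in ", path)
  cnt <- suppressWarnings(as.numeric(tab[[cols[["count"]]]]))
  bad <- which(is.na(cnt) | cnt <= 0 | cnt != round(cnt))
  if (length(bad)) {
    stop("count column '", cols[["count"]], "' must hold positive integers; ",
         "first offending data row: ", bad[1],
         " (value '", tab[[cols[["count"]]]][bad[1]], "')")
  }
  key <- clonotype_key(tab[[cols[["v_gene"]]]], tab[[cols[["cdr3_aa"]]]],
                       tab[[cols[["j_gene"]]]])
  sample <- tab[[cols[["sample_id"]]]]
  reps <- lapply(split(seq_len(nrow(tab)), sample), function(i) {
    counts <- vapply(split(cnt[i], key[i]), sum, numeric(1))
    repertoire(counts, sample[i[1]])
  })
  reps[order(names(reps), method = "radix")]
}

#' Write repertoires to a clonotype count table
#'
#' Inverse of [read_repertoire_table()] under the default column names:
#' reading a written file reproduces the same clonotype-to-count maps.
#'
#' @param reps A `repertoire` or non-empty list of them.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_repertoire_table <- function(reps, path) {
  if (inherits(reps, "repertoire")) reps <- list(reps)
  if (length(reps) == 0) stop("no repertoires to write")
  if (!all(vapply(reps, inherits, logical(1), "repertoire"))) {
    stop("reps must be repertoire objects")
  }
  rows <- do.call(rbind, lapply(reps, function(r) {
    parts <- strsplit(names(r$counts), "|", fixed = TRUE)
    if (any(lengths(parts) != 3)) {
      stop("malformed clonotype key in sample ", r$sample_id)
    }
    m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
    data.frame(sample_id = r$sample_id, v_gene = m[, 1], cdr3_aa = m[, 2],
               j_gene = m[, 3], count = r$counts, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble a cohort table from repertoires and metadata
#'
#' Builds the per-sample table (sample id, library size, covariates) used by
#' the association machinery. When the metadata already carries a
#' `library_size` column it must agree exactly with the repertoire sums.
#'
#' @param reps List of `repertoire` objects.
#' @param metadata Optional data frame with a `sample_id` column and covariate
#'   columns. Samples missing from `metadata` get `NA` covariates.
#' @return Data frame with one row per repertoire, in `reps` order.
#' @export
cohort_table <- function(reps, metadata = NULL) {
  if (inherits(reps, "repertoire")) reps <- list(reps)
  if (!length(reps)) stop("no repertoires supplied")
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicated sample ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- data.frame(sample_id = ids,
                    library_size = vapply(reps, library_size, numeric(1)),
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    if (!"sample_id" %in% names(metadata)) {
      stop("metadata must contain a sample_id column")
    }
    m <- match(out$sample_id, metadata$sample_id)
    if ("library_size" %in% names(metadata)) {
      ls_meta <- metadata$library_size[m]
      off <- which(!is.na(ls_meta) & ls_meta != out$library_size)
      if (length(off)) {
        stop("metadata library_size disagrees with repertoire sums for: ",
             paste(out$sample_id[off], collapse = ", "))
      }
    }
    extra <- setdiff(names(metadata), c("sample_id", "library_size"))
    for (col in extra) out[[col]] <- metadata[[col]][m]
  }
  out
}

#' Read a sample metadata table
#'
#' @param path TSV file with a header containing `sample_id` plus arbitrary
#'   covariate columns.
#' @return Data frame.
#' @export
read_sample_metadata <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(tab)) {
    stop("metadata file must contain a sample_id column")
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicated sample_id in ", path)
  tab
}
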