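test_that("reading aggregates duplicated clonotype rows and conserves counts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s3", "s3"),
    v_gene = c("V1", "V1", "V2", "V1", "V3", "V3"),
    cdr3_aa = c("CASSA", "CASSA", "CASSB", "CASSA", "CASSC", "CASSD"),
    j_gene = c("J1", "J1", "J1", "J1", "J2", "J2"),
    count = c(2, 3, 1, 7, 4, 6))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)

  reps <- read_repertoire_table(path)
  expect_named(reps, c("s1", "s2", "s3"))
  expect_equal(unname(reps$s1$counts[clonotype_key("V1", "CASSA", "J1")]), 5)
  expect_equal(vapply(reps, library_size, numeric(1)),
               c(s1 = 6, s2 = 7, s3 = 10))

  # order invariance: permuting input rows yields identical repertoires
  perm <- withr::with_seed(1, tab[sample(nrow(tab)), ])
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(perm, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(reps, read_repertoire_table(path2))
})

test_that("reader rejects bad counts and names missing columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tv_gene\tcdr3_aa\tj_gene\tcount",
               "s1\tV1\tCASSA\tJ1\t-1"), path)
  expect_error(read_repertoire_table(path), "positive integers")

  writeLines(c("sample_id\tv_gene\tcdr3_aa\tj_gene\tcount",
               "s1\tV1\tCASSA\tJ1\t2.5"), path)
  expect_error(read_repertoire_table(path), "row: 1")

  writeLines(c("sample_id\tv_gene\tcdr3_aa\tj_gene",
               "s1\tV1\tCASSA\tJ1"), path)
  expect_error(read_repertoire_table(path), "count")
})

test_that("column_map supports AIRR rearrangement field names", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("repertoire_id\tv_call\tjunction_aa\tj_call\tduplicate_count",
               "r1\tTRBV9\tCASSF\tTRBJ2-1\t4"), path)
  reps <- read_repertoire_table(path, column_map = airr_columns())
  expect_equal(library_size(reps$r1), 4)
  expect_named(reps$r1$counts, clonotype_key("TRBV9", "CASSF", "TRBJ2-1"))
})

test_that("write/read round-trip is the identity on the count map", {
  set.seed(5)
  reps <- list(
    a = fix_repertoire(sample(1:50, 100, replace = TRUE), "a"),
    b = fix_repertoire(c(4), "b"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_repertoire_table(reps, path)
  back <- read_repertoire_table(path)
  expect_identical(back$a$counts, reps$a$counts)
  expect_identical(back$b$counts, reps$b$counts)
  expect_error(write_repertoire_table(list(), path), "no repertoires")
})

test_that("repertoire constructor enforces positive integer counts", {
  expect_error(repertoire(c(a = 0), "s"), "positive integers")
  expect_error(repertoire(c(a = 1.5), "s"), "positive integers")
  expect_error(repertoire(numeric(0), "s"), "at least one")
  expect_error(repertoire(c(3, 1), "s"), "named")
  # duplicated keys are summed
  r <- repertoire(c(a = 2, a = 3, b = 1), "s")
  expect_equal(unname(r$counts["a"]), 5)
  expect_equal(library_size(r), 6)
})

test_that("cohort_table aligns metadata and checks library sizes", {
  reps <- list(fix_repertoire(c(3, 1), "s1"), fix_repertoire(c(10), "s2"))
  meta <- data.frame(sample_id = c("s2", "s1"), age = c(40, 60),
                     library_size = c(10, 4))
  ct <- cohort_table(reps, meta)
  expect_equal(ct$sample_id, c("s1", "s2"))
  expect_equal(ct$library_size, c(4, 10))
  expect_equal(ct$age, c(60, 40))

  meta$library_size <- c(10, 5)
  expect_error(cohort_table(reps, meta), "disagrees")
})
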