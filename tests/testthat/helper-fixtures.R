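# Fixtures are built in code; no data files.

# Named counts vector with unique synthetic clonotype keys.
fix_counts <- function(x, prefix = "A") {
  stats::setNames(x, sprintf("TRBV01|C%s%04d|TRBJ1", prefix, seq_along(x)))
}

fix_repertoire <- function(x, id, prefix = id) {
  repertoire(fix_counts(x, prefix = prefix), id)
}

# A small cohort of repertoires with library sizes spanning the given range,
# drawn from one synthetic pool so that depth and diversity are coupled.
fix_cohort <- function(n = 20, lo_exp = 3, hi_exp = 5, pool_size = 200,
                       seed = 99) {
  withr::with_seed(seed, {
    pool <- synthesize_pools(pool_size, 0)$pool_a
    l <- draw_library_sizes(n, lo_exp, hi_exp)
    reps <- lapply(seq_len(n), function(i) {
      simulate_sample(pool, l[i], sample_id = sprintf("s%03d", i))
    })
    names(reps) <- vapply(reps, function(r) r$sample_id, character(1))
    reps
  })
}
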