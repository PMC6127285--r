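toy_coverage <- function(counts, interval_bp = 200L) {
  st <- seq(0, by = interval_bp + 50L, length.out = nrow(counts))
  des <- panel_design("chr1", st, st + interval_bp, "G")
  colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  structure(list(intervals = des, counts = counts, truth = NULL,
                 batch_id = "toy"),
            class = "coverage_matrix")
}

test_that("identical samples normalize to ratios of exactly 1", {
  cov <- toy_coverage(matrix(500L, 12, 4))
  rm <- normalize_counts(cov)
  expect_true(all(rm$ratios == 1))
  expect_equal(nrow(call_cnv_intervals(rm)), 0L)
})

test_that("library-size differences are removed, not called as dosage", {
  base <- matrix(400L, 10, 4)
  base[, 2] <- 800L  # double the library, diploid dosage
  rm <- normalize_counts(toy_coverage(base))
  expect_true(all(abs(rm$ratios[, 2] - 1) < 1e-9))
})

test_that("normalization rejects degenerate batches", {
  expect_error(normalize_counts(toy_coverage(matrix(100L, 5, 2))),
               "at least 3")
  bad <- matrix(100L, 5, 4)
  bad[, 3] <- 0L
  expect_error(normalize_counts(toy_coverage(bad)), "zero total")
})

test_that("ratios are scale-invariant in any single sample", {
  set.seed(8)
  counts <- matrix(rpois(60, 400), 15, 4)
  cov <- toy_coverage(counts)
  rm1 <- normalize_counts(cov)
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 7L
  rm2 <- normalize_counts(toy_coverage(scaled))
  expect_true(all(abs(rm1$ratios - rm2$ratios) < 1e-9, na.rm = TRUE))
})

test_that("low-reference intervals are flagged uncallable, never divided", {
  counts <- matrix(400L, 8, 4)
  counts[3, ] <- c(2L, 1L, 2L, 1L)
  rm <- normalize_counts(toy_coverage(counts))
  expect_false(any(rm$callable[3, ]))
  expect_true(all(is.na(rm$ratios[3, ])))
  expect_equal(nrow(call_cnv_intervals(rm)), 0L)
})

test_that("per-interval classification matches the brute-force oracle", {
  for (s in 1:20) {
    set.seed(s)
    counts <- matrix(rpois(200, 300), 25, 8)
    counts[sample(200, 12)] <- rpois(12, 80)   # scatter deletions
    counts[sample(200, 8)] <- rpois(8, 600)    # scatter duplications
    cov <- toy_coverage(counts)
    rm <- normalize_counts(cov)
    got <- vapply(colnames(rm$ratios),
                  function(s2) classify_ratio(rm$ratios[, s2]),
                  character(nrow(counts)))
    dimnames(got) <- NULL
    expect_identical(got, oracle_classify_matrix(counts))
  }
})

test_that("merging honours min_intervals, max_gap and the zygosity bands", {
  counts <- matrix(400L, 12, 4)
  counts[6, 1] <- 200L  # isolated single-interval het deletion
  rm <- normalize_counts(toy_coverage(counts))
  expect_equal(nrow(call_cnv_intervals(rm, cnv_config(min_intervals = 2))),
               0L)
  one <- call_cnv_intervals(rm, cnv_config(min_intervals = 1))
  expect_equal(nrow(one), 1L)
  expect_equal(one$direction, "deletion")
  expect_equal(one$zygosity, "heterozygous")
  expect_equal(one$n_intervals, 1L)

  # a run with one interior normal interval merges; with max_gap 0 it
  # splits (the panel is large enough that the event does not distort the
  # carrier's library-size estimate)
  counts2 <- matrix(400L, 40, 4)
  counts2[c(3, 4, 6, 7), 2] <- 0L
  rm2 <- normalize_counts(toy_coverage(counts2))
  merged <- call_cnv_intervals(rm2)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$first_interval, 3L)
  expect_equal(merged$last_interval, 7L)
  expect_equal(merged$n_intervals, 4L)
  expect_equal(merged$zygosity, "homozygous")
  split <- call_cnv_intervals(rm2, cnv_config(max_gap = 0))
  expect_equal(nrow(split), 2L)
})

test_that("threshold monotonicity: tighter thresholds never add calls", {
  set.seed(77)
  counts <- matrix(rpois(300, 350), 30, 10)
  counts[5:8, 2] <- rpois(4, 170)
  counts[20:23, 6] <- rpois(4, 520)
  rm <- normalize_counts(toy_coverage(counts))
  base <- call_cnv_intervals(rm, cnv_config(min_intervals = 1))
  for (cfg in list(cnv_config(theta_dup = 1.6, min_intervals = 1),
                   cnv_config(theta_del = 0.45, min_intervals = 1))) {
    alt <- call_cnv_intervals(rm, cfg)
    expect_lte(sum(alt$direction == "duplication"),
               sum(base$direction == "duplication"))
    expect_lte(sum(alt$direction == "deletion"),
               sum(base$direction == "deletion"))
  }
})

test_that("heterozygous-deletion ratios concentrate inside the het band", {
  # Monte-Carlo oracle against the generative model: CN1 event cells land
  # in [0.4, 0.6] in at least 95% of seeded replicates
  ok <- vapply(1:200, function(s) {
    st <- seq(0, by = 600, length.out = 40)
    des <- panel_design("chr1", st, st + 500, "G")
    ev <- tibble::tibble(sample = 1L, first_interval = 10L,
                         last_interval = 12L, copy_number = 1L)
    cov <- simulate_coverage(des, sim_config(
      n_samples = 6, mean_depth = 600, library_size_sd = 0.15,
      cnv_events = ev, seed = s))
    rm <- normalize_counts(cov)
    all(rm$ratios[10:12, 1] > 0.4 & rm$ratios[10:12, 1] < 0.6)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("calls within a sample are sorted and non-overlapping", {
  set.seed(31)
  counts <- matrix(rpois(400, 350), 40, 10)
  counts[4:6, 3] <- 0L
  counts[15:18, 3] <- rpois(4, 175)
  counts[30:33, 3] <- rpois(4, 525)
  rm <- normalize_counts(toy_coverage(counts))
  calls <- call_cnv_intervals(rm)
  for (s in unique(calls$sample)) {
    cs <- calls[calls$sample == s, ]
    if (nrow(cs) > 1L) {
      expect_true(all(diff(cs$first_interval) > 0))
      expect_true(all(cs$first_interval[-1] > cs$last_interval[-nrow(cs)]))
    }
  }
})
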