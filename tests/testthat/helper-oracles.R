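# Independent brute-force oracles used by unit and acceptance tests.
# Each recomputes the checked quantity by direct per-element evaluation,
# never calling the implementation under test.

# per-cell ratio classification: rescale by batch mean total, leave-one-out
# median reference, strict thresholds
oracle_classify_matrix <- function(counts, theta_del = 0.6, theta_dup = 1.40,
                                   min_ref = 50) {
  totals <- colSums(counts)
  rescaled <- counts
  for (s in seq_len(ncol(counts))) {
    rescaled[, s] <- counts[, s] * mean(totals) / totals[s]
  }
  out <- matrix("normal", nrow(counts), ncol(counts))
  for (i in seq_len(nrow(counts))) {
    for (s in seq_len(ncol(counts))) {
      ref <- median(rescaled[i, -s])
      if (ref < min_ref) next
      r <- rescaled[i, s] / ref
      if (r < theta_del) out[i, s] <- "del"
      if (r > theta_dup) out[i, s] <- "dup"
    }
  }
  out
}

# set-comprehension version of the QC retain rule
oracle_qc_keep <- function(dp, fs, min_dp = 20, max_fs = 60) {
  vapply(seq_along(dp), function(i) {
    !is.na(dp[i]) && !is.na(fs[i]) && dp[i] >= min_dp && fs[i] <= max_fs
  }, logical(1))
}

# set-comprehension version of the MAF retain rule (conjunction over
# observed databases; absence passes)
oracle_maf_keep <- function(maf_matrix, threshold = 0.015) {
  vapply(seq_len(nrow(maf_matrix)), function(i) {
    v <- maf_matrix[i, ]
    all(is.na(v) | v < threshold)
  }, logical(1))
}

# direct transcription of the per-tool splice pass rules
oracle_splice_pass <- function(tool, wt, mut, site) {
  active <- if (site == "native-site-loss") wt else mut
  if (active == 0) return(FALSE)
  variation <- abs(mut - wt) / active * 100
  if (tool == "MaxEnt") return(active >= 2 && variation > 15)
  if (tool == "HSF") return(active >= 70 && variation > 10)
  active > 0.4 && variation > 10
}

# one simulated batch with a known 3-interval event; returns the event
# description, the coverage matrix and the calls
simulate_known_event_batch <- function(seed, n_intervals = 200L,
                                       n_samples = 6L, depth = 600,
                                       span = 3L) {
  set.seed(seed + 5000)
  cn <- sample(c(0L, 1L, 3L), 1)
  fi <- sample(seq_len(n_intervals - span + 1L), 1)
  carrier <- 1L + (seed %% n_samples)
  ev <- tibble::tibble(sample = carrier, first_interval = fi,
                       last_interval = fi + span - 1L, copy_number = cn)
  st <- seq(0, by = 600, length.out = n_intervals)
  des <- withr::with_seed(seed,
    panel_design("chr1", st, st + 500, "GENE", "coding-exon",
                 stats::runif(n_intervals, 0.9, 1.1)))
  cov <- simulate_coverage(des, sim_config(
    n_samples = n_samples, mean_depth = depth, library_size_sd = 0.15,
    cnv_events = ev, seed = seed))
  list(event = ev, coverage = cov,
       expected_direction = if (cn == 3L) "duplication" else "deletion",
       expected_zygosity = c("homozygous", "heterozygous", NA,
                             "heterozygous")[cn + 1L])
}

# random splice-score sets spanning losses, gains and absent tools
random_splice_scores <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      maxent_wt = ifelse(stats::runif(n) < 0.3, NA, stats::runif(n, 0, 12)),
      maxent_mut = ifelse(stats::runif(n) < 0.3, NA, stats::runif(n, 0, 12)),
      hsf_wt = ifelse(stats::runif(n) < 0.3, NA, stats::runif(n, 0, 100)),
      hsf_mut = ifelse(stats::runif(n) < 0.3, NA, stats::runif(n, 0, 100)),
      nns_wt = ifelse(stats::runif(n) < 0.3, NA, stats::runif(n)),
      nns_mut = ifelse(stats::runif(n) < 0.3, NA, stats::runif(n)),
      splice_site = sample(c("native-site-loss", "cryptic-site-gain"), n,
                           replace = TRUE)
    )
  })
}
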