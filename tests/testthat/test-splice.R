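test_that("per-tool thresholds reproduce hand-computed outcomes", {
  # MaxEnt 8.0 -> 5.0: variation 37.5% with score >= 2 passes
  expect_true(evaluate_splice_tool("MaxEnt", 8.0, 5.0, "native-site-loss"))
  # MaxEnt active score below 2 fails regardless of variation
  expect_false(evaluate_splice_tool("MaxEnt", 1.5, 0.2, "native-site-loss"))
  # HSF 90 -> 89: variation 1.1% fails
  expect_false(evaluate_splice_tool("HSF", 90, 89, "native-site-loss"))
  # NNSPLICE 0.95 -> 0.94: 1.05% < 10% fails
  expect_false(evaluate_splice_tool("NNSPLICE", 0.95, 0.94,
                                    "native-site-loss"))
  expect_true(evaluate_splice_tool("NNSPLICE", 0.95, 0.20,
                                   "native-site-loss"))
  # cryptic gain: variation evaluated against the new site's score
  expect_true(evaluate_splice_tool("HSF", 0, 75, "cryptic-site-gain"))
  expect_false(evaluate_splice_tool("HSF", 74, 75, "cryptic-site-gain"))
  # absent tool is skipped, not failed
  expect_true(is.na(evaluate_splice_tool("MaxEnt", NA, NA,
                                         "native-site-loss")))
  expect_error(evaluate_splice_tool("NNSPLICE", 1.2, 0.5,
                                    "native-site-loss"), "\\[0, 1\\]")
})

test_that("per-tool evaluation matches a brute-force grid", {
  grid <- expand.grid(wt = c(0, 0.5, 1.9, 2, 2.5, 8, 10),
                      mut = c(0, 0.5, 1.7, 2, 5, 8, 9.5),
                      site = c("native-site-loss", "cryptic-site-gain"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    expect_identical(
      evaluate_splice_tool("MaxEnt", grid$wt[i], grid$mut[i], grid$site[i]),
      oracle_splice_pass("MaxEnt", grid$wt[i], grid$mut[i], grid$site[i]))
  }
  hsf <- expand.grid(wt = c(0, 40, 69, 70, 85, 100),
                     mut = c(0, 45, 70, 76, 92),
                     site = c("native-site-loss", "cryptic-site-gain"),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(hsf))) {
    expect_identical(
      evaluate_splice_tool("HSF", hsf$wt[i], hsf$mut[i], hsf$site[i]),
      oracle_splice_pass("HSF", hsf$wt[i], hsf$mut[i], hsf$site[i]))
  }
})

test_that("combination policies follow their truth tables", {
  # build score sets realising every pass/fail combination of three tools
  pass_scores <- list(maxent = c(8, 5), hsf = c(90, 60), nns = c(0.9, 0.2))
  fail_scores <- list(maxent = c(8, 7.5), hsf = c(90, 89),
                      nns = c(0.95, 0.94))
  combos <- expand.grid(m = c(TRUE, FALSE), h = c(TRUE, FALSE),
                        n = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    pick <- function(tool, on) if (on) pass_scores[[tool]] else
      fail_scores[[tool]]
    sc <- list(maxent_wt = pick("maxent", combos$m[i])[1],
               maxent_mut = pick("maxent", combos$m[i])[2],
               hsf_wt = pick("hsf", combos$h[i])[1],
               hsf_mut = pick("hsf", combos$h[i])[2],
               nns_wt = pick("nns", combos$n[i])[1],
               nns_mut = pick("nns", combos$n[i])[2],
               splice_site = "native-site-loss")
    n_pass <- sum(unlist(combos[i, ]))
    expect_equal(evaluate_splice_variant(sc, "majority")$flagged, n_pass >= 2)
    expect_equal(evaluate_splice_variant(sc, "any")$flagged, n_pass >= 1)
    expect_equal(evaluate_splice_variant(sc, "all")$flagged, n_pass == 3)
  }
})

test_that("policy flag sets are nested: any >= majority >= all", {
  scores <- random_splice_scores(400, seed = 12)
  flags <- lapply(c("any", "majority", "all"), function(p)
    splice_flag_variants(scores, policy = p)$splice_flag)
  expect_true(all(flags[[2]] <= flags[[1]]))
  expect_true(all(flags[[3]] <= flags[[2]]))
})

test_that("verdicts are deterministic and tools without scores are skipped", {
  sc <- list(maxent_wt = NA, maxent_mut = NA, hsf_wt = 80, hsf_mut = 55,
             nns_wt = 0.8, nns_mut = 0.1, splice_site = "native-site-loss")
  a <- evaluate_splice_variant(sc)
  expect_identical(a, evaluate_splice_variant(sc))
  expect_equal(a$n_tools, 2L)
  expect_true(a$flagged)
  none <- evaluate_splice_variant(list(maxent_wt = NA, maxent_mut = NA,
                                       hsf_wt = NA, hsf_mut = NA,
                                       nns_wt = NA, nns_mut = NA,
                                       splice_site = NA))
  expect_false(none$flagged)
  expect_equal(none$n_tools, 0L)
})
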