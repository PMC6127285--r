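toy_map <- tibble::tibble(
  gene = c("USH2A", "ABCA4", "CNGB3", "FSCN2"),
  mode = c("autosomal-recessive", "autosomal-recessive",
           "autosomal-recessive", "autosomal-dominant"),
  phenotypes = c("RP;USH", "STGD;RP;COD", "COD;STGD", "RP"))

toy_family <- function(diagnosis = "sRP", prior_gene = "USH2A",
                       seg = FALSE) {
  tibble::tibble(family_id = "FAM", index_id = "II:1",
                 clin_diagnosis = diagnosis, inheritance = "simplex",
                 segregation_available = seg, prior_gene = prior_gene,
                 prior_variant = "V0", prior_gene2 = NA_character_,
                 prior_variant2 = NA_character_)
}

toy_variant <- function(id, gene = "USH2A", consequence = "missense",
                        zygosity = "het", db_label = "absent",
                        novel = FALSE, segregation = "unavailable",
                        splice_flag = FALSE, missense_pred = NA_character_,
                        votes = c(NA, NA, NA)) {
  tibble::tibble(variant_id = id, gene = gene, consequence = consequence,
                 zygosity = zygosity, db_label = db_label,
                 db_votes_path = votes[1], db_votes_benign = votes[2],
                 db_votes_vus = votes[3], novel = novel,
                 missense_pred = missense_pred, splice_flag = splice_flag,
                 segregation = segregation)
}

test_that("causality criteria classify the canonical evidence patterns", {
  fam <- toy_family()
  # known pathogenic allele, phenotype-consistent, relatives unavailable:
  # presumed causal
  a <- assess_causality(toy_variant("v1", db_label = "pathogenic"), fam,
                        toy_map)
  expect_equal(a$classification, "causal")
  expect_match(a$rationale, "presumed")
  # failed segregation (in cis) excludes outright
  b <- assess_causality(toy_variant("v2", consequence = "deep-intronic",
                                    novel = TRUE, splice_flag = TRUE,
                                    segregation = "inconsistent"),
                        fam, toy_map)
  expect_equal(b$classification, "excluded")
  expect_match(b$rationale, "cis")
  # novel frameshift with consistent segregation: maximal evidence
  c3 <- assess_causality(toy_variant("v3", consequence = "frameshift",
                                     novel = TRUE,
                                     segregation = "consistent"),
                         fam, toy_map)
  expect_equal(c3$classification, "causal")
  # deep-intronic without segregation is capped at candidate
  d <- assess_causality(toy_variant("v4", consequence = "deep-intronic",
                                    novel = TRUE, splice_flag = TRUE),
                        fam, toy_map)
  expect_equal(d$classification, "candidate")
  expect_match(d$rationale, "capped")
  # majority-benign conflicting database record excludes
  e <- assess_causality(toy_variant("v5", db_label = "conflicting",
                                    votes = c(4, 5, 0)), fam, toy_map)
  expect_equal(e$classification, "excluded")
  # majority-pathogenic conflicting record counts as database-pathogenic
  f <- assess_causality(toy_variant("v6", db_label = "conflicting",
                                    votes = c(13, 0, 2)), fam, toy_map)
  expect_equal(f$classification, "causal")
  # gene-phenotype mismatch excludes
  g <- assess_causality(toy_variant("v7", gene = "CNGB3",
                                    db_label = "pathogenic"), fam, toy_map)
  expect_equal(g$classification, "excluded")
})

test_that("genotype models complete per inheritance mode", {
  mk <- function(...) {
    rows <- list(...)
    tibble::tibble(
      variant_id = vapply(rows, `[[`, "", 1),
      classification = vapply(rows, `[[`, "", 2),
      zygosity = vapply(rows, `[[`, "", 3),
      segregates = vapply(rows, `[[`, "", 4))
  }
  hom <- check_genotype_model(mk(list("a", "causal", "hom", "yes")))
  expect_equal(hom$status, "completed-causal")
  expect_equal(hom$model, "homozygous")
  # unphased double het completes with an explicit flag
  ch <- check_genotype_model(mk(list("a", "causal", "het", "NA"),
                                list("b", "causal", "het", "yes")))
  expect_equal(ch$status, "completed-causal")
  expect_match(ch$notes, "phase unconfirmed")
  # the cohort-defining monoallelic state never completes
  single <- check_genotype_model(mk(list("a", "causal", "het", "yes")))
  expect_equal(single$status, "incomplete")
  expect_equal(check_genotype_model(mk())$status, "incomplete")
  # candidate-only completion is capped below causal
  cand <- check_genotype_model(mk(list("a", "candidate", "het", "NA"),
                                  list("b", "candidate", "het", "NA")))
  expect_equal(cand$status, "completed-candidate")
  # contradictory double-homozygous causal genotype
  contra <- check_genotype_model(mk(list("a", "causal", "hom", "yes"),
                                    list("b", "causal", "hom", "yes")))
  expect_equal(contra$status, "inconsistent")
  # dominant gene: one confirmed het completes; unconfirmed stays candidate
  dom <- check_genotype_model(mk(list("a", "causal", "het", "yes")),
                              "autosomal-dominant")
  expect_equal(dom$status, "completed-causal")
  dom2 <- check_genotype_model(mk(list("a", "candidate", "het", "NA")),
                               "autosomal-dominant")
  expect_equal(dom2$status, "completed-candidate")
})

test_that("the stepwise search mirrors the published family patterns", {
  map <- load_cohort_fixture()$gene_phenotypes
  # family-E pattern: prior missense plus novel nonsense in USH2A
  famE <- toy_family("sRP", "USH2A")
  candE <- dplyr::bind_rows(
    toy_variant("M9", db_label = "conflicting", votes = c(13, 0, 2)),
    toy_variant("M8", consequence = "nonsense", novel = TRUE))
  rE <- prioritize_family(famE, candE, map)
  expect_equal(rE$status, "solved")
  expect_equal(rE$causal_gene, "USH2A")
  expect_equal(rE$causal_alleles, "M8;M9")
  expect_equal(rE$model, "compound-het")
  # family-B pattern: prior gene empty-handed, homozygous hit elsewhere
  famB <- toy_family("COD", "ABCA4")
  candB <- toy_variant("M3", gene = "CNGB3", consequence = "frameshift",
                       zygosity = "hom", db_label = "conflicting",
                       votes = c(14, 0, 1), segregation = "consistent")
  rB <- prioritize_family(famB, candB, map)
  expect_equal(rB$status, "solved")
  expect_equal(rB$causal_gene, "CNGB3")
  expect_match(rB$notes, "different locus")
  # family-S pattern: unsegregated deep-intronic pair completes at
  # candidate level only
  famS <- toy_family("sRP", "USH2A")
  candS <- dplyr::bind_rows(
    toy_variant("m33"),
    toy_variant("m39", consequence = "deep-intronic", novel = TRUE,
                splice_flag = TRUE),
    toy_variant("m40", consequence = "deep-intronic", novel = TRUE,
                splice_flag = TRUE))
  rS <- prioritize_family(famS, candS, map)
  expect_equal(rS$status, "candidate")
  expect_equal(rS$causal_alleles, "")
  # no candidates at all
  r0 <- prioritize_family(toy_family(), candE[0, ], map)
  expect_equal(r0$status, "unsolved")
})

test_that("prioritization is deterministic and permutation-invariant", {
  cohort <- load_cohort_fixture()
  pipe <- run_cohort_pipeline(cohort)
  again <- run_cohort_pipeline(cohort)
  expect_identical(pipe$results, again$results)
  shuffled <- cohort
  withr::with_seed(10, {
    shuffled$variants <- shuffled$variants[sample(nrow(shuffled$variants)), ]
  })
  res2 <- run_cohort_pipeline(shuffled)$results
  expect_identical(pipe$results, res2)
})

test_that("excluded alleles never reach the causal allele list", {
  pipe <- run_cohort_pipeline()
  assessed_excluded <- c("m33b", "m36", "m37", "m5", "m6", "m4")
  alleles <- unlist(strsplit(pipe$results$causal_alleles, ";"))
  expect_false(any(assessed_excluded %in% alleles))
})
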