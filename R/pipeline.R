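#' Run the whole second-hit workflow on a cohort
#'
#' Chains the stages exactly as the analysis applies them: record-level
#' screening (depth/strand-bias QC, then the population-frequency filter),
#' splice-rule evaluation of the retained variants, per-family stepwise
#' prioritization, and cohort-level aggregation.
#'
#' @param cohort a `cohort_fixture`; defaults to the packaged 29-family
#'   fixture.
#' @param screen_cfg a [screen_config()].
#' @param policy splice combination policy (see [evaluate_splice_variant()]).
#' @return List with `screen` (retained/rejected), `candidates` (retained +
#'   splice flags), `results` (per-family) and `summary`.
#' @export
run_cohort_pipeline <- function(cohort = load_cohort_fixture(),
                                screen_cfg = screen_config(),
                                policy = "majority") {
  screened <- screen_variants(cohort$variants, screen_cfg)
  candidates <- splice_flag_variants(screened$retained, policy = policy)
  results <- prioritize_cohort(cohort, candidates)
  summary <- summarize_cohort(results, cohort)
  list(screen = screened, candidates = candidates, results = results,
       summary = summary)
}
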