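#' Evaluate one splice-predictor tool against its decision thresholds
#'
#' Decision rules over externally produced scores (the predictors themselves
#' are not run here):
#' * MaxEntScan: active-site score >= 2 and relative score variation > 15%;
#' * HSF: active-site score >= 70 and variation > 10%;
#' * NNSPLICE: active-site score > 0.4 and variation > 10%.
#'
#' The "active" site is the biologically relevant one for the event: the
#' wild-type site for a native-site loss, the mutant (new) site for a
#' cryptic-site gain. Variation is `|mutant - wild_type| / active * 100`,
#' i.e. relative to the wild-type score for a loss and to the new site's
#' score for a gain (so a site arising from nothing scores a 100% change
#' rather than a division by zero).
#'
#' @param tool `"MaxEnt"`, `"HSF"` or `"NNSPLICE"`.
#' @param wild_type,mutant tool scores for the site in the reference and
#'   mutated sequence. `NA` for both means the tool was not run.
#' @param site `"native-site-loss"` or `"cryptic-site-gain"`.
#' @return `TRUE`/`FALSE` pass flag, or `NA` if the tool has no scores.
#' @export
evaluate_splice_tool <- function(tool = c("MaxEnt", "HSF", "NNSPLICE"),
                                 wild_type, mutant,
                                 site = c("native-site-loss",
                                          "cryptic-site-gain")) {
  tool <- match.arg(tool)
  site <- match.arg(site)
  if (is.na(wild_type) && is.na(mutant)) return(NA)
  wt <- ifelse(is.na(wild_type), 0, wild_type)
  mut <- ifelse(is.na(mutant), 0, mutant)
  if (tool == "NNSPLICE") {
    abort_if(any(c(wt, mut) < 0 | c(wt, mut) > 1),
             "NNSPLICE scores must lie in [0, 1]")
  }
  if (tool == "HSF") {
    abort_if(any(c(wt, mut) < 0 | c(wt, mut) > 100),
             "HSF scores must lie in [0, 100]")
  }
  active <- if (site == "native-site-loss") wt else mut
  if (active == 0) return(FALSE)
  variation <- abs(mut - wt) / active * 100
  switch(tool,
         MaxEnt = active >= 2 && variation > 15,
         HSF = active >= 70 && variation > 10,
         NNSPLICE = active > 0.4 && variation > 10)
}

#' Combine per-tool splice verdicts for one variant
#'
#' The combination policy is configurable; the default flags a variant as
#' predicted splice-altering when at least two of the tools with scores pass
#' (majority-style, mirroring the practice of citing multiple concordant
#' predictors), `"any"` when at least one passes, `"all"` when every
#' available tool passes.
#'
#' @param scores named list/row with `maxent_wt`, `maxent_mut`, `hsf_wt`,
#'   `hsf_mut`, `nns_wt`, `nns_mut` (any pair may be `NA`) and `splice_site`.
#' @param policy `"majority"`, `"any"` or `"all"`.
#' @return List with `per_tool` (named logical, `NA` = not run), `n_tools`,
#'   `n_pass`, `flagged`, `rationale`.
#' @export
evaluate_splice_variant <- function(scores, policy = c("majority", "any",
                                                       "all")) {
  policy <- match.arg(policy)
  site <- scores$splice_site %||% "native-site-loss"
  if (is.na(site)) site <- "native-site-loss"
  g <- function(nm) {
    v <- scores[[nm]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  per_tool <- c(
    MaxEnt = evaluate_splice_tool("MaxEnt", g("maxent_wt"), g("maxent_mut"),
                                  site),
    HSF = evaluate_splice_tool("HSF", g("hsf_wt"), g("hsf_mut"), site),
    NNSPLICE = evaluate_splice_tool("NNSPLICE", g("nns_wt"), g("nns_mut"),
                                    site)
  )
  avail <- !is.na(per_tool)
  n_pass <- sum(per_tool[avail])
  n_tools <- sum(avail)
  # majority needs two concordant tools when two or more were run; with a
  # single tool run it degenerates to that tool's verdict, which keeps the
  # any >= majority >= all containment ordering on every input
  flagged <- if (n_tools == 0L) FALSE else switch(policy,
    majority = n_pass >= min(2L, n_tools),
    any = n_pass >= 1L,
    all = n_pass == n_tools)
  list(per_tool = per_tool, n_tools = n_tools, n_pass = n_pass,
       flagged = flagged,
       rationale = sprintf("%d/%d available tools pass under %s policy",
                           n_pass, n_tools, policy))
}

#' Flag predicted splice-altering variants in a table
#'
#' Applies [evaluate_splice_variant()] to every row carrying splice-score
#' columns (`maxent_wt/mut`, `hsf_wt/mut`, `nns_wt/mut`, `splice_site`).
#' Rows with no scores at all are not flagged.
#'
#' @param variants variant tibble.
#' @param policy combination policy, see [evaluate_splice_variant()].
#' @return The input with logical `splice_flag` and character
#'   `splice_rationale` columns appended.
#' @export
splice_flag_variants <- function(variants, policy = "majority") {
  variants <- tibble::as_tibble(variants)
  cols <- c("maxent_wt", "maxent_mut", "hsf_wt", "hsf_mut", "nns_wt",
            "nns_mut")
  for (cc in c(cols, "splice_site")) {
    if (!cc %in% names(variants)) {
      variants[[cc]] <- if (cc == "splice_site") NA_character_ else NA_real_
    }
  }
  res <- purrr::map(seq_len(nrow(variants)), function(i)
    evaluate_splice_variant(as.list(variants[i, ]), policy = policy))
  variants$splice_flag <- purrr::map_lgl(res, "flagged")
  variants$splice_rationale <- purrr::map_chr(res, "rationale")
  variants
}
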