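# Client-report rendering. Reports expose only case identifiers, never
# raw training-case texts, and always carry a caveat block.

CAVEAT_TEXT <- paste(
  "This automated text assessment is a screening aid, not a diagnosis.",
  "Estimates are retrieved from judgments previously made on similar",
  "training cases and must be reviewed by a qualified counselor before",
  "any clinical decision."
)

#' Try an assessment, capturing the insufficient-evidence refusal
#'
#' Like [assess()], but an insufficient-evidence condition is returned as
#' a structured refusal object (class `sitr_refusal`) instead of an error,
#' so batch workflows and report rendering can handle it uniformly.
#'
#' @inheritParams assess
#' @return A `sitr_assessment` or a `sitr_refusal`.
#' @export
assess_safely <- function(raw_text, codebook, ...) {
  tryCatch(
    assess(raw_text, codebook, ...),
    sitr_insufficient_evidence = function(e) {
      structure(list(doc_id = e$doc_id %||% NA_character_,
                     status = "insufficient_evidence",
                     message = conditionMessage(e),
                     n_matched = e$n_matched %||% NA_integer_),
                class = "sitr_refusal")
    }
  )
}

#' @export
print.sitr_refusal <- function(x, ...) {
  cat("Assessment refused (insufficient evidence):", x$message, "\n")
  invisible(x)
}

report_payload <- function(result) {
  if (inherits(result, "sitr_refusal")) {
    return(list(
      status = "insufficient_evidence",
      case = result$doc_id,
      message = result$message,
      n_matched_tokens = result$n_matched,
      caveats = CAVEAT_TEXT
    ))
  }
  list(
    status = "ok",
    case = result$doc_id,
    assessment_summary = list(
      predicted_subset = result$predicted_subset,
      subset_semantics = result$subset_semantics,
      severity_estimate = result$severity_estimate,
      severity_sd = result$severity_sd,
      outcome_estimate = result$outcome_estimate,
      outcome_sd = result$outcome_sd
    ),
    topic_profile = as.list(setNames(as.integer(result$input_profile),
                                     names(result$input_profile))),
    intervention_priorities =
      if (is.null(result$priority_ranking)) NULL
      else as.list(result$priority_ranking[order(result$priority_ranking)]),
    matched_case = list(case_id = result$matched_case_id,
                        similarity = result$case_similarity),
    matched_tokens = result$match_events[
      result$match_events$subset == result$predicted_subset,
      c("input_position", "token", "base_rep_score", "position_bonus",
        "risk_bonus", "contribution")],
    caveats = CAVEAT_TEXT,
    config = result$config
  )
}

#' Render a client report
#'
#' Deterministic rendering of an assessment (or refusal) as JSON or
#' markdown. Section order: assessment summary, topic profile,
#' intervention priorities, matched-token audit trail, caveats. JSON
#' output is byte-stable for identical input; a generation timestamp is
#' included only when supplied explicitly, so default renders stay
#' reproducible.
#'
#' @param result A `sitr_assessment` or `sitr_refusal`.
#' @param format `"json"` or `"markdown"`.
#' @param timestamp Optional character timestamp to embed.
#' @return A character scalar (JSON) or vector of markdown lines.
#' @export
render_report <- function(result, format = c("json", "markdown"),
                          timestamp = NULL) {
  if (length(format) > 1L) format <- format[1]
  if (!format %in% c("json", "markdown")) {
    stop_sitr("sitr_config_error", paste0("unknown report format: ", format))
  }
  payload <- report_payload(result)
  if (!is.null(timestamp)) payload$generated <- timestamp
  if (format == "json") {
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, null = "null",
                                         dataframe = "rows")))
  }
  md <- c("# Text assessment report", "")
  if (!is.null(timestamp)) md <- c(md, paste("Generated:", timestamp), "")
  if (payload$status == "insufficient_evidence") {
    md <- c(md,
      "## Assessment refused",
      "",
      payload$message,
      "",
      "## Caveats",
      "",
      payload$caveats)
    return(md)
  }
  s <- payload$assessment_summary
  md <- c(md,
    paste("Case:", payload$case),
    "",
    "## Assessment summary",
    "",
    sprintf("- Predicted subset: %s (%s)", s$predicted_subset,
            s$subset_semantics),
    sprintf("- Severity estimate: %.2f (subset SD %.2f), scale 1-7",
            s$severity_estimate, s$severity_sd),
    sprintf("- Expected negative-outcome estimate: %.2f (subset SD %.2f), scale 1-7",
            s$outcome_estimate, s$outcome_sd),
    "",
    "## Topic profile",
    "",
    sprintf("- %s: %d", names(payload$topic_profile),
            unlist(payload$topic_profile)),
    "",
    "## Intervention priorities",
    "")
  if (is.null(payload$intervention_priorities)) {
    md <- c(md, "- (no priority ranking cached for the matched case)")
  } else {
    pr <- payload$intervention_priorities
    md <- c(md, sprintf("%d. %s", unlist(pr), names(pr)))
  }
  mt <- payload$matched_tokens
  md <- c(md,
    "",
    sprintf("Best-matched training case: %s (cosine similarity %.3f)",
            payload$matched_case$case_id, payload$matched_case$similarity),
    "",
    "## Matched tokens (audit trail)",
    "",
    sprintf("- pos %d `%s`: %.3f (+%.1f position, +%.1f risk)",
            mt$input_position, mt$token, mt$base_rep_score,
            mt$position_bonus, mt$risk_bonus),
    "",
    "## Caveats",
    "",
    payload$caveats)
  md
}
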