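# Beta-test-style validation: assess held-out cases, compare machine
# estimates against reference judgments, and apply an equivalence
# criterion.

#' Validate a codebook against reference judgments
#'
#' Assesses each held-out case; cases refused for insufficient evidence
#' are logged and excluded (mirroring real screening behavior on very
#' short writings). Machine severity/outcome estimates and the reference
#' judgments are then compared with a one-way MANOVA (machine vs
#' reference on the two criteria) plus per-criterion agreement statistics
#' (ICC(2,2) treating machine and reference as two raters, and Pearson
#' correlations). The summary passes when the configured equivalence
#' criterion holds; the default is a non-significant multivariate test at
#' `alpha` — a deliberately weak notion of equivalence, flagged as such.
#'
#' @param codebook A `sitr_codebook`.
#' @param heldout Tibble: `doc_id`, `text`, `ref_severity`, `ref_outcome`.
#' @param stoplist,w_pos,w_risk,min_matches,tokenizer Passed to [assess()].
#' @param alpha Significance level of the equivalence criterion.
#' @return Object of class `sitr_validation`: per-case table, exclusion
#'   log, `manova` (a `sitr_manova`), `agreement` tibble, and `pass`.
#' @export
run_validation <- function(codebook, heldout, stoplist = character(0),
                           w_pos = 1.0, w_risk = 1.0, min_matches = 3L,
                           tokenizer = "default", alpha = 0.05) {
  stopifnot(all(c("doc_id", "text", "ref_severity", "ref_outcome")
                %in% names(heldout)))
  if (nrow(heldout) < 2L) {
    stop_sitr("sitr_input_error", "need at least 2 held-out cases")
  }
  results <- purrr::map(seq_len(nrow(heldout)), function(i) {
    assess_safely(heldout$text[[i]], codebook, stoplist = stoplist,
                  w_pos = w_pos, w_risk = w_risk,
                  min_matches = min_matches, tokenizer = tokenizer,
                  doc_id = heldout$doc_id[[i]])
  })
  refused <- vapply(results, inherits, logical(1), "sitr_refusal")
  exclusions <- tibble::tibble(
    doc_id = heldout$doc_id[refused],
    reason = vapply(results[refused], function(r) r$message, character(1))
  )
  ok <- results[!refused]
  if (length(ok) < 2L) {
    stop_sitr("sitr_input_error",
              "fewer than 2 cases survived assessment; cannot validate")
  }
  per_case <- tibble::tibble(
    doc_id = heldout$doc_id[!refused],
    predicted_subset = vapply(ok, `[[`, character(1), "predicted_subset"),
    machine_severity = vapply(ok, `[[`, numeric(1), "severity_estimate"),
    machine_outcome = vapply(ok, `[[`, numeric(1), "outcome_estimate"),
    ref_severity = heldout$ref_severity[!refused],
    ref_outcome = heldout$ref_outcome[!refused]
  )

  dv <- rbind(
    cbind(severity = per_case$machine_severity,
          outcome = per_case$machine_outcome),
    cbind(severity = per_case$ref_severity,
          outcome = per_case$ref_outcome)
  )
  src <- rep(c("machine", "reference"), each = nrow(per_case))
  mv <- one_way_manova(src, dv)

  agreement <- dplyr::bind_rows(
    dplyr::mutate(icc_2k(cbind(per_case$machine_severity,
                               per_case$ref_severity)),
                  criterion = "severity"),
    dplyr::mutate(icc_2k(cbind(per_case$machine_outcome,
                               per_case$ref_outcome)),
                  criterion = "outcome")
  )

  structure(list(
    per_case = per_case,
    exclusions = exclusions,
    n_assessed = nrow(per_case),
    n_excluded = sum(refused),
    manova = mv,
    agreement = agreement,
    alpha = alpha,
    pass = mv$p > alpha
  ), class = "sitr_validation")
}

#' @export
print.sitr_validation <- function(x, ...) {
  cat("Validation:", x$n_assessed, "assessed,", x$n_excluded,
      "excluded (insufficient evidence)\n")
  cat(sprintf("MANOVA (machine vs reference): Wilks = %.4f, F(%g, %.1f) = %.3f, p = %.4g -> %s\n",
              x$manova$wilks, x$manova$df1, x$manova$df2, x$manova$F,
              x$manova$p,
              if (x$pass) "pass (indistinguishable at alpha)" else "fail"))
  invisible(x)
}

#' @method glance sitr_validation
#' @export
glance.sitr_validation <- function(x, ...) {
  tibble::tibble(
    n_assessed = x$n_assessed, n_excluded = x$n_excluded,
    wilks = x$manova$wilks, F = x$manova$F, p = x$manova$p,
    alpha = x$alpha, pass = x$pass
  )
}

#' @method tidy sitr_validation
#' @export
tidy.sitr_validation <- function(x, ...) x$per_case
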