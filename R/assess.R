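# The two-tier inference: H1 weighted subset scoring and selection,
# H2 topic-profile matching to a training case, and assembly of the
# assessment result.

#' Match input tokens against the codebook (H1 scoring ledger)
#'
#' Scans the filtered input tokens in text order. Each distinct token type
#' is scored at most once per subset, at its first occurrence; its base
#' contribution is its representativeness score in that subset. The first
#' three distinct input token types that match the codebook receive a
#' single position bonus `w_pos` (main points tend to open a narrative),
#' credited in the first subset -- screening order A, B, C, D -- where the
#' token matches; tokens in the risk lexicon additionally receive `w_risk`
#' in every subset where they match. Every contribution is logged as a
#' match event so the final probability score decomposes exactly into its
#' parts.
#'
#' @param input_tokens Character vector, already tokenized and
#'   stoplist-filtered, in text order.
#' @param codebook A `sitr_codebook`.
#' @param w_pos,w_risk Bonus weights (defaults 1; set 0 to ablate).
#' @return List with `events` (tibble: input_position, token, subset,
#'   base_rep_score, position_bonus, risk_bonus, contribution) and
#'   `scores` (tibble: subset, probability_score, match_count, one row per
#'   subset A-D).
#' @export
match_tokens <- function(input_tokens, codebook, w_pos = 1.0, w_risk = 1.0) {
  stopifnot(inherits(codebook, "sitr_codebook"), w_pos >= 0, w_risk >= 0)
  subsets <- subset_labels()$subset
  ent <- codebook$entries
  first_pos <- match(unique(input_tokens), input_tokens)
  types <- input_tokens[first_pos]

  events <- list()
  n_matched_types <- 0L
  for (i in seq_along(types)) {
    tok <- types[i]
    hits <- ent[ent$token == tok, c("subset", "rep_score", "is_risk")]
    if (nrow(hits) == 0L) next
    n_matched_types <- n_matched_types + 1L
    # one position bonus per token, in its first-matching subset (A..D)
    pos_bonus <- rep(0, nrow(hits))
    if (n_matched_types <= 3L) {
      pos_bonus[order(hits$subset)[1]] <- w_pos
    }
    risk_bonus <- if (tok %in% codebook$risk_lexicon) w_risk else 0
    events[[length(events) + 1L]] <- tibble::tibble(
      input_position = first_pos[i] - 1L,
      token = tok,
      subset = hits$subset,
      base_rep_score = hits$rep_score,
      position_bonus = pos_bonus,
      risk_bonus = risk_bonus,
      contribution = hits$rep_score + pos_bonus + risk_bonus
    )
  }
  events <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(input_position = integer(0), token = character(0),
                   subset = character(0), base_rep_score = numeric(0),
                   position_bonus = numeric(0), risk_bonus = numeric(0),
                   contribution = numeric(0))

  scores <- events |>
    dplyr::group_by(.data$subset) |>
    dplyr::summarise(probability_score = sum(.data$contribution),
                     match_count = dplyr::n_distinct(.data$token),
                     .groups = "drop") |>
    dplyr::right_join(tibble::tibble(subset = subsets), by = "subset") |>
    dplyr::mutate(
      probability_score = dplyr::coalesce(.data$probability_score, 0),
      match_count = dplyr::coalesce(.data$match_count, 0L)
    ) |>
    dplyr::arrange(.data$subset)

  list(events = events, scores = scores)
}

#' H1 subset selection
#'
#' Ranks the four subsets by probability score (descending), breaking ties
#' by the absolute number of distinct matched tokens (descending), and
#' residual exact ties by the severity-conservative precedence
#' B > A > D > C.
#'
#' @param scores Tibble with columns `subset`, `probability_score`,
#'   `match_count` (all four subsets).
#' @return The selected subset label, or `NA_character_` when every score
#'   is zero (insufficient evidence; [assess()] turns this into an error).
#' @export
h1_select_subset <- function(scores) {
  stopifnot(all(subset_labels()$subset %in% scores$subset))
  if (all(scores$probability_score == 0)) return(NA_character_)
  prec <- match(scores$subset, subset_precedence())
  ord <- order(-scores$probability_score, -scores$match_count, prec)
  scores$subset[ord[1]]
}

profile_cosine <- function(a, b) {
  na <- sqrt(sum(as.numeric(a)^2))
  nb <- sqrt(sum(as.numeric(b)^2))
  if (na == 0 || nb == 0) return(0)
  sum(as.numeric(a) * as.numeric(b)) / (na * nb)
}

#' H2 best-case matching
#'
#' Compares the input's topic profile with every cached training-case
#' profile of the selected subset by cosine similarity over the subset's
#' topic-title axis. Ties are broken by the number of shared nonzero
#' topics (more first), then by lexicographically smallest case id. An
#' all-zero input profile has similarity 0 to every case and falls through
#' to the tie rules.
#'
#' @param input_profile A `sitr_topic_profile` (from [topic_profile()]).
#' @param codebook A `sitr_codebook` with cached case profiles.
#' @param subset Subset label to search within.
#' @return List with `case_id`, `similarity`.
#' @export
h2_best_case <- function(input_profile, codebook, subset) {
  cp <- codebook$case_profiles
  if (!is.null(cp)) cp <- cp[cp$subset == subset, , drop = FALSE]
  if (is.null(cp) || nrow(cp) == 0L) {
    stop_sitr("sitr_input_error",
              paste0("no training-case profiles for subset ", subset))
  }
  sims <- vapply(cp$profile, function(p) {
    p <- p[names(input_profile)]
    profile_cosine(input_profile, p)
  }, numeric(1))
  shared <- vapply(cp$profile, function(p) {
    p <- p[names(input_profile)]
    sum(as.integer(input_profile) > 0 & as.integer(p) > 0)
  }, integer(1))
  ord <- order(-sims, -shared, cp$case_id, method = "radix")
  list(case_id = cp$case_id[ord[1]], similarity = sims[ord[1]])
}

#' Assess a free-text writing through the two-tier hierarchy
#'
#' Tokenizes and stoplist-filters the input, scores it against the four
#' subsets (H1), selects a subset, builds the input's topic profile within
#' that subset, matches it to the most similar training case (H2), and
#' assembles the result: severity and outcome estimates are the selected
#' subset's stored judgment means; the intervention-priority ranking is
#' retrieved from the matched case. Fully deterministic.
#'
#' When fewer than `min_matches` distinct token types match any subset,
#' assessment is refused with an insufficient-evidence error (condition
#' class `sitr_insufficient_evidence`) rather than returning an
#' unreliable result.
#'
#' @param raw_text A single character string.
#' @param codebook A `sitr_codebook`.
#' @param stoplist Character vector of tokens to drop before matching.
#' @param w_pos,w_risk H1 bonus weights; see [match_tokens()].
#' @param min_matches Minimum distinct matched token types (default 3).
#' @param tokenizer Passed to [tokenize()].
#' @param doc_id Optional identifier echoed in the result.
#' @return An object of class `sitr_assessment`.
#' @export
assess <- function(raw_text, codebook, stoplist = character(0),
                   w_pos = 1.0, w_risk = 1.0, min_matches = 3L,
                   tokenizer = "default", doc_id = NA_character_) {
  stopifnot(inherits(codebook, "sitr_codebook"))
  tokens <- filter_tokens(tokenize(raw_text, tokenizer), stoplist)
  m <- match_tokens(tokens, codebook, w_pos = w_pos, w_risk = w_risk)
  n_distinct_matched <- dplyr::n_distinct(m$events$token)
  if (n_distinct_matched < min_matches) {
    stop_sitr("sitr_insufficient_evidence",
              paste0("only ", n_distinct_matched, " distinct token(s) ",
                     "matched the codebook (need ", min_matches,
                     "); refusing to assess"),
      doc_id = doc_id, n_matched = n_distinct_matched
    )
  }
  predicted <- h1_select_subset(m$scores)
  profile <- topic_profile(tokens, codebook, predicted)
  best <- h2_best_case(profile, codebook, predicted)
  summ <- codebook$subsets[codebook$subsets$subset == predicted, ]
  cp <- codebook$case_profiles
  priorities <- cp$priorities[[match(best$case_id, cp$case_id)]]

  config <- list(w_pos = w_pos, w_risk = w_risk, min_matches = min_matches,
                 tokenizer = if (is.function(tokenizer)) "custom"
                             else tokenizer,
                 stoplist_size = length(stoplist))
  structure(list(
    doc_id = doc_id,
    predicted_subset = predicted,
    subset_semantics = summ$semantics,
    subset_scores = m$scores,
    match_events = m$events,
    severity_estimate = summ$mean_severity,
    severity_sd = summ$sd_severity,
    outcome_estimate = summ$mean_outcome,
    outcome_sd = summ$sd_outcome,
    input_profile = profile,
    matched_case_id = best$case_id,
    case_similarity = best$similarity,
    priority_ranking = priorities,
    n_tokens = length(tokens),
    config = c(config, config_hash = config_hash(config))
  ), class = "sitr_assessment")
}

#' @export
print.sitr_assessment <- function(x, ...) {
  cat("Assessment", if (!is.na(x$doc_id)) paste0("of ", x$doc_id), "\n")
  cat("  predicted subset:", x$predicted_subset,
      paste0("(", x$subset_semantics, ")"), "\n")
  cat(sprintf("  severity estimate: %.2f (SD %.2f)   outcome estimate: %.2f (SD %.2f)\n",
              x$severity_estimate, x$severity_sd,
              x$outcome_estimate, x$outcome_sd))
  cat("  matched case:", x$matched_case_id,
      sprintf("(cosine %.3f)", x$case_similarity), "\n")
  invisible(x)
}

#' Tidy an assessment into its subset-score table
#'
#' @param x A `sitr_assessment`.
#' @param ... Unused.
#' @return Tibble with one row per subset: probability score, match count,
#'   and whether it was selected.
#' @method tidy sitr_assessment
#' @export
tidy.sitr_assessment <- function(x, ...) {
  x$subset_scores |>
    dplyr::mutate(selected = .data$subset == x$predicted_subset)
}

#' @method glance sitr_assessment
#' @export
glance.sitr_assessment <- function(x, ...) {
  tibble::tibble(
    doc_id = x$doc_id,
    predicted_subset = x$predicted_subset,
    severity_estimate = x$severity_estimate,
    outcome_estimate = x$outcome_estimate,
    matched_case_id = x$matched_case_id,
    case_similarity = x$case_similarity,
    n_tokens = x$n_tokens,
    n_matched = dplyr::n_distinct(x$match_events$token)
  )
}

#' Plot the H1 subset scores of an assessment
#'
#' @param object A `sitr_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sitr_assessment
#' @export
autoplot.sitr_assessment <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$subset,
                                   y = .data$probability_score,
                                   fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "subset", y = "probability score")
}
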