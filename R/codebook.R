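# Build, serialize and query the scored codebook: per-subset key tokens
# with representativeness scores, topic metadata, risk flags, subset
# judgment summaries, and cached training-case topic profiles.

CODEBOOK_SCHEMA <- "1.0"

#' Token representativeness scores
#'
#' Standardizes raw within-subset token frequencies to \[0, 1\] by min-max:
#' the most frequent codebook token of a subset scores 1, the least
#' frequent 0. When all frequencies are equal (including a single-token
#' table) every token scores 1, so matches still contribute.
#'
#' @param freq Named numeric vector of token frequencies (one subset).
#' @return Named numeric vector of scores in \[0, 1\].
#' @export
#' @examples
#' representativeness_scores(c(a = 10, b = 7, c = 4))
representativeness_scores <- function(freq) {
  if (length(freq) == 0L) {
    stop_sitr("sitr_input_error", "empty frequency table")
  }
  rng <- range(freq)
  if (rng[1] == rng[2]) {
    return(setNames(rep(1, length(freq)), names(freq)))
  }
  setNames((freq - rng[1]) / (rng[2] - rng[1]), names(freq))
}

default_topic_titles <- function(K) paste0("topic-", seq_len(K) - 1L)

#' Build the scored codebook from four subset topic models
#'
#' Each subset contributes the key tokens of its topics as codebook
#' entries. A token appearing in several topics of one subset is housed in
#' the topic where its weight is maximal (lowest topic index on exact
#' ties), so the audit trail from a matched token to a topic is
#' unambiguous. Representativeness scores are min-max standardized raw
#' frequencies within the subset's training documents; tokens from the
#' risk lexicon are flagged. Per-subset judgment summaries and per-case
#' topic profiles are cached for the H2 matching stage.
#'
#' @param models Named list `list(A = , B = , C = , D = )` of `sitr_lda`
#'   fits, one per subset.
#' @param cases Tibble of training cases: `doc_id`, `subset`, `tokens`
#'   (list-column of filtered token vectors), `merged_severity`,
#'   `mean_outcome`, and optionally `priorities` (list-column of named
#'   integer rankings over [priority_domains()]).
#' @param risk_lexicon Character vector of high-risk tokens.
#' @param titles Optional named list `subset -> character(K)` of topic
#'   titles (index order); defaults to `"topic-<k>"`.
#' @param tokens_per_topic,min_weight Key-token extraction bounds per topic.
#' @return An object of class `sitr_codebook`.
#' @export
build_codebook <- function(models, cases, risk_lexicon = character(0),
                           titles = NULL, tokens_per_topic = 20,
                           min_weight = 0.001) {
  subsets <- subset_labels()$subset
  missing_m <- setdiff(subsets, names(models))
  if (length(missing_m) > 0) {
    stop_sitr("sitr_config_error",
              paste0("missing subset model(s): ",
                     paste(missing_m, collapse = ", ")))
  }
  stopifnot(all(c("doc_id", "subset", "tokens", "merged_severity",
                  "mean_outcome") %in% names(cases)))

  entries <- purrr::map_dfr(subsets, function(s) {
    m <- models[[s]]
    tt <- if (!is.null(titles)) titles[[s]] else default_topic_titles(m$K)
    if (is.null(tt) || length(tt) != m$K) {
      stop_sitr("sitr_config_error",
                paste0("titles for subset ", s, " must have length ", m$K))
    }
    per_topic <- purrr::map_dfr(seq_len(m$K) - 1L, function(k) {
      toks <- key_tokens(m, k, n = tokens_per_topic, min_weight = min_weight)
      if (length(toks) == 0L) return(tibble::tibble())
      tibble::tibble(
        subset = s, token = toks, topic_index = k,
        topic_title = tt[k + 1L],
        proportion_estimate = m$proportion_estimates[k + 1L],
        weight = m$phi[k + 1L, toks]
      )
    })
    if (nrow(per_topic) == 0L) {
      stop_sitr("sitr_input_error",
                paste0("no codebook-eligible tokens for subset ", s))
    }
    # house each token in its max-weight topic (lowest index on ties)
    per_topic <- per_topic |>
      dplyr::arrange(.data$token, dplyr::desc(.data$weight),
                     .data$topic_index) |>
      dplyr::distinct(.data$token, .keep_all = TRUE)

    sub_tokens <- unlist(cases$tokens[cases$subset == s])
    freq <- table(factor(sub_tokens, levels = sort(unique(per_topic$token))))
    rep_score <- representativeness_scores(as.numeric(freq) |>
                                             setNames(names(freq)))
    per_topic |>
      dplyr::mutate(rep_score = unname(rep_score[.data$token]),
                    is_risk = .data$token %in% risk_lexicon) |>
      dplyr::select("subset", "token", "rep_score", "topic_index",
                    "topic_title", "proportion_estimate", "is_risk") |>
      dplyr::arrange(.data$topic_index, dplyr::desc(.data$rep_score),
                     .data$token)
  })

  summaries <- cases |>
    dplyr::group_by(.data$subset) |>
    dplyr::summarise(
      n = dplyr::n(),
      sd_severity = if (dplyr::n() > 1) sd(.data$merged_severity) else 0,
      sd_outcome = if (dplyr::n() > 1) sd(.data$mean_outcome) else 0,
      mean_severity = mean(.data$merged_severity),
      mean_outcome = mean(.data$mean_outcome),
      .groups = "drop"
    ) |>
    dplyr::right_join(subset_labels(), by = "subset") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::select("subset", "semantics", "n", "mean_severity",
                  "sd_severity", "mean_outcome", "sd_outcome") |>
    dplyr::arrange(.data$subset)

  cb <- structure(list(
    schema_version = CODEBOOK_SCHEMA,
    entries = entries,
    subsets = summaries,
    risk_lexicon = sort(unique(risk_lexicon)),
    case_profiles = NULL,
    meta = list(
      built = NA_character_,
      tokens_per_topic = tokens_per_topic, min_weight = min_weight,
      lda_settings = purrr::map(models, "settings")
    )
  ), class = "sitr_codebook")

  cb$case_profiles <- cases |>
    dplyr::mutate(
      profile = purrr::map2(.data$tokens, .data$subset,
                            ~topic_profile(.x, cb, .y)),
      priorities = if ("priorities" %in% names(cases)) .data$priorities
                   else purrr::map(seq_len(nrow(cases)), ~NULL)
    ) |>
    dplyr::select(case_id = "doc_id", "subset", "profile", "priorities")
  cb
}

subset_topics <- function(codebook, subset) {
  codebook$entries |>
    dplyr::filter(.data$subset == !!subset) |>
    dplyr::distinct(.data$topic_index, .data$topic_title,
                    .data$proportion_estimate) |>
    dplyr::arrange(.data$topic_index)
}

#' Topic profile of a token set within a subset
#'
#' For each topic title of the subset, the profile value is that topic's
#' integer proportion estimate if any input token matches any codebook
#' entry housed in the topic, and 0 otherwise. This is the H2 comparison
#' object: keys are the subset's topic titles, in topic-index order.
#'
#' @param tokens Character vector of (filtered) input tokens.
#' @param codebook A `sitr_codebook`.
#' @param subset Subset label, one of A-D.
#' @return Named integer vector (class `sitr_topic_profile`).
#' @export
topic_profile <- function(tokens, codebook, subset) {
  if (!subset %in% codebook$entries$subset &&
      !subset %in% subset_labels()$subset) {
    stop_sitr("sitr_input_error", paste0("unknown subset: ", subset))
  }
  topics <- subset_topics(codebook, subset)
  ent <- codebook$entries[codebook$entries$subset == subset, ]
  matched_topics <- unique(ent$topic_index[ent$token %in% tokens])
  vals <- ifelse(topics$topic_index %in% matched_topics,
                 topics$proportion_estimate, 0L)
  structure(as.integer(vals), names = topics$topic_title,
            class = "sitr_topic_profile")
}

#' @export
print.sitr_topic_profile <- function(x, ...) {
  cat(paste0(names(x), ": ", as.integer(x), collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.sitr_codebook <- function(x, ...) {
  cat("Codebook (schema", x$schema_version, "):",
      nrow(x$entries), "entries,",
      length(x$risk_lexicon), "risk tokens,",
      if (is.null(x$case_profiles)) 0L else nrow(x$case_profiles),
      "cached case profiles\n")
  print(x$subsets)
  invisible(x)
}

#' Tidy a codebook into its entry table
#'
#' @param x A `sitr_codebook`.
#' @param ... Unused.
#' @return The entries tibble (subset, token, rep_score, topic_index,
#'   topic_title, proportion_estimate, is_risk).
#' @method tidy sitr_codebook
#' @export
tidy.sitr_codebook <- function(x, ...) x$entries

#' @method glance sitr_codebook
#' @export
glance.sitr_codebook <- function(x, ...) {
  tibble::tibble(
    n_entries = nrow(x$entries),
    n_subsets = dplyr::n_distinct(x$entries$subset),
    n_risk = sum(x$entries$is_risk),
    n_cases = if (is.null(x$case_profiles)) 0L else nrow(x$case_profiles),
    schema_version = x$schema_version
  )
}

#' Write / read a codebook (JSON), and export entries as CSV
#'
#' The JSON round-trip is semantically lossless. The CSV export mirrors
#' the printed codebook layout: one row per entry with columns subset,
#' token, rep_score, topic_index, topic_title, proportion_estimate,
#' is_risk.
#'
#' @param codebook A `sitr_codebook`.
#' @param path Output path.
#' @return `path` invisibly; `read_codebook()` returns the codebook.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "sitr_codebook"))
  cp <- codebook$case_profiles
  obj <- list(
    schema_version = codebook$schema_version,
    entries = codebook$entries,
    subsets = codebook$subsets,
    risk_lexicon = codebook$risk_lexicon,
    case_profiles = if (!is.null(cp)) list(
      case_id = cp$case_id, subset = cp$subset,
      profile = purrr::map(cp$profile, ~as.list(setNames(as.integer(.x),
                                                         names(.x)))),
      priorities = purrr::map(cp$priorities,
                              ~if (is.null(.x)) NULL else as.list(.x))
    ),
    meta = codebook$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) {
    stop_sitr("sitr_io_error", paste0("file not found: ", path))
  }
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_sitr("sitr_io_error",
                              paste0("malformed codebook JSON: ",
                                     conditionMessage(e))))
  if (is.null(obj$schema_version) ||
      !identical(as.character(obj$schema_version), CODEBOOK_SCHEMA)) {
    stop_sitr("sitr_io_error",
              paste0("unsupported codebook schema: ",
                     obj$schema_version %||% "<missing>"))
  }
  entries <- purrr::map_dfr(obj$entries, tibble::as_tibble)
  entries$topic_index <- as.integer(entries$topic_index)
  entries$proportion_estimate <- as.integer(entries$proportion_estimate)
  missing_s <- setdiff(subset_labels()$subset, unique(entries$subset))
  if (length(missing_s) > 0) {
    stop_sitr("sitr_io_error",
              paste0("codebook missing subset(s): ",
                     paste(missing_s, collapse = ", ")))
  }
  subsets <- purrr::map_dfr(obj$subsets, function(r) {
    tibble::as_tibble(lapply(r, function(x) x %||% NA))
  })
  subsets$n <- as.integer(subsets$n)
  cp <- NULL
  if (!is.null(obj$case_profiles) && length(obj$case_profiles$case_id) > 0) {
    raw <- obj$case_profiles
    cp <- tibble::tibble(
      case_id = as.character(unlist(raw$case_id)),
      subset = as.character(unlist(raw$subset)),
      profile = purrr::map(raw$profile, function(p) {
        structure(as.integer(unlist(p)), names = names(p),
                  class = "sitr_topic_profile")
      }),
      priorities = purrr::map(raw$priorities, function(p) {
        if (is.null(p) || length(p) == 0) NULL
        else setNames(as.integer(unlist(p)), names(p))
      })
    )
  }
  structure(list(
    schema_version = as.character(obj$schema_version),
    entries = entries,
    subsets = subsets,
    risk_lexicon = as.character(unlist(obj$risk_lexicon) %||% character(0)),
    case_profiles = cp,
    meta = obj$meta
  ), class = "sitr_codebook")
}

#' @rdname write_codebook
#' @export
export_codebook_csv <- function(codebook, path) {
  stopifnot(inherits(codebook, "sitr_codebook"))
  write.csv(codebook$entries, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
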