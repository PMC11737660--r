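# Document model, tokenization, screening, and the judgment-merging /
# subset-partition logic that labels training cases.

#' The five intervention-priority domains
#'
#' Counselors rank five counseling domains from 1 (highest priority) to 5;
#' the machine retrieves the ranking of the best-matched training case.
#'
#' @return Character vector of the five domain names, in canonical order.
#' @export
priority_domains <- function() {
  c("traits_personality", "thoughts", "emotions",
    "past_environment", "current_environment")
}

#' Tokenize raw text into unigram tokens
#'
#' The default tokenizer NFC-normalizes the text, lowercases it (Hangul and
#' other caseless scripts pass through unchanged), and extracts maximal runs
#' of Unicode word characters (letters, digits, underscore). A morphological
#' analyzer can be plugged in by passing a function in place of the
#' tokenizer name; it receives the NFC-normalized text and must return a
#' character vector of tokens in text order.
#'
#' @param raw_text A single character string (UTF-8).
#' @param tokenizer `"default"` or a function `function(text) tokens`.
#' @return Character vector of tokens in text order (possibly empty).
#' @export
#' @examples
#' tokenize("I cut my arm. I cried.")
tokenize <- function(raw_text, tokenizer = "default") {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  if (is.na(raw_text)) return(character(0))
  text <- stringi::stri_trans_nfc(raw_text)
  if (is.function(tokenizer)) {
    out <- tokenizer(text)
    return(as.character(out))
  }
  if (!identical(tokenizer, "default")) {
    stop_sitr("sitr_config_error",
              paste0("unknown tokenizer: ", tokenizer))
  }
  text <- stringi::stri_trans_tolower(text)
  toks <- stringi::stri_extract_all_regex(text, "[\\p{L}\\p{N}_]+")[[1]]
  if (length(toks) == 1L && is.na(toks)) character(0) else toks
}

#' Remove stoplist tokens
#'
#' Drops tokens present in the stoplist (the analogue of excluding empty
#' morphemes such as pre- and postpositions); order is preserved.
#'
#' @param tokens Character vector of tokens.
#' @param stoplist Character vector of tokens to drop.
#' @return The retained subsequence of `tokens`.
#' @export
filter_tokens <- function(tokens, stoplist = character(0)) {
  if (length(stoplist) == 0L) return(tokens)
  tokens[!tokens %in% stoplist]
}

#' Read a token list (stoplist or risk lexicon)
#'
#' Plain text, one token per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector of tokens.
#' @export
read_token_list <- function(path) {
  if (!file.exists(path)) {
    stop_sitr("sitr_io_error", paste0("file not found: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Screen documents against inclusion criteria
#'
#' A document is retained iff it satisfies every configured criterion;
#' unset criteria are skipped. The rejection log records the first failed
#' criterion per document, checked in the order min_chars, min_tokens,
#' required_keyword, min_suitability.
#'
#' @param docs Tibble with columns `doc_id`, `text`, optionally
#'   `suitability` (numeric mean expert rating).
#' @param min_chars,min_tokens Minimum raw character / token counts.
#' @param required_keyword Token that must appear among the tokens, or `NULL`.
#' @param min_suitability Minimum mean suitability rating, or `NULL`
#'   (applied only when a `suitability` column is present).
#' @param tokenizer Passed to [tokenize()].
#' @return List with `retained` (input rows passing) and `rejected`
#'   (tibble `doc_id`, `reason`).
#' @export
screen_documents <- function(docs, min_chars = 0L, min_tokens = 0L,
                             required_keyword = NULL,
                             min_suitability = NULL,
                             tokenizer = "default") {
  stopifnot(all(c("doc_id", "text") %in% names(docs)))
  reason <- rep(NA_character_, nrow(docs))
  for (i in seq_len(nrow(docs))) {
    txt <- docs$text[[i]]
    if (nchar(txt) < min_chars) { reason[i] <- "min_chars"; next }
    toks <- tokenize(txt, tokenizer)
    if (length(toks) < min_tokens) { reason[i] <- "min_tokens"; next }
    if (!is.null(required_keyword) && !required_keyword %in% toks) {
      reason[i] <- "required_keyword"; next
    }
    if (!is.null(min_suitability) && "suitability" %in% names(docs) &&
        !is.na(docs$suitability[[i]]) &&
        docs$suitability[[i]] < min_suitability) {
      reason[i] <- "min_suitability"; next
    }
  }
  keep <- is.na(reason)
  list(
    retained = docs[keep, , drop = FALSE],
    rejected = tibble::tibble(doc_id = docs$doc_id[!keep],
                              reason = reason[!keep])
  )
}

#' Merge rater judgments into case-level severity and outcome
#'
#' Case severity and expected intervention difficulty are strongly
#' correlated in training judgments, so they are merged into one severity
#' indicator: the arithmetic mean of all severity and difficulty values
#' pooled across raters. Expected treatment outcome is averaged separately.
#'
#' @param judgments Tibble with columns `case_id`, `severity`, `difficulty`,
#'   `outcome` (integers 1-7), one row per rater x case.
#' @return Tibble with one row per case: `case_id`, `merged_severity`,
#'   `mean_outcome`.
#' @export
merge_judgments <- function(judgments) {
  stopifnot(all(c("case_id", "severity", "difficulty", "outcome")
                %in% names(judgments)))
  if (nrow(judgments) == 0L) {
    stop_sitr("sitr_input_error", "no judgments supplied")
  }
  judgments |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      merged_severity = mean(c(.data$severity, .data$difficulty)),
      mean_outcome = mean(.data$outcome),
      .groups = "drop"
    )
}

#' Partition cases into the four training subsets
#'
#' Serious iff merged severity >= `severity_threshold`; negative outcome
#' concerning iff mean outcome >= `outcome_threshold` (both inclusive).
#' Crossing the two gives A (serious, positive), B (serious, negative),
#' C (not as serious, positive), D (not as serious, negative). The default
#' thresholds are the midpoint-style pair consistent with the published
#' subset summary means; both are configuration, not constants.
#'
#' @param cases Tibble with columns `merged_severity`, `mean_outcome`.
#' @param severity_threshold,outcome_threshold Cut points in (1, 7).
#' @return `cases` with a `subset` column added (character, A-D).
#' @export
partition_subsets <- function(cases, severity_threshold = 4.0,
                              outcome_threshold = 3.5) {
  stopifnot(severity_threshold > 1, severity_threshold < 7,
            outcome_threshold > 1, outcome_threshold < 7)
  serious <- cases$merged_severity >= severity_threshold
  negative <- cases$mean_outcome >= outcome_threshold
  cases$subset <- dplyr::case_when(
    serious & !negative ~ "A",
    serious & negative ~ "B",
    !serious & !negative ~ "C",
    !serious & negative ~ "D"
  )
  cases
}

#' Read a corpus from JSONL or CSV
#'
#' JSONL: one JSON object per line with fields `id` (or `doc_id`), `text`,
#' and optionally `suitability`, judgment fields, and a `subset` label.
#' CSV: the same columns. Document IDs are preserved verbatim.
#'
#' @param path File path; format inferred from the extension
#'   (`.jsonl`/`.ndjson` vs `.csv`) unless `format` is given.
#' @param format `"jsonl"` or `"csv"`, optional.
#' @return Tibble with at least `doc_id` and `text`.
#' @export
read_corpus <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop_sitr("sitr_io_error", paste0("file not found: ", path))
  }
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  df <- switch(format,
    jsonl = {
      lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      recs <- lapply(lines, jsonlite::fromJSON)
      dplyr::bind_rows(lapply(recs, function(r) {
        tibble::as_tibble(r[!vapply(r, is.null, logical(1))])
      }))
    },
    csv = tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                     encoding = "UTF-8")),
    stop_sitr("sitr_config_error", paste0("unknown corpus format: ", format))
  )
  if ("id" %in% names(df) && !"doc_id" %in% names(df)) {
    df <- dplyr::rename(df, doc_id = "id")
  }
  if (!all(c("doc_id", "text") %in% names(df))) {
    stop_sitr("sitr_io_error", "corpus must have columns doc_id/id and text")
  }
  df$doc_id <- as.character(df$doc_id)
  df
}

#' Write a corpus to JSONL
#'
#' @param corpus Tibble with `doc_id`, `text`, and any extra columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- as.list(corpus[i, , drop = FALSE])
    rec <- lapply(rec, function(x) if (is.list(x)) x[[1]] else x)
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
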