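# End-to-end training pipeline: labeled cases -> per-subset topic models
# -> scored codebook.

#' Train a codebook from a labeled corpus
#'
#' Convenience pipeline over [fit_lda()] and [build_codebook()]: fits one
#' topic model per subset (seeds derived from `seed` by subset index, so
#' the whole build is reproducible from a single integer) and composes the
#' scored codebook.
#'
#' @param cases Tibble of training cases: `doc_id`, `subset`, `tokens`
#'   (list-column) or `text`, `merged_severity`, `mean_outcome`, optional
#'   `priorities`.
#' @param K Topics per subset.
#' @param risk_lexicon Character vector of high-risk tokens.
#' @param titles Optional named list of per-subset topic titles.
#' @param stoplist Tokens dropped before modeling.
#' @param alpha,beta,n_iter,burn_in LDA settings (see [fit_lda()]).
#' @param tokens_per_topic,min_weight Codebook extraction bounds.
#' @param seed Integer seed.
#' @param tokenizer Used when `tokens` must be derived from `text`.
#' @return A `sitr_codebook`.
#' @export
train_codebook <- function(cases, K = 10, risk_lexicon = character(0),
                           titles = NULL, stoplist = character(0),
                           alpha = 0.1, beta = 0.01,
                           n_iter = 1000, burn_in = 500,
                           tokens_per_topic = 20, min_weight = 0.001,
                           seed, tokenizer = "default") {
  stopifnot(all(c("doc_id", "subset") %in% names(cases)))
  if (!"tokens" %in% names(cases)) {
    cases$tokens <- purrr::map(cases$text, tokenize, tokenizer = tokenizer)
  }
  cases$tokens <- purrr::map(cases$tokens, filter_tokens, stoplist = stoplist)
  subsets <- subset_labels()$subset
  models <- purrr::map(setNames(seq_along(subsets), subsets), function(i) {
    s <- subsets[i]
    sub <- cases[cases$subset == s, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop_sitr("sitr_input_error",
                paste0("no training cases for subset ", s))
    }
    fit_lda(sub, K = K, alpha = alpha, beta = beta,
            n_iter = n_iter, burn_in = burn_in, seed = seed + i)
  })
  build_codebook(models, cases, risk_lexicon = risk_lexicon,
                 titles = titles, tokens_per_topic = tokens_per_topic,
                 min_weight = min_weight)
}
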