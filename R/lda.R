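# Per-subset LDA topic modeling by collapsed Gibbs sampling.

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Fits latent Dirichlet allocation to a tokenized corpus. Inference is
#' collapsed Gibbs sampling over token-topic assignments. Point estimates
#' of the topic-token distributions (`phi`) and document-topic mixtures
#' (`theta`) are taken from the final count state with Dirichlet smoothing,
#' which keeps fits deterministic for a fixed seed and keeps topic indices
#' stable for codebook construction; set `average = TRUE` to use the mean
#' over post-burn-in sweeps instead.
#'
#' @param docs List of character vectors (tokens per document), or a tibble
#'   with a `tokens` list-column (and optional `doc_id`).
#' @param K Number of topics (default 10).
#' @param alpha,beta Dirichlet hyperparameters for document mixtures and
#'   topic-token distributions.
#' @param n_iter,burn_in Gibbs sweeps and burn-in (burn_in only matters
#'   when `average = TRUE`).
#' @param seed Integer RNG seed; required for reproducibility.
#' @param average Average phi/theta over post-burn-in sweeps instead of
#'   using the final state.
#' @return An object of class `sitr_lda`: list with `phi` (K x V, rows sum
#'   to 1), `theta` (D x K, rows sum to 1), `proportion_estimates`
#'   (K integers, ~percent), `vocabulary`, `doc_ids`, `assignments`,
#'   and the settings used.
#' @export
fit_lda <- function(docs, K = 10, alpha = 0.1, beta = 0.01,
                    n_iter = 1000, burn_in = 500, seed,
                    average = FALSE) {
  if (is.data.frame(docs)) {
    doc_ids <- if ("doc_id" %in% names(docs)) as.character(docs$doc_id)
               else as.character(seq_len(nrow(docs)))
    docs <- docs$tokens
  } else {
    doc_ids <- if (!is.null(names(docs))) names(docs)
               else as.character(seq_along(docs))
  }
  stopifnot(K >= 1, alpha > 0, beta > 0, n_iter >= burn_in, burn_in >= 0)
  if (missing(seed) || is.null(seed)) {
    stop_sitr("sitr_config_error", "fit_lda() requires an explicit seed")
  }
  if (length(docs) == 0L) {
    stop_sitr("sitr_input_error", "empty corpus")
  }
  vocab <- sort(unique(unlist(docs)))
  if (length(vocab) == 0L) {
    stop_sitr("sitr_input_error", "empty vocabulary")
  }
  doc_id <- rep.int(seq_along(docs) - 1L, lengths(docs))
  word_id <- match(unlist(docs), vocab) - 1L

  set.seed(seed)
  fit <- .lda_gibbs_cpp(doc_id, word_id, length(docs), length(vocab),
                        as.integer(K), alpha, beta,
                        as.integer(n_iter), as.integer(burn_in), average)

  V <- length(vocab)
  if (average && fit$n_samples > 0) {
    phi <- fit$phi_sum / fit$n_samples
    theta <- fit$theta_sum / fit$n_samples
  } else {
    phi <- (fit$n_kv + beta) / (fit$n_k + V * beta)
    theta <- (fit$n_dk + alpha) / (fit$n_d + K * alpha)
  }
  dimnames(phi) <- list(NULL, vocab)
  rownames(theta) <- doc_ids

  structure(list(
    K = as.integer(K),
    phi = phi,
    theta = theta,
    proportion_estimates = proportion_estimates(theta),
    vocabulary = vocab,
    doc_ids = doc_ids,
    assignments = fit$z,
    settings = list(alpha = alpha, beta = beta, n_iter = n_iter,
                    burn_in = burn_in, seed = seed, average = average)
  ), class = "sitr_lda")
}

#' Integer topic proportion estimates
#'
#' A topic's importance within a corpus: the mean of its document-mixture
#' column, times 100, rounded half-up to an integer percent.
#'
#' @param doc_mixtures D x K matrix; rows sum to 1.
#' @return Integer vector of length K.
#' @export
#' @examples
#' proportion_estimates(rbind(c(0.5, 0.5), c(0.25, 0.75)))
proportion_estimates <- function(doc_mixtures) {
  stopifnot(is.matrix(doc_mixtures))
  as.integer(round_half_up(colMeans(doc_mixtures) * 100))
}

#' Key tokens of a topic
#'
#' The `n` highest-weight tokens of a topic with weight at least
#' `min_weight`, in descending weight order; ties broken lexicographically.
#'
#' @param model A `sitr_lda` fit.
#' @param topic Topic index, 0-based (0..K-1).
#' @param n Maximum number of tokens.
#' @param min_weight Minimum topic-token weight.
#' @return Character vector of tokens.
#' @export
key_tokens <- function(model, topic, n = 20, min_weight = 0) {
  stopifnot(inherits(model, "sitr_lda"), n >= 1)
  if (topic < 0 || topic >= model$K) {
    stop_sitr("sitr_input_error",
              paste0("topic index out of range: ", topic))
  }
  w <- model$phi[topic + 1L, ]
  keep <- w >= min_weight
  toks <- model$vocabulary[keep]
  w <- w[keep]
  ord <- order(-w, toks, method = "radix")
  head(toks[ord], n)
}

#' UMass-style topic coherence
#'
#' Document-co-occurrence coherence per topic: for the top `n_top` tokens
#' of each topic ordered by weight, the sum over ordered pairs (m, l),
#' m > l, of `log((D(w_m, w_l) + 1) / D(w_l))` where `D` counts documents
#' containing the token(s). Higher is more coherent; used as a
#' model-selection diagnostic only.
#'
#' @param model A `sitr_lda` fit.
#' @param docs The corpus (list of token vectors) the model was fitted on,
#'   or a compatible corpus.
#' @param n_top Number of top tokens per topic.
#' @return Numeric vector of length K.
#' @export
topic_coherence <- function(model, docs, n_top = 10) {
  stopifnot(inherits(model, "sitr_lda"))
  if (is.data.frame(docs)) docs <- docs$tokens
  doc_sets <- lapply(docs, unique)
  score <- numeric(model$K)
  for (k in seq_len(model$K) - 1L) {
    top <- key_tokens(model, k, n = n_top)
    s <- 0
    if (length(top) >= 2) {
      present <- vapply(top, function(t)
        vapply(doc_sets, function(d) t %in% d, logical(1)),
        logical(length(doc_sets)))
      present <- matrix(present, ncol = length(top))
      df_single <- colSums(present)
      for (m in 2:length(top)) for (l in 1:(m - 1)) {
        co <- sum(present[, m] & present[, l])
        if (df_single[l] > 0) s <- s + log((co + 1) / df_single[l])
      }
    }
    score[k + 1L] <- s
  }
  score
}

#' @export
print.sitr_lda <- function(x, ...) {
  cat("LDA topic model (collapsed Gibbs):", x$K, "topics,",
      length(x$vocabulary), "token types,", nrow(x$theta), "documents\n")
  cat("proportion estimates:", paste(x$proportion_estimates, collapse = " "),
      "\n")
  invisible(x)
}

#' Tidy a topic model into a token-weight table
#'
#' @param x A `sitr_lda` fit.
#' @param ... Unused.
#' @return Tibble with columns `topic` (0-based), `token`, `weight`.
#' @method tidy sitr_lda
#' @export
tidy.sitr_lda <- function(x, ...) {
  tibble::tibble(
    topic = rep(seq_len(x$K) - 1L, each = length(x$vocabulary)),
    token = rep(x$vocabulary, times = x$K),
    weight = as.vector(t(x$phi))
  )
}

#' @method glance sitr_lda
#' @export
glance.sitr_lda <- function(x, ...) {
  tibble::tibble(
    K = x$K, n_docs = nrow(x$theta), n_types = length(x$vocabulary),
    n_tokens = length(x$assignments),
    alpha = x$settings$alpha, beta = x$settings$beta,
    n_iter = x$settings$n_iter, seed = x$settings$seed
  )
}

#' Plot top tokens per topic
#'
#' @param object A `sitr_lda` fit.
#' @param n_top Tokens per topic.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sitr_lda
#' @export
autoplot.sitr_lda <- function(object, n_top = 8, ...) {
  td <- tidy(object) |>
    dplyr::group_by(.data$topic) |>
    dplyr::slice_max(.data$weight, n = n_top, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(token = stats::reorder(
      interaction(.data$token, .data$topic), .data$weight))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$weight, y = .data$token)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~topic, scales = "free_y") +
    ggplot2::scale_y_discrete(labels = function(l) sub("\\.\\d+$", "", l)) +
    ggplot2::labs(x = "topic-token weight", y = NULL)
}

#' Serialize / read a topic model as JSON
#'
#' @param model A `sitr_lda` fit.
#' @param path Output path.
#' @return `path` invisibly; `read_lda()` returns the model.
#' @export
write_lda <- function(model, path) {
  stopifnot(inherits(model, "sitr_lda"))
  obj <- list(
    schema_version = "1.0", K = model$K,
    vocabulary = model$vocabulary, doc_ids = model$doc_ids,
    phi = unname(apply(model$phi, 1, identity, simplify = FALSE)),
    theta = unname(apply(model$theta, 1, identity, simplify = FALSE)),
    proportion_estimates = model$proportion_estimates,
    assignments = model$assignments, settings = model$settings
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lda
#' @export
read_lda <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_matrix <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  phi <- as_matrix(obj$phi)
  dimnames(phi) <- list(NULL, obj$vocabulary)
  theta <- as_matrix(obj$theta)
  dimnames(theta) <- list(obj$doc_ids, NULL)
  structure(list(
    K = as.integer(obj$K), phi = phi, theta = theta,
    proportion_estimates = as.integer(obj$proportion_estimates),
    vocabulary = obj$vocabulary, doc_ids = obj$doc_ids,
    assignments = as.integer(obj$assignments),
    settings = obj$settings
  ), class = "sitr_lda")
}
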