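# Hand-built fixtures and cached synthetic objects shared across tests.

# Codebook for the hand-scoring fixture:
#   A = {pain: 0.8, alone: 0.5}, B = {knife: 0.9, pain: 0.6},
#   risk lexicon = {knife}; C/D carry one unrelated token each so all four
#   subsets exist. Subset summaries hold the published-style judgment
#   means; B has two cached case profiles over its two topics.
hand_codebook <- function() {
  entries <- tibble::tibble(
    subset = c("A", "A", "B", "B", "C", "D"),
    token = c("pain", "alone", "knife", "pain", "school", "game"),
    rep_score = c(0.8, 0.5, 0.9, 0.6, 0.4, 0.4),
    topic_index = c(0L, 1L, 0L, 1L, 0L, 0L),
    topic_title = c("family conflict", "feelings of inadequacy",
                    "psychopathology", "self-stigma",
                    "academic stress", "mood issues"),
    proportion_estimate = c(36L, 8L, 35L, 18L, 25L, 32L),
    is_risk = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  subsets <- tibble::tibble(
    subset = c("A", "B", "C", "D"),
    semantics = subset_labels()$semantics,
    n = c(26L, 62L, 64L, 26L),
    mean_severity = c(4.44, 4.53, 3.30, 3.58),
    sd_severity = c(0.38, 0.40, 0.52, 0.37),
    mean_outcome = c(2.88, 3.94, 2.55, 3.65),
    sd_outcome = c(0.26, 0.37, 0.52, 0.27)
  )
  prof <- function(vals, titles) {
    structure(as.integer(vals), names = titles,
              class = "sitr_topic_profile")
  }
  b_titles <- c("psychopathology", "self-stigma")
  case_profiles <- tibble::tibble(
    case_id = c("B001", "B002", "A001"),
    subset = c("B", "B", "A"),
    profile = list(prof(c(35, 18), b_titles), prof(c(35, 0), b_titles),
                   prof(c(36, 8), c("family conflict",
                                    "feelings of inadequacy"))),
    priorities = list(
      setNames(c(3L, 2L, 1L, 4L, 5L), priority_domains()),
      setNames(c(2L, 3L, 1L, 4L, 5L), priority_domains()),
      setNames(c(3L, 2L, 1L, 5L, 4L), priority_domains())
    )
  )
  structure(list(
    schema_version = "1.0",
    entries = entries,
    subsets = subsets,
    risk_lexicon = "knife",
    case_profiles = case_profiles,
    meta = list(tokens_per_topic = 20, min_weight = 0.001)
  ), class = "sitr_codebook")
}

# Minimal sitr_lda object with prescribed topic-token weights, for testing
# key-token extraction without a fit.
fake_lda <- function(phi, theta = NULL) {
  K <- nrow(phi)
  vocab <- colnames(phi)
  if (is.null(theta)) theta <- matrix(1 / K, nrow = 1, ncol = K)
  structure(list(
    K = K, phi = phi, theta = theta,
    proportion_estimates = proportion_estimates(theta),
    vocabulary = vocab, doc_ids = as.character(seq_len(nrow(theta))),
    assignments = integer(0),
    settings = list(alpha = 0.1, beta = 0.01, n_iter = 0, burn_in = 0,
                    seed = 0, average = FALSE)
  ), class = "sitr_lda")
}

# The 4-document 2-topic toy corpus used for sampler checks.
toy_corpus <- function() {
  list(c("a", "a", "b"), c("b", "a", "a"), c("c", "d", "d"),
       c("d", "c", "c"))
}

# Small synthetic pipeline (corpus + trained codebook), built once per
# test run and cached; several test files reuse it.
.fixture_cache <- new.env(parent = emptyenv())
cached_pipeline <- function() {
  if (is.null(.fixture_cache$pipeline)) {
    spec <- generator_spec(n_docs = c(A = 12L, B = 12L, C = 12L, D = 12L),
                           K = 5L, V = 150L, overlap = 0)
    corpus <- sample_corpus(spec, seed = 2024)
    codebook <- train_codebook(corpus$cases, K = 5, n_iter = 400,
                               burn_in = 200, seed = 2024)
    .fixture_cache$pipeline <- list(spec = spec, corpus = corpus,
                                    codebook = codebook)
  }
  .fixture_cache$pipeline
}

# Align topics of a fitted model to reference distributions by greedy
# best-cosine matching; returns the permutation ref_topic -> fit_topic.
align_topics <- function(phi_fit, phi_ref) {
  common <- intersect(colnames(phi_fit), colnames(phi_ref))
  fit <- phi_fit[, common, drop = FALSE]
  ref <- phi_ref[, common, drop = FALSE]
  K <- nrow(ref)
  sim <- matrix(0, K, nrow(fit))
  for (i in seq_len(K)) for (j in seq_len(nrow(fit))) {
    sim[i, j] <- sum(ref[i, ] * fit[j, ]) /
      (sqrt(sum(ref[i, ]^2)) * sqrt(sum(fit[j, ]^2)))
  }
  perm <- rep(NA_integer_, K)
  taken <- rep(FALSE, ncol(sim))
  for (step in seq_len(K)) {
    best <- -Inf; bi <- NA_integer_; bj <- NA_integer_
    for (i in seq_len(K)) {
      if (!is.na(perm[i])) next
      for (j in seq_len(ncol(sim))) {
        if (taken[j]) next
        if (sim[i, j] > best) { best <- sim[i, j]; bi <- i; bj <- j }
      }
    }
    perm[bi] <- bj
    taken[bj] <- TRUE
  }
  list(perm = perm,
       cosines = vapply(seq_len(K), function(i) sim[i, perm[i]], numeric(1)))
}

# Accuracy of held-out subset recovery for a spec/codebook pair.
heldout_accuracy <- function(spec, codebook, n_per_subset = 10,
                             seed_base = 7000, min_matches = 3L) {
  total <- 0L; correct <- 0L
  for (s in subset_labels()$subset) {
    for (i in seq_len(n_per_subset)) {
      inp <- sample_input(spec, s, seed = seed_base + i)
      res <- assess_safely(inp$text[[1]], codebook,
                           min_matches = min_matches)
      total <- total + 1L
      if (!inherits(res, "sitr_refusal") && res$predicted_subset == s) {
        correct <- correct + 1L
      }
    }
  }
  correct / total
}
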