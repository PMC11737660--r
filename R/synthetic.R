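# Generative stand-in for the unpublished labeled corpus: four-subset
# corpora with LDA structure, held-out assessment inputs, and simulated
# rater judgments. The generator's defaults are the study conditions the
# machine was trained under: subset sizes 26/62/64/26, document lengths
# with mean 103.85 and SD 61.38 tokens, subset-conditional judgment
# distributions matching the published subset summaries, and paired
# raters in the "fair" agreement regime.

#' Synthetic corpus generator specification
#'
#' Describes a four-subset generative corpus. Each subset has its own
#' vocabulary of `V` token types, split into `K` equal per-topic slices
#' with Zipf-shaped within-slice weights (disjoint topics within a
#' subset). A fraction `overlap` of every slice is replaced by tokens from
#' a pool shared across all four subsets; `overlap` is the single knob
#' controlling task difficulty (0 = disjoint subset vocabularies,
#' 1 = fully shared).
#'
#' Judgment truth is drawn per case from subset-conditional normal
#' distributions (means/SDs matching the published subset summaries),
#' truncated to the subset's severity/outcome region; paired raters then
#' add rounding and Gaussian noise via [simulate_raters()].
#'
#' @param n_docs Named integer vector of documents per subset.
#' @param K Topics per subset.
#' @param V Vocabulary size per subset.
#' @param overlap Shared-vocabulary fraction in \[0, 1\].
#' @param doc_alpha Dirichlet concentration for document-topic mixtures.
#' @param length_mean,length_sd Target token-count moments (lognormal,
#'   moment-matched, clamped at >= 5 tokens).
#' @param judgment_model Tibble of subset-conditional truth parameters;
#'   defaults to the published subset summary means/SDs.
#' @param n_raters,rater_noise_sd Paired-rater simulation parameters.
#' @param priority_noise SD of the Gaussian jitter applied to the
#'   subset-typical priority ranking before re-ranking.
#' @param severity_threshold,outcome_threshold Partition thresholds the
#'   truth draws must respect (with a 0.25 margin).
#' @return A list of class `sitr_generator_spec`.
#' @export
generator_spec <- function(n_docs = c(A = 26L, B = 62L, C = 64L, D = 26L),
                           K = 10L, V = 400L, overlap = 0,
                           doc_alpha = 0.3,
                           length_mean = 103.85, length_sd = 61.38,
                           judgment_model = NULL,
                           n_raters = 2L, rater_noise_sd = 1.0,
                           priority_noise = 0.7,
                           severity_threshold = 4.0,
                           outcome_threshold = 3.5) {
  stopifnot(overlap >= 0, overlap <= 1, K >= 1, V >= K,
            doc_alpha > 0, length_mean > 0, length_sd > 0)
  subsets <- subset_labels()$subset
  if (is.null(names(n_docs))) names(n_docs) <- subsets
  stopifnot(all(subsets %in% names(n_docs)))
  if (is.null(judgment_model)) {
    judgment_model <- tibble::tibble(
      subset = subsets,
      severity_mean = c(4.44, 4.53, 3.30, 3.58),
      severity_sd = c(0.38, 0.40, 0.52, 0.37),
      outcome_mean = c(2.88, 3.94, 2.55, 3.65),
      outcome_sd = c(0.26, 0.37, 0.52, 0.27)
    )
  }
  structure(list(
    n_docs = n_docs[subsets], K = as.integer(K), V = as.integer(V),
    overlap = overlap, doc_alpha = doc_alpha,
    length_mean = length_mean, length_sd = length_sd,
    judgment_model = judgment_model,
    n_raters = as.integer(n_raters), rater_noise_sd = rater_noise_sd,
    priority_noise = priority_noise,
    severity_threshold = severity_threshold,
    outcome_threshold = outcome_threshold
  ), class = "sitr_generator_spec")
}

# Deterministic per-subset topic-token distributions. Returns a list
# subset -> list(vocab = character(V), phi = K x V matrix, rows sum to 1).
generator_truth <- function(spec) {
  subsets <- subset_labels()$subset
  K <- spec$K; V <- spec$V
  slice <- V %/% K
  n_shared_per_slice <- round(spec$overlap * slice)
  shared_pool <- sprintf("sh_w%04d", seq_len(n_shared_per_slice * K))
  purrr::map(setNames(subsets, subsets), function(s) {
    vocab <- character(0)
    phi <- matrix(0, nrow = K, ncol = 0)
    for (k in seq_len(K)) {
      own <- sprintf("%s_t%02d_w%03d", tolower(s), k,
                     seq_len(slice - n_shared_per_slice))
      sh <- if (n_shared_per_slice > 0)
        shared_pool[((k - 1) * n_shared_per_slice + 1):(k * n_shared_per_slice)]
      else character(0)
      toks <- c(sh, own)
      w <- 1 / seq_along(toks) # Zipf-shaped within-topic weights
      w <- w / sum(w)
      block <- matrix(0, nrow = K, ncol = length(toks))
      block[k, ] <- w
      vocab <- c(vocab, toks)
      phi <- cbind(phi, block)
    }
    colnames(phi) <- vocab
    list(vocab = vocab, phi = phi)
  })
}

rdirichlet1 <- function(alpha, K) {
  g <- stats::rgamma(K, shape = alpha)
  if (sum(g) == 0) g <- rep(1, K)
  g / sum(g)
}

lognormal_params <- function(m, s) {
  sig2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sig2 / 2, sigma = sqrt(sig2))
}

sample_document_tokens <- function(truth_s, spec) {
  lp <- lognormal_params(spec$length_mean, spec$length_sd)
  len <- max(5L, as.integer(round_half_up(rlnorm(1, lp$mu, lp$sigma))))
  mix <- rdirichlet1(spec$doc_alpha, spec$K)
  z <- sample.int(spec$K, len, replace = TRUE, prob = mix)
  toks <- character(len)
  for (k in sort(unique(z))) {
    idx <- z == k
    toks[idx] <- sample(truth_s$vocab, sum(idx), replace = TRUE,
                        prob = truth_s$phi[k, ])
  }
  list(tokens = toks, mixture = mix)
}

subset_typical_priorities <- function() {
  # emotions are ranked first across subsets; the remaining order varies
  # with the subset's character (ranks 1 = highest priority)
  d <- priority_domains()
  list(
    A = setNames(c(3L, 2L, 1L, 4L, 5L), d),
    B = setNames(c(2L, 3L, 1L, 4L, 5L), d),
    C = setNames(c(4L, 3L, 1L, 5L, 2L), d),
    D = setNames(c(5L, 4L, 1L, 3L, 2L), d)
  )
}

sample_priorities <- function(subset, noise) {
  typical <- subset_typical_priorities()[[subset]]
  jitter <- typical + rnorm(length(typical), 0, noise)
  setNames(as.integer(rank(jitter, ties.method = "first")), names(typical))
}

truncnorm1 <- function(mean, sd, lower, upper) {
  for (i in 1:200) {
    x <- rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

#' Sample a labeled four-subset training corpus
#'
#' Generates documents, rater judgments, and priority rankings per the
#' spec; deterministic for a fixed seed. Each case's merged judgments are
#' guaranteed consistent with its generating subset under the spec's
#' partition thresholds (rater noise is redrawn for the rare case that
#' rounding pushes a merged value across a threshold).
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed.
#' @return List of class `sitr_synthetic_corpus`: `cases` (tibble:
#'   doc_id, subset, text, tokens, merged_severity, mean_outcome,
#'   priorities), `judgments` (long tibble of individual rater records),
#'   and `truth` (generating topic distributions and document mixtures).
#' @export
sample_corpus <- function(spec, seed) {
  stopifnot(inherits(spec, "sitr_generator_spec"))
  set.seed(seed)
  truth <- generator_truth(spec)
  jm <- spec$judgment_model
  st <- spec$severity_threshold; ot <- spec$outcome_threshold
  margin <- 0.25

  cases <- list(); judgments <- list(); mixtures <- list()
  for (s in subset_labels()$subset) {
    pars <- jm[jm$subset == s, ]
    serious <- s %in% c("A", "B")
    negative <- s %in% c("B", "D")
    sev_rng <- if (serious) c(st + margin, 7) else c(1, st - margin)
    out_rng <- if (negative) c(ot + margin, 7) else c(1, ot - margin)
    for (i in seq_len(spec$n_docs[[s]])) {
      doc_id <- sprintf("%s%03d", s, i)
      doc <- sample_document_tokens(truth[[s]], spec)
      true_sev <- truncnorm1(pars$severity_mean, pars$severity_sd,
                             sev_rng[1], sev_rng[2])
      true_out <- truncnorm1(pars$outcome_mean, pars$outcome_sd,
                             out_rng[1], out_rng[2])
      # redraw rater noise until merged values stay in the subset's region
      for (attempt in 1:100) {
        jd <- simulate_raters_one(doc_id, true_sev, true_sev, true_out,
                                  spec$n_raters, spec$rater_noise_sd)
        merged <- merge_judgments(jd)
        ok <- (merged$merged_severity >= st) == serious &&
              (merged$mean_outcome >= ot) == negative
        if (ok) break
      }
      if (!ok) { # deterministic region-safe fallback
        safe_sev <- if (serious) max(round_half_up(true_sev), st)
                    else min(round_half_up(true_sev), ceiling(st) - 1)
        safe_out <- if (negative) max(round_half_up(true_out), ceiling(ot))
                    else min(round_half_up(true_out), floor(ot))
        jd <- tibble::tibble(
          case_id = doc_id, rater_id = seq_len(spec$n_raters),
          severity = as.integer(safe_sev), difficulty = as.integer(safe_sev),
          outcome = as.integer(safe_out)
        )
        merged <- merge_judgments(jd)
      }
      cases[[length(cases) + 1L]] <- tibble::tibble(
        doc_id = doc_id, subset = s,
        text = paste(doc$tokens, collapse = " "),
        tokens = list(doc$tokens),
        merged_severity = merged$merged_severity,
        mean_outcome = merged$mean_outcome,
        priorities = list(sample_priorities(s, spec$priority_noise))
      )
      judgments[[length(judgments) + 1L]] <- jd
      mixtures[[doc_id]] <- doc$mixture
    }
  }
  structure(list(
    cases = dplyr::bind_rows(cases),
    judgments = dplyr::bind_rows(judgments),
    truth = list(spec = spec, seed = seed,
                 topic_distributions = purrr::map(truth, "phi"),
                 doc_mixtures = mixtures)
  ), class = "sitr_synthetic_corpus")
}

#' @export
print.sitr_synthetic_corpus <- function(x, ...) {
  cat("Synthetic corpus:", nrow(x$cases), "cases;",
      "token count mean", round(mean(lengths(x$cases$tokens)), 1), "\n")
  print(dplyr::count(x$cases, .data$subset))
  invisible(x)
}

#' Sample a held-out assessment input
#'
#' Generates one document from a subset's generative process on a seed
#' stream separate from [sample_corpus()], so it never appears in a
#' training corpus built from the same spec and seed.
#'
#' @param spec A [generator_spec()].
#' @param subset Generating subset label.
#' @param length Token count; `NULL` draws from the length distribution.
#' @param seed Integer seed.
#' @return Tibble with one row: `doc_id`, `subset`, `text`, `tokens`.
#' @export
sample_input <- function(spec, subset, length = NULL, seed) {
  stopifnot(inherits(spec, "sitr_generator_spec"))
  if (!subset %in% subset_labels()$subset) {
    stop_sitr("sitr_input_error", paste0("unknown subset: ", subset))
  }
  set.seed((as.integer(seed) %% 1000003L) * 2011L +
             match(subset, subset_labels()$subset))
  truth <- generator_truth(spec)
  doc <- sample_document_tokens(truth[[subset]], spec)
  toks <- doc$tokens
  if (!is.null(length)) {
    stopifnot(length >= 1)
    mix <- doc$mixture
    z <- sample.int(spec$K, length, replace = TRUE, prob = mix)
    toks <- character(length)
    for (k in sort(unique(z))) {
      idx <- z == k
      toks[idx] <- sample(truth[[subset]]$vocab, sum(idx), replace = TRUE,
                          prob = truth[[subset]]$phi[k, ])
    }
  }
  tibble::tibble(doc_id = sprintf("heldout_%s_%d", subset, seed),
                 subset = subset,
                 text = paste(toks, collapse = " "),
                 tokens = list(toks))
}

simulate_raters_one <- function(case_id, sev, dif, out, n_raters, noise_sd) {
  clamp17 <- function(x) pmin(7L, pmax(1L, as.integer(round_half_up(x))))
  tibble::tibble(
    case_id = case_id,
    rater_id = seq_len(n_raters),
    severity = clamp17(sev + rnorm(n_raters, 0, noise_sd)),
    difficulty = clamp17(dif + rnorm(n_raters, 0, noise_sd)),
    outcome = clamp17(out + rnorm(n_raters, 0, noise_sd))
  )
}

#' Simulate rater judgments around true case scores
#'
#' Each rater's score is the true score plus Gaussian noise, rounded
#' half-up and clamped to the 1-7 scale.
#'
#' @param true_scores Tibble with columns `case_id`, `severity`,
#'   `outcome`, optionally `difficulty` (defaults to `severity`).
#' @param n_raters Number of raters.
#' @param noise_sd Rater noise SD (0 = perfect agreement with the rounded
#'   truth).
#' @param seed Integer seed.
#' @return Long tibble: `case_id`, `rater_id`, `severity`, `difficulty`,
#'   `outcome`.
#' @export
simulate_raters <- function(true_scores, n_raters = 2L, noise_sd = 1.0,
                            seed) {
  stopifnot(n_raters >= 1, noise_sd >= 0,
            all(c("case_id", "severity", "outcome") %in% names(true_scores)))
  set.seed(seed)
  dif <- if ("difficulty" %in% names(true_scores)) true_scores$difficulty
         else true_scores$severity
  purrr::pmap_dfr(
    list(true_scores$case_id, true_scores$severity, dif,
         true_scores$outcome),
    function(id, s, d, o) simulate_raters_one(id, s, d, o, n_raters,
                                              noise_sd)
  )
}

#' Calibrate rater noise to a target agreement level
#'
#' Grid search over the rater noise SD so that the mean pairwise Cohen's
#' kappa on simulated severity judgments matches a target (defaults to the
#' "fair" 0.40 regime of paired suitability ratings).
#'
#' @param target_kappa Target mean kappa.
#' @param spec A [generator_spec()] giving the judgment model.
#' @param grid Candidate noise SDs.
#' @param n_cases Simulated cases per grid point.
#' @param seed Integer seed.
#' @return Tibble of the grid with mean kappa per noise SD and a `chosen`
#'   flag on the closest match.
#' @export
calibrate_rater_noise <- function(target_kappa = 0.40,
                                  spec = generator_spec(),
                                  grid = seq(0.4, 2.0, by = 0.2),
                                  n_cases = 500, seed = 1) {
  jm <- spec$judgment_model
  set.seed(seed)
  subs <- sample(jm$subset, n_cases, replace = TRUE)
  truth <- tibble::tibble(
    case_id = sprintf("c%04d", seq_len(n_cases)),
    severity = rnorm(n_cases, jm$severity_mean[match(subs, jm$subset)],
                     jm$severity_sd[match(subs, jm$subset)] + 0.5),
    outcome = rnorm(n_cases, jm$outcome_mean[match(subs, jm$subset)],
                    jm$outcome_sd[match(subs, jm$subset)] + 0.5)
  )
  res <- purrr::map_dfr(seq_along(grid), function(i) {
    jd <- simulate_raters(truth, n_raters = 2L, noise_sd = grid[i],
                          seed = seed + i)
    wide <- tidyr::pivot_wider(jd[, c("case_id", "rater_id", "severity")],
                               names_from = "rater_id",
                               values_from = "severity")
    k <- cohens_kappa(wide$`1`, wide$`2`)$value
    tibble::tibble(noise_sd = grid[i], mean_kappa = k)
  })
  res$chosen <- seq_len(nrow(res)) ==
    which.min(abs(res$mean_kappa - target_kappa))
  res
}
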