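test_that("representativeness scores min-max standardize within-subset frequencies", {
  expect_equal(representativeness_scores(c(pain = 10, alone = 5)),
               c(pain = 1, alone = 0))
  expect_equal(representativeness_scores(c(a = 10, b = 7, c = 4)),
               c(a = 1, b = 0.5, c = 0))
  expect_equal(representativeness_scores(c(x = 3, y = 3)),
               c(x = 1, y = 1))
  expect_equal(representativeness_scores(c(solo = 5)), c(solo = 1))
  expect_error(representativeness_scores(numeric(0)),
               class = "sitr_input_error")
  # monotone: score order preserves frequency order
  set.seed(17)
  for (i in 1:20) {
    f <- setNames(sample(0:50, 8), paste0("t", 1:8))
    s <- representativeness_scores(f)
    expect_identical(order(s), order(f))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("codebook build satisfies its structural invariants", {
  pl <- cached_pipeline()
  cb <- pl$codebook
  ent <- cb$entries
  expect_setequal(unique(ent$subset), c("A", "B", "C", "D"))
  # (subset, token) unique; at most K * tokens_per_topic entries per subset
  expect_false(any(duplicated(ent[, c("subset", "token")])))
  per_sub <- table(ent$subset)
  expect_true(all(per_sub <= 5 * 20))
  expect_true(all(ent$rep_score >= 0 & ent$rep_score <= 1))
  expect_true(all(ent$proportion_estimate >= 0))
  # every cached profile's titles are exactly its subset's topic titles
  for (i in seq_len(nrow(cb$case_profiles))) {
    s <- cb$case_profiles$subset[i]
    titles <- unique(ent$topic_title[ent$subset == s])
    expect_setequal(names(cb$case_profiles$profile[[i]]), titles)
  }
  expect_error(
    build_codebook(list(A = NULL), pl$corpus$cases),
    class = "sitr_config_error"
  )
})

test_that("risk lexicon flags matching entries and only those", {
  pl <- cached_pipeline()
  risk <- head(pl$codebook$entries$token[pl$codebook$entries$subset == "B"], 3)
  cb <- train_codebook(pl$corpus$cases, K = 5, n_iter = 200, burn_in = 100,
                       seed = 2024, risk_lexicon = risk)
  expect_identical(cb$entries$is_risk, cb$entries$token %in% risk)
  expect_false(any(pl$codebook$entries$is_risk)) # empty lexicon build
})

test_that("subset summaries store judgment means verbatim", {
  cases <- tibble::tibble(
    doc_id = sprintf("c%02d", 1:8),
    subset = rep(c("A", "B", "C", "D"), each = 2),
    tokens = rep(list(c("pain", "worry", "alone")), 8),
    merged_severity = rep(c(4.44, 4.53, 3.30, 3.58), each = 2),
    mean_outcome = rep(c(2.88, 3.94, 2.55, 3.65), each = 2)
  )
  models <- setNames(lapply(1:4, function(i) {
    fit_lda(cases$tokens[1:2], K = 2, n_iter = 50, burn_in = 10, seed = i)
  }), c("A", "B", "C", "D"))
  cb <- build_codebook(models, cases)
  a <- cb$subsets[cb$subsets$subset == "A", ]
  expect_identical(a$mean_severity, 4.44)
  expect_identical(a$mean_outcome, 2.88)
  expect_identical(cb$subsets$n, rep(2L, 4))
})

test_that("topic profiles map matched topics to proportion estimates, zero otherwise", {
  cb <- hand_codebook()
  # tokens matching family conflict (est 36) and feelings of inadequacy (8)
  p <- topic_profile(c("pain", "alone", "zzz"), cb, "A")
  expect_identical(as.integer(p), c(36L, 8L))
  expect_identical(names(p), c("family conflict", "feelings of inadequacy"))
  expect_identical(as.integer(topic_profile("zzz", cb, "A")), c(0L, 0L))
  full <- topic_profile(c("pain", "alone"), cb, "A")
  expect_identical(as.integer(full), c(36L, 8L))
  expect_error(topic_profile("x", cb, "Z"), class = "sitr_input_error")
  # audit trail: every nonzero topic has at least one matched entry
  pl <- cached_pipeline()
  toks <- pl$corpus$cases$tokens[[5]]
  prof <- topic_profile(toks, pl$codebook, pl$corpus$cases$subset[5])
  ent <- pl$codebook$entries
  for (tt in names(prof)[as.integer(prof) > 0]) {
    sub_ent <- ent[ent$subset == pl$corpus$cases$subset[5] &
                     ent$topic_title == tt, ]
    expect_true(any(sub_ent$token %in% toks))
  }
})

test_that("tokens shared across topics are housed in their max-weight topic", {
  pl <- cached_pipeline()
  ent <- pl$codebook$entries
  models <- pl$codebook$meta$lda_settings # settings only; refit one subset
  sub <- pl$corpus$cases[pl$corpus$cases$subset == "A", ]
  m <- fit_lda(sub, K = 5, n_iter = 400, burn_in = 200,
               seed = 2024 + 1)
  a_ent <- ent[ent$subset == "A", ]
  for (i in sample(nrow(a_ent), 10)) {
    tok <- a_ent$token[i]
    w <- m$phi[, tok]
    expect_identical(a_ent$topic_index[i], which.max(w) - 1L)
  }
})

test_that("codebook JSON round-trips losslessly and CSV mirrors the entries", {
  pl <- cached_pipeline()
  cb <- pl$codebook
  f <- withr::local_tempfile(fileext = ".json")
  write_codebook(cb, f)
  back <- read_codebook(f)
  expect_equal(back$entries, cb$entries)
  expect_equal(back$subsets, cb$subsets)
  expect_identical(back$risk_lexicon, cb$risk_lexicon)
  expect_equal(back$case_profiles$profile, cb$case_profiles$profile)
  expect_equal(back$case_profiles$priorities, cb$case_profiles$priorities)

  csv <- withr::local_tempfile(fileext = ".csv")
  export_codebook_csv(cb, csv)
  expect_identical(nrow(read.csv(csv)), nrow(cb$entries))

  # tampering: dropping a subset is reported by name
  ent2 <- cb$entries[cb$entries$subset != "C", ]
  cb2 <- cb; cb2$entries <- ent2
  f2 <- withr::local_tempfile(fileext = ".json")
  write_codebook(cb2, f2)
  expect_error(read_codebook(f2), "C", class = "sitr_io_error")
  expect_error(read_codebook("/nonexistent.json"), class = "sitr_io_error")
})

test_that("codebook build is deterministic given models, cases and config", {
  pl <- cached_pipeline()
  cb2 <- train_codebook(pl$corpus$cases, K = 5, n_iter = 400,
                        burn_in = 200, seed = 2024)
  expect_equal(cb2$entries, pl$codebook$entries)
  expect_equal(cb2$case_profiles$profile, pl$codebook$case_profiles$profile)
})
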