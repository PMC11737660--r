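# H1/H2 inference against hand-computed fixtures and audit properties.

test_that("H1 scoring reproduces the hand-computed ledger", {
  cb <- hand_codebook()
  m <- match_tokens(c("pain", "knife", "alone"), cb, w_pos = 1, w_risk = 1)
  sc <- m$scores
  # pain and alone first match in A; knife first (and only) matches in B,
  # where its risk bonus also lands
  expect_equal(sc$probability_score[sc$subset == "A"], (0.8 + 1) + (0.5 + 1))
  expect_equal(sc$probability_score[sc$subset == "B"], 0.6 + (0.9 + 1 + 1))
  expect_identical(sc$match_count[sc$subset == "A"], 2L)
  expect_identical(sc$match_count[sc$subset == "B"], 2L)

  m0 <- match_tokens(c("pain", "knife", "alone"), cb, w_pos = 0, w_risk = 0)
  sc0 <- m0$scores
  expect_equal(sc0$probability_score[sc0$subset == "A"], 1.3)
  expect_equal(sc0$probability_score[sc0$subset == "B"], 1.5)

  none <- match_tokens(c("qq", "ww"), cb)
  expect_true(all(none$scores$probability_score == 0))
  expect_true(all(none$scores$match_count == 0L))
  expect_identical(nrow(none$events), 0L)
})

test_that("repeated tokens score once per subset, at first occurrence", {
  cb <- hand_codebook()
  rep_in <- match_tokens(c("pain", "pain", "pain", "knife", "alone"), cb,
                         w_pos = 0, w_risk = 0)
  once <- match_tokens(c("pain", "knife", "alone"), cb, w_pos = 0,
                       w_risk = 0)
  expect_equal(rep_in$scores$probability_score,
               once$scores$probability_score)
  # position bonus: first three distinct matched types, once per token,
  # in the first subset (A..D) where the token matches
  m <- match_tokens(c("zz", "pain", "school", "game", "knife"), cb,
                    w_pos = 1, w_risk = 0)
  ev <- m$events
  expect_identical(ev$position_bonus[ev$token == "pain" & ev$subset == "A"], 1)
  expect_identical(ev$position_bonus[ev$token == "pain" & ev$subset == "B"], 0)
  expect_identical(ev$position_bonus[ev$token == "school"], 1)
  expect_identical(ev$position_bonus[ev$token == "game"], 1)
  expect_true(all(ev$position_bonus[ev$token == "knife"] == 0))
})

test_that("subset selection ranks by score, then match count, then B>A>D>C", {
  sc <- function(a, b, c, d, ca = 1L, cbn = 1L, cc = 1L, cd = 1L) {
    tibble::tibble(subset = c("A", "B", "C", "D"),
                   probability_score = c(a, b, c, d),
                   match_count = c(ca, cbn, cc, cd))
  }
  expect_identical(h1_select_subset(sc(3.3, 3.5, 0, 0)), "B")
  expect_identical(h1_select_subset(sc(2, 2, 0, 0, ca = 2L, cbn = 3L)), "B")
  expect_identical(h1_select_subset(sc(2, 2, 0, 0, ca = 3L, cbn = 2L)), "A")
  expect_identical(h1_select_subset(sc(1, 1, 1, 1)), "B")
  expect_identical(h1_select_subset(sc(0, 0, 2, 2, cc = 1L, cd = 1L)), "D")
  expect_identical(h1_select_subset(sc(0, 0, 0, 0)), NA_character_)
})

test_that("H2 matching reproduces the hand-computed cosine fixture", {
  titles <- c("family conflict", "bullying", "feelings of inadequacy",
              "interest in treatment")
  prof <- function(v) structure(as.integer(v), names = titles,
                                class = "sitr_topic_profile")
  cb <- hand_codebook()
  cb$case_profiles <- tibble::tibble(
    case_id = c("case1", "case2"),
    subset = "A",
    profile = list(prof(c(36, 0, 0, 0)), prof(c(0, 36, 8, 0))),
    priorities = list(NULL, NULL)
  )
  input <- prof(c(36, 0, 8, 0))
  best <- h2_best_case(input, cb, "A")
  expect_identical(best$case_id, "case1")
  expect_equal(best$similarity, 36^2 / (sqrt(36^2 + 8^2) * 36),
               tolerance = 1e-9)
  # the runner-up similarity, computed by hand, is far lower
  expect_equal(8 * 8 / (sqrt(1360) * sqrt(1360)), 0.047, tolerance = 2e-3)

  # identical profile: similarity exactly 1
  cb$case_profiles$profile[[2]] <- prof(c(36, 0, 8, 0))
  best2 <- h2_best_case(input, cb, "A")
  expect_identical(best2$case_id, "case2")
  expect_equal(best2$similarity, 1.0, tolerance = 1e-12)

  # all-zero input: similarity 0, shared-nonzero tie-break then smallest id
  zero <- prof(c(0, 0, 0, 0))
  best3 <- h2_best_case(zero, cb, "A")
  expect_identical(best3$case_id, "case1")
  expect_identical(best3$similarity, 0)
  expect_error(h2_best_case(input, cb, "C"), class = "sitr_input_error")
})

test_that("H2 ties prefer more shared nonzero topics, then smaller case id", {
  titles <- c("t1", "t2", "t3", "t4")
  prof <- function(v) structure(as.integer(v), names = titles,
                                class = "sitr_topic_profile")
  cb <- hand_codebook()
  # both cases are scalar multiples of the input -> cosine 1 for both;
  # case_b shares two nonzero topics, case_a only has the same direction
  cb$case_profiles <- tibble::tibble(
    case_id = c("aaa", "bbb"),
    subset = "A",
    profile = list(prof(c(10, 5, 0, 0)), prof(c(20, 10, 0, 0))),
    priorities = list(NULL, NULL)
  )
  input <- prof(c(10, 5, 0, 0))
  expect_identical(h2_best_case(input, cb, "A")$case_id, "aaa")
  # exact tie on similarity and shared topics -> lexicographic id
  cb$case_profiles$profile[[2]] <- prof(c(10, 5, 0, 0))
  expect_identical(h2_best_case(input, cb, "A")$case_id, "aaa")
})

test_that("assessment assembles estimates from the selected subset and matched case", {
  cb <- hand_codebook()
  r <- assess("pain knife alone", cb)
  expect_identical(r$predicted_subset, "B")
  expect_identical(r$severity_estimate, 4.53)
  expect_identical(r$outcome_estimate, 3.94)
  expect_identical(r$matched_case_id, "B001")
  expect_identical(names(r$priority_ranking), priority_domains())
  expect_setequal(unname(r$priority_ranking), 1:5)
  # profile within B: both topics matched -> full estimate vector
  expect_identical(as.integer(r$input_profile), c(35L, 18L))

  expect_error(assess("pain knife", cb),
               class = "sitr_insufficient_evidence")
  expect_error(assess("no matching words here at all", cb),
               class = "sitr_insufficient_evidence")
})

test_that("unmatched tokens are inert: insertion changes nothing", {
  cb <- hand_codebook()
  base <- assess("pain knife alone", cb)
  more <- assess("pain qq knife zz alone ww", cb)
  expect_equal(more$subset_scores, base$subset_scores)
  expect_identical(more$predicted_subset, base$predicted_subset)
  expect_identical(more$matched_case_id, base$matched_case_id)
})

test_that("probability scores decompose exactly into logged match events", {
  pl <- cached_pipeline()
  set.seed(41)
  for (i in 1:10) {
    toks <- sample(pl$codebook$entries$token, 30, replace = TRUE)
    m <- match_tokens(toks, pl$codebook)
    agg <- tapply(m$events$contribution, m$events$subset, sum)
    for (s in names(agg)) {
      expect_equal(
        m$scores$probability_score[m$scores$subset == s],
        unname(agg[s])
      )
    }
  }
})

test_that("assessment is byte-identical across repeated runs", {
  pl <- cached_pipeline()
  txt <- pl$corpus$cases$text[[3]]
  r1 <- assess(txt, pl$codebook, doc_id = "x")
  r2 <- assess(txt, pl$codebook, doc_id = "x")
  expect_identical(render_report(r1, "json"), render_report(r2, "json"))
})
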