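# Agreement, reliability, comparison and regression statistics against
# brute-force oracles.

test_that("Cohen's kappa matches hand arithmetic and the agreement bands", {
  a <- rep(c(1, 1, 2, 2), c(20, 5, 10, 15))
  b <- rep(c(1, 2, 1, 2), c(20, 5, 10, 15))
  k <- cohens_kappa(a, b)
  expect_equal(k$value, 0.40, tolerance = 1e-12)
  expect_identical(k$band, "fair")

  ident <- cohens_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(ident$value, 1.0)
  expect_identical(ident$band, "almost perfect")

  expect_error(cohens_kappa(rep(1, 5), rep(1, 5)),
               class = "sitr_stat_error")

  # independent ratings: kappa near zero at large n
  set.seed(5)
  x <- sample(1:7, 4000, replace = TRUE)
  y <- sample(1:7, 4000, replace = TRUE)
  expect_lt(abs(cohens_kappa(x, y)$value), 0.05)
})

test_that("kappa agrees with the brute-force oracle over random ratings", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(10:40, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    if (length(union(a, b)) < 2) next
    expect_equal(cohens_kappa(a, b)$value, oracle_kappa(a, b),
                 tolerance = 1e-10)
  }
  # weighted variants stay within [-1, 1] and equal 1 on identical input
  set.seed(13)
  a <- sample(1:7, 50, replace = TRUE)
  expect_equal(cohens_kappa(a, a, weighting = "quadratic")$value, 1)
  b <- sample(1:7, 50, replace = TRUE)
  for (wmode in c("linear", "quadratic")) {
    v <- cohens_kappa(a, b, weighting = wmode)$value
    expect_true(v >= -1 && v <= 1)
  }
})

test_that("ICC(2,k) matches the variance-components oracle", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 2, byrow = TRUE)
  expect_equal(icc_2k(m)$value, oracle_icc2k(m), tolerance = 1e-10)

  # identical raters with between-target variance -> 1
  ident <- cbind(c(1, 3, 5, 7), c(1, 3, 5, 7))
  expect_equal(icc_2k(ident)$value, 1.0)

  set.seed(77)
  for (i in 1:200) {
    n <- sample(5:30, 1); k <- sample(2:5, 1)
    truth <- rnorm(n, 4, 1)
    m <- truth + matrix(rnorm(n * k, 0, 0.8), n, k)
    r <- icc_2k(m)
    expect_equal(r$value, oracle_icc2k(m), tolerance = 1e-10)
    expect_lte(r$value, 1)
  }

  # beta-test shaped fixture: 30 targets x 4 raters reports ICC(2,4) with p
  set.seed(30)
  truth <- runif(30, 2, 6)
  ratings <- sapply(1:4, function(j) truth + rnorm(30, 0, 0.5))
  r <- icc_2k(ratings)
  expect_identical(r$statistic, "ICC(2,4)")
  expect_identical(c(r$df1, r$df2), c(29, 87))
  expect_lt(r$p, 0.001)
  expect_gt(r$value, 0.8)
})

test_that("Pearson correlation matches closed-form computation", {
  expect_equal(pearson_cor(1:5, 1:5)$r, 1.0)
  expect_equal(pearson_cor(c(1, 2, 3), c(6, 4, 2))$r, -1.0)
  set.seed(23)
  for (i in 1:100) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(pearson_cor(x, y)$r, oracle_pearson(x, y),
                 tolerance = 1e-12)
  }
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), class = "sitr_stat_error")
  expect_error(pearson_cor(1:2, 1:2), class = "sitr_input_error")
})

test_that("MANOVA: identical groups give lambda 1; single DV equals ANOVA", {
  set.seed(3)
  y <- cbind(sev = rnorm(20, 4), out = rnorm(20, 3))
  dv <- rbind(y, y)
  g <- rep(c("m", "r"), each = 20)
  res <- one_way_manova(g, dv)
  expect_equal(res$wilks, 1.0, tolerance = 1e-12)
  expect_equal(res$F, 0, tolerance = 1e-9)
  expect_true(all(abs(res$mean_differences$mean_difference) < 1e-12))

  for (i in 1:50) {
    g <- sample(c("a", "b", "c"), 24, replace = TRUE)
    if (length(unique(g)) < 3) next
    y1 <- rnorm(24)
    res1 <- one_way_manova(g, cbind(y = y1))
    a <- summary(aov(y1 ~ factor(g)))[[1]]
    expect_lt(abs(res1$F - a$`F value`[1]), 1e-8 * max(1, a$`F value`[1]))
    expect_lt(abs(res1$p - a$`Pr(>F)`[1]), 1e-8)
    expect_identical(c(res1$df1, res1$df2), c(a$Df[1], a$Df[2]))
  }
})

test_that("Wilks' lambda and Rao's F agree with the standard fitter", {
  set.seed(15)
  for (i in 1:50) {
    n <- sample(20:40, 1)
    g <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (min(table(g)) < 3) next
    dv <- cbind(rnorm(n), rnorm(n), rnorm(n))
    res <- one_way_manova(g, dv)
    o <- oracle_wilks(g, dv)
    expect_equal(res$wilks, unname(o$wilks), tolerance = 1e-8)
    expect_equal(res$F, unname(o$F), tolerance = 1e-8)
    expect_equal(res$p, unname(o$p), tolerance = 1e-8)
  }
})

test_that("mean differences come with pooled-variance confidence intervals", {
  set.seed(9)
  g <- rep(c("machine", "reference"), each = 15)
  dv <- cbind(sev = c(rnorm(15, 4.5), rnorm(15, 3.5)),
              out = rnorm(30, 3))
  res <- one_way_manova(g, dv)
  md <- res$mean_differences
  expect_setequal(names(md), c("dv", "I", "J", "mean_difference", "p",
                               "ci_lower", "ci_upper"))
  sev <- md[md$dv == "sev", ]
  expect_equal(sev$mean_difference,
               mean(dv[g == "machine", "sev"]) -
                 mean(dv[g == "reference", "sev"]))
  expect_true(all(md$ci_lower < md$ci_upper))
})

test_that("hierarchical regression reports R2 change matching the OLS oracle", {
  set.seed(33)
  d <- tibble::tibble(x1 = rnorm(20), x2 = rnorm(20), x3 = rnorm(20))
  d$y <- 1 + 0.8 * d$x1 - 0.5 * d$x2 + rnorm(20)
  fit <- hierarchical_regression(d, "y", list("x1", c("x2", "x3")))
  st <- fit$steps
  r2_1 <- oracle_r2(d["x1"], d$y)
  r2_2 <- oracle_r2(d[c("x1", "x2", "x3")], d$y)
  expect_equal(st$R2, c(r2_1, r2_2), tolerance = 1e-10)
  expect_equal(st$dR2, c(r2_1, r2_2 - r2_1), tolerance = 1e-10)
  expect_equal(st$F_change[2],
               oracle_f_change(r2_1, r2_2, 2, 20, 3), tolerance = 1e-8)
  expect_true(all(st$dR2 >= 0))
  expect_true(all(diff(st$R2) >= 0))

  # standardized betas equal B * sd(x) / sd(y)
  co <- fit$coefficients
  b1 <- co[co$step == 1 & co$term == "x1", ]
  expect_equal(b1$beta, b1$B * sd(d$x1) / sd(d$y), tolerance = 1e-12)

  # exact linear dependence on block 1
  d2 <- d; d2$y <- 2 * d2$x1 + 1
  fit2 <- suppressWarnings(hierarchical_regression(d2, "y",
                                                   list("x1", "x2")))
  expect_equal(fit2$steps$R2[1], 1.0, tolerance = 1e-12)
  expect_equal(fit2$steps$dR2[2], 0.0, tolerance = 1e-10)

  # constant predictor -> rank error
  d3 <- d; d3$zc <- 1
  expect_error(hierarchical_regression(d3, "y", list("x1", "zc")),
               class = "sitr_stat_error")
  expect_error(hierarchical_regression(d[1:3, ], "y",
                                       list(c("x1", "x2", "x3"))),
               class = "sitr_input_error")
})

test_that("assumption checks flag heteroscedastic groups and reject degenerate input", {
  set.seed(44)
  y_ok <- rnorm(60)
  g <- rep(c("a", "b"), each = 30)
  rep_ok <- assumption_checks(y_ok, g)
  expect_setequal(unique(rep_ok$check), c("shapiro_wilk", "levene_median"))

  # strong variance ratio: Levene should reject
  y_het <- c(rnorm(100, sd = 1), rnorm(100, sd = sqrt(10)))
  g2 <- rep(c("a", "b"), each = 100)
  lev <- assumption_checks(y_het, g2)
  expect_true(lev$flagged[lev$check == "levene_median"])

  expect_error(assumption_checks(rep(2, 10)), class = "sitr_stat_error")
  expect_error(assumption_checks(rnorm(10), c(rep("a", 8), "b", "b")),
               class = "sitr_input_error")
})
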