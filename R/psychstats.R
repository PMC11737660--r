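# Statistical procedures used to calibrate and validate the machine:
# inter-rater agreement, reliability, machine-vs-rater group comparison,
# correlation, and incremental-validity regression.

#' Landis-Koch agreement band for a kappa value
#' @param kappa Numeric scalar in \[-1, 1\].
#' @return Character label.
#' @export
landis_koch_band <- function(kappa) {
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two raters over the same targets:
#' `kappa = (p_o - p_e) / (1 - p_e)`. Ratings are treated as categories
#' over the union of observed levels (sorted). `weighting` selects the
#' disagreement weight matrix: `"none"` (identity agreement), `"linear"`,
#' or `"quadratic"` on the ordinal distance. Unweighted is the default for
#' Likert judgments.
#'
#' @param ratings_a,ratings_b Equal-length vectors of paired ratings.
#' @param weighting `"none"`, `"linear"` or `"quadratic"`.
#' @return Tibble: `statistic`, `value`, `band`, `n`, `weighting`.
#' @export
#' @examples
#' # 2x2 agreement table [[20, 5], [10, 15]] -> kappa = 0.40 ("fair")
#' a <- rep(c(1, 1, 2, 2), c(20, 5, 10, 15))
#' b <- rep(c(1, 2, 1, 2), c(20, 5, 10, 15))
#' cohens_kappa(a, b)
cohens_kappa <- function(ratings_a, ratings_b,
                         weighting = c("none", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  stopifnot(length(ratings_a) == length(ratings_b))
  levels <- sort(union(unique(ratings_a), unique(ratings_b)))
  if (length(levels) < 2) {
    stop_sitr("sitr_stat_error",
              "kappa undefined: fewer than 2 observed categories")
  }
  a <- factor(ratings_a, levels = levels)
  b <- factor(ratings_b, levels = levels)
  n <- length(a)
  obs <- table(a, b) / n
  exp <- outer(rowSums(obs), colSums(obs))
  C <- length(levels)
  d <- abs(outer(seq_len(C), seq_len(C), "-"))
  w <- switch(weighting,
    none = ifelse(d == 0, 0, 1),
    linear = d / (C - 1),
    quadratic = (d / (C - 1))^2
  )
  denom <- sum(w * exp)
  if (denom == 0) {
    stop_sitr("sitr_stat_error",
              "kappa undefined: expected agreement is 1 (no chance disagreement)")
  }
  value <- 1 - sum(w * obs) / denom
  tibble::tibble(statistic = "kappa", value = value,
                 band = landis_koch_band(value), n = n,
                 weighting = weighting)
}

#' Intraclass correlation ICC(2,k)
#'
#' Shrout-Fleiss two-way random-effects, absolute-agreement, average-
#' measures reliability of the mean of `k` raters over `n` targets,
#' computed from the two-way ANOVA mean squares:
#' `ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`,
#' with `F = MSR / MSE` on `(n - 1, (n - 1)(k - 1))` degrees of freedom.
#'
#' @param ratings Numeric matrix, targets in rows, raters in columns;
#'   complete (no missing cells).
#' @return Tibble: `statistic`, `value`, `F`, `df1`, `df2`, `p`,
#'   `n_targets`, `n_raters`.
#' @export
icc_2k <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot(n >= 2, k >= 2)
  if (anyNA(ratings)) {
    stop_sitr("sitr_input_error", "ICC requires a complete ratings matrix")
  }
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (msc - mse) / n
  if (denom == 0 && msr - mse == 0) {
    stop_sitr("sitr_stat_error",
              "ICC undefined: no between-target variance and no error")
  }
  value <- (msr - mse) / denom
  Fv <- if (mse == 0) Inf else msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  tibble::tibble(statistic = sprintf("ICC(2,%d)", k), value = value,
                 F = Fv, df1 = df1, df2 = df2, p = p,
                 n_targets = n, n_raters = k)
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (n >= 3, nonzero variances).
#' @return Tibble: `r`, `t`, `df`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) {
    stop_sitr("sitr_input_error", "need n >= 3 for a correlation test")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_sitr("sitr_stat_error", "correlation undefined: zero variance")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), t = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value, n = length(x))
}

#' One-way MANOVA (Wilks' lambda with Rao's F)
#'
#' Multivariate comparison of group mean vectors. Wilks' lambda is
#' computed from the between- and within-group SSCP matrices,
#' `lambda = det(W) / det(B + W)`, with Rao's F approximation. Univariate
#' one-way F tests per dependent variable and pairwise group mean
#' differences with pooled-variance 95% confidence intervals are included
#' as follow-ups.
#'
#' @param group Factor-like vector of group labels.
#' @param dv Numeric matrix or data frame of dependent variables (rows
#'   aligned with `group`).
#' @return Object of class `sitr_manova`: list with `wilks`, `F`, `df1`,
#'   `df2`, `p`, `univariate` (tibble per DV), `mean_differences` (tibble
#'   in mean-difference (I-J) layout with 95% CI).
#' @export
one_way_manova <- function(group, dv) {
  dv <- as.matrix(dv)
  if (is.null(colnames(dv))) colnames(dv) <- paste0("dv", seq_len(ncol(dv)))
  group <- factor(group)
  stopifnot(nlevels(group) >= 2, nrow(dv) == length(group))
  n <- nrow(dv); g <- nlevels(group); p <- ncol(dv)

  grand <- colMeans(dv)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in levels(group)) {
    rows <- dv[group == lev, , drop = FALSE]
    ng <- nrow(rows); gm <- colMeans(rows)
    cent <- sweep(rows, 2, gm)
    W <- W + crossprod(cent)
    B <- B + ng * tcrossprod(gm - grand)
  }
  T_ <- B + W
  detW <- det(W); detT <- det(T_)
  if (detW <= 0 || !is.finite(detW)) {
    stop_sitr("sitr_stat_error",
              "singular within-group covariance; MANOVA undefined")
  }
  lambda <- detW / detT

  # Rao's F approximation
  q <- g - 1
  t_ <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w_ <- n - 1 - (p + g) / 2
  df1 <- p * q
  df2 <- w_ * t_ - (p * q - 2) / 2
  Lt <- lambda^(1 / t_)
  Fv <- ((1 - Lt) / Lt) * (df2 / df1)
  pval <- pf(Fv, df1, df2, lower.tail = FALSE)

  univ <- purrr::map_dfr(colnames(dv), function(v) {
    fit <- aov(dv[, v] ~ group)
    s <- summary(fit)[[1]]
    tibble::tibble(dv = v, F = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
                   p = s$`Pr(>F)`[1])
  })

  mean_diffs <- purrr::map_dfr(colnames(dv), function(v) {
    fit <- aov(dv[, v] ~ group)
    s <- summary(fit)[[1]]
    msw <- s$`Mean Sq`[2]; dfw <- s$Df[2]
    combos <- utils::combn(levels(group), 2, simplify = FALSE)
    purrr::map_dfr(combos, function(pr) {
      i <- pr[1]; j <- pr[2]
      ni <- sum(group == i); nj <- sum(group == j)
      diff <- mean(dv[group == i, v]) - mean(dv[group == j, v])
      se <- sqrt(msw * (1 / ni + 1 / nj))
      tcrit <- qt(0.975, dfw)
      tibble::tibble(dv = v, I = i, J = j, mean_difference = diff,
                     p = 2 * pt(abs(diff / se), dfw, lower.tail = FALSE),
                     ci_lower = diff - tcrit * se,
                     ci_upper = diff + tcrit * se)
    })
  })

  structure(list(wilks = lambda, F = Fv, df1 = df1, df2 = df2, p = pval,
                 univariate = univ, mean_differences = mean_diffs,
                 n = n, n_groups = g, n_dv = p),
            class = "sitr_manova")
}

#' @export
print.sitr_manova <- function(x, ...) {
  cat(sprintf("One-way MANOVA: Wilks' lambda = %.4f, F(%g, %.1f) = %.3f, p = %.4g\n",
              x$wilks, x$df1, x$df2, x$F, x$p))
  print(x$univariate)
  invisible(x)
}

#' @method tidy sitr_manova
#' @export
tidy.sitr_manova <- function(x, ...) x$mean_differences

#' @method glance sitr_manova
#' @export
glance.sitr_manova <- function(x, ...) {
  tibble::tibble(wilks = x$wilks, F = x$F, df1 = x$df1, df2 = x$df2,
                 p = x$p, n = x$n, n_groups = x$n_groups, n_dv = x$n_dv)
}

#' Hierarchical multiple regression with R-squared change
#'
#' Fits ordinary least squares on cumulative predictor blocks and reports
#' per-step R-squared, its change over the previous step, and the
#' F-change test `F = (dR2 / q) / ((1 - R2_step) / (n - p_step - 1))`
#' where `q` is the number of predictors added. Coefficients are reported
#' as unstandardized B with SE and t, plus standardized beta
#' (`B * sd(x) / sd(y)`), mirroring the usual incremental-validity table.
#'
#' @param data Data frame holding the outcome and all predictors.
#' @param outcome Name of the outcome column.
#' @param blocks List of character vectors: predictors entered at each step.
#' @return Object of class `sitr_hierreg`: list with `steps` (tibble:
#'   step, R2, dR2, F_change, df1, df2, p_change, F_model) and
#'   `coefficients` (tibble per step x term).
#' @export
hierarchical_regression <- function(data, outcome, blocks) {
  stopifnot(outcome %in% names(data), length(blocks) >= 1)
  n <- nrow(data)
  y <- data[[outcome]]
  all_preds <- unique(unlist(blocks))
  if (n <= length(all_preds) + 1) {
    stop_sitr("sitr_input_error",
              "need more observations than predictors + 1")
  }
  steps <- list(); coefs <- list()
  r2_prev <- 0
  for (s in seq_along(blocks)) {
    preds <- unique(unlist(blocks[seq_len(s)]))
    fml <- stats::reformulate(preds, response = outcome)
    fit <- lm(fml, data = data)
    if (fit$rank < length(preds) + 1) {
      stop_sitr("sitr_stat_error",
                paste0("rank-deficient design at step ", s,
                       " (collinear or constant predictor)"))
    }
    sm <- summary(fit)
    r2 <- sm$r.squared
    q <- length(preds) - (length(unique(unlist(blocks[seq_len(s - 1)]))))
    dr2 <- r2 - r2_prev
    df2 <- n - length(preds) - 1
    f_change <- (dr2 / q) / ((1 - r2) / df2)
    p_change <- pf(f_change, q, df2, lower.tail = FALSE)
    steps[[s]] <- tibble::tibble(
      step = s, R2 = r2, dR2 = dr2, F_change = f_change,
      df1 = q, df2 = df2, p_change = p_change,
      F_model = unname(sm$fstatistic[1])
    )
    ct <- sm$coefficients
    beta <- vapply(rownames(ct), function(term) {
      if (term == "(Intercept)") NA_real_
      else unname(ct[term, 1]) * sd(data[[term]]) / sd(y)
    }, numeric(1))
    coefs[[s]] <- tibble::tibble(
      step = s, term = rownames(ct), B = ct[, 1], SE = ct[, 2],
      beta = beta, t = ct[, 3], p = ct[, 4]
    )
    r2_prev <- r2
  }
  structure(list(steps = dplyr::bind_rows(steps),
                 coefficients = dplyr::bind_rows(coefs),
                 outcome = outcome, n = n),
            class = "sitr_hierreg")
}

#' @export
print.sitr_hierreg <- function(x, ...) {
  cat("Hierarchical regression of", x$outcome, "(n =", x$n, ")\n")
  print(x$steps)
  invisible(x)
}

#' @method tidy sitr_hierreg
#' @export
tidy.sitr_hierreg <- function(x, ...) x$coefficients

#' @method glance sitr_hierreg
#' @export
glance.sitr_hierreg <- function(x, ...) x$steps

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group (or pooled when `group` is `NULL`) and, with
#' groups, Levene's test centered at the median. A flag is raised when a
#' test rejects at `alpha`.
#'
#' @param y Numeric outcome.
#' @param group Optional group labels.
#' @param alpha Flagging level (default 0.05).
#' @return Tibble: `check`, `group`, `statistic`, `p`, `flagged`.
#' @export
assumption_checks <- function(y, group = NULL, alpha = 0.05) {
  if (sd(y) == 0) {
    stop_sitr("sitr_stat_error",
              "constant outcome: normality test undefined")
  }
  out <- list()
  if (is.null(group)) {
    if (length(y) < 3) {
      stop_sitr("sitr_input_error", "Shapiro-Wilk needs n >= 3")
    }
    sw <- shapiro.test(y)
    out[[1]] <- tibble::tibble(check = "shapiro_wilk", group = "all",
                               statistic = unname(sw$statistic),
                               p = sw$p.value, flagged = sw$p.value < alpha)
  } else {
    group <- factor(group)
    for (lev in levels(group)) {
      yi <- y[group == lev]
      if (length(yi) < 3) {
        stop_sitr("sitr_input_error",
                  paste0("Shapiro-Wilk needs n >= 3 in group ", lev))
      }
      sw <- shapiro.test(yi)
      out[[length(out) + 1L]] <-
        tibble::tibble(check = "shapiro_wilk", group = lev,
                       statistic = unname(sw$statistic), p = sw$p.value,
                       flagged = sw$p.value < alpha)
    }
    lv <- car::leveneTest(y ~ group, center = stats::median)
    out[[length(out) + 1L]] <-
      tibble::tibble(check = "levene_median", group = "all",
                     statistic = lv$`F value`[1], p = lv$`Pr(>F)`[1],
                     flagged = lv$`Pr(>F)`[1] < alpha)
  }
  dplyr::bind_rows(out)
}
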