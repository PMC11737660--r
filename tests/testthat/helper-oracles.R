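# Independent brute-force oracles for the psychometric statistics. These
# deliberately use explicit loops / closed-form arithmetic, not the
# package's code paths.

oracle_kappa <- function(a, b) {
  lev <- sort(union(unique(a), unique(b)))
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (l in lev) {
    pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
  }
  (po - pe) / (1 - pe)
}

oracle_icc2k <- function(m) {
  n <- nrow(m); k <- ncol(m)
  mu <- mean(m)
  ss_r <- 0; ss_c <- 0; ss_t <- 0
  for (i in seq_len(n)) ss_r <- ss_r + k * (mean(m[i, ]) - mu)^2
  for (j in seq_len(k)) ss_c <- ss_c + n * (mean(m[, j]) - mu)^2
  for (i in seq_len(n)) for (j in seq_len(k)) ss_t <- ss_t + (m[i, j] - mu)^2
  msr <- ss_r / (n - 1)
  msc <- ss_c / (k - 1)
  mse <- (ss_t - ss_r - ss_c) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}

# Normal-equations OLS R-squared for a design with intercept.
oracle_r2 <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  b <- solve(crossprod(X1), crossprod(X1, y))
  res <- y - X1 %*% b
  1 - sum(res^2) / sum((y - mean(y))^2)
}

oracle_f_change <- function(r2_red, r2_full, q, n, p_full) {
  ((r2_full - r2_red) / q) / ((1 - r2_full) / (n - p_full - 1))
}

# Wilks' lambda and its approximate F via the standard fitter.
oracle_wilks <- function(group, dv) {
  fit <- stats::manova(as.matrix(dv) ~ factor(group))
  s <- summary(fit, test = "Wilks")$stats
  list(wilks = s[1, "Wilks"], F = s[1, "approx F"],
       df1 = s[1, "num Df"], df2 = s[1, "den Df"],
       p = s[1, "Pr(>F)"])
}
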