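test_that("Pearson correlation matches the covariance-formula oracle", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 3.1, 6.0, 2.9, 4.8, 5.1)
  y <- c(2.0, 3.1, 2.5, 6.1, 3.9, 3.5, 5.2, 2.2, 5.5, 4.1)
  res <- pearson_with_ci(x, y)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, oracle, tolerance = 1e-12)
  expect_true(res$ci[1] < res$estimate & res$estimate < res$ci[2])
  expect_equal(pearson_with_ci(x, x)$estimate, 1)
  expect_equal(pearson_with_ci(x, -x)$estimate, -1)
  expect_error(pearson_with_ci(x, rep(2, 10)), "constant")
})

test_that("Pearson p agrees with the exhaustive permutation p at small n", {
  x <- c(0.3, 1.9, -0.6, 2.2, 0.8, -1.4, 1.1)
  y <- c(0.1, 1.2, -0.2, 1.0, 1.4, -0.8, 0.2)
  r_obs <- abs(cor(x, y))
  # enumerate all 7! orderings of y
  idx <- seq_along(y)
  all_perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  ps <- all_perms(idx)
  rs <- vapply(ps, function(p) abs(cor(x, y[p])), numeric(1))
  p_perm <- mean(rs >= r_obs - 1e-12)
  p_t <- pearson_with_ci(x, y)$p
  expect_lt(abs(p_t - p_perm), 0.06)
})

test_that("tau-b equals the brute-force pair-count oracle", {
  expect_equal(kendall_tau_b(1:6, 1:6 * 2)$estimate, 1)
  expect_equal(kendall_tau_b(1:6, rev(1:6))$estimate, -1)
  set.seed(17)
  for (i in 1:12) {
    n <- sample(8:50, 1)
    x <- sample(1:7, n, replace = TRUE)
    y <- sample(1:10, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau_b(x, y)$estimate, tau_b_bruteforce(x, y),
                 tolerance = 1e-12)
  }
  expect_error(kendall_tau_b(rep(3, 5), 1:5), "constant")
  # non-constant self-correlation is exactly 1 even with ties
  x <- c(1, 2, 2, 3, 5, 5, 6)
  expect_equal(kendall_tau_b(x, x)$estimate, 1)
})

test_that("paired t-test matches hand computation", {
  a <- c(4.1, 3.8, 5.2, 4.7, 3.3, 4.9, 5.5, 4.0)
  b <- c(3.6, 3.9, 4.8, 4.1, 3.1, 4.2, 5.0, 3.8)
  res <- paired_t_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(8))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_identical(res$df, 7)
  expect_equal(res$p, 2 * pt(abs(t_hand), 7, lower.tail = FALSE))
  z <- paired_t_test(a, a)
  expect_equal(z$t, 0); expect_equal(z$p, 1)
  expect_error(paired_t_test(a, a - 1), "unbounded")
})

test_that("two-factor GLM reproduces a hand ANOVA on a balanced table", {
  # balanced 2x2, 3 per cell
  A <- rep(c("m", "f"), each = 6)
  B <- rep(rep(c("br", "cz"), each = 3), 2)
  dv <- c(10, 11, 12,  13, 14, 15,   20, 21, 22,  17, 18, 19)
  res <- two_way_anova_partial_eta(dv, A, B)
  cell <- tapply(dv, list(A, B), mean)
  grand <- mean(dv)
  ss_a <- 6 * sum((rowMeans(cell) - grand)^2)
  ss_b <- 6 * sum((colMeans(cell) - grand)^2)
  ss_ab <- 3 * sum((cell - outer(rowMeans(cell), colMeans(cell), `+`) + grand)^2)
  ss_err <- sum((dv - rep(as.vector(cell[cbind(A, B)]), 1))^2)
  tab <- res$table
  get <- function(term, col) tab[tab$term == term, col]
  expect_equal(get("A", "F"), (ss_a / 1) / (ss_err / 8), tolerance = 1e-10)
  expect_equal(get("B", "F"), (ss_b / 1) / (ss_err / 8), tolerance = 1e-10)
  expect_equal(get("A:B", "F"), (ss_ab / 1) / (ss_err / 8), tolerance = 1e-10)
  expect_equal(get("A", "partial_eta_sq"), ss_a / (ss_a + ss_err),
               tolerance = 1e-10)
  # estimated marginal means average cells equally
  expect_equal(res$emmeans$a, rowMeans(cell))
  expect_equal(res$emmeans$b, colMeans(cell))
})

test_that("GLM effect sizes are null-consistent and affine invariant", {
  set.seed(23)
  n <- 4000
  A <- sample(c("x", "y"), n, TRUE); B <- sample(c("p", "q"), n, TRUE)
  dv <- rnorm(n)
  res <- two_way_anova_partial_eta(dv, A, B)
  expect_true(all(res$table$partial_eta_sq < 0.01))
  res2 <- two_way_anova_partial_eta(3 * dv - 7, A, B)
  expect_equal(res$table$F, res2$table$F, tolerance = 1e-9)
  expect_equal(res$table$partial_eta_sq, res2$table$partial_eta_sq,
               tolerance = 1e-9)
  # empty cell rejected
  expect_error(two_way_anova_partial_eta(dv, A, ifelse(A == "x", "p", "q")),
               "empty")
})

test_that("unbalanced Type-III tests match the model-comparison definition", {
  set.seed(29)
  n <- 60
  A <- factor(sample(c("m", "f"), n, TRUE, prob = c(0.7, 0.3)))
  B <- factor(sample(c("br", "cz"), n, TRUE))
  dv <- rnorm(n) + (A == "m") * 0.8
  res <- two_way_anova_partial_eta(dv, A, B)
  # oracle: lm with sum contrasts, drop each term's columns
  contrasts(A) <- contr.sum(2); contrasts(B) <- contr.sum(2)
  X <- model.matrix(~ A * B)
  rss <- function(cols) sum(lsfit(X[, cols, drop = FALSE], dv,
                                  intercept = FALSE)$residuals^2)
  full <- rss(1:4)
  f_a <- ((rss(c(1, 3, 4)) - full) / 1) / (full / (n - 4))
  expect_equal(res$table$F[res$table$term == "A"], f_a, tolerance = 1e-8)
})
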