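## Generic statistics reported alongside the path model: correlations with
## confidence intervals, paired comparisons, and a two-factor GLM with
## partial eta-squared effect sizes.

correlation_result <- function(method, estimate, n, p, ci = NULL,
                               statistic = NULL, conf = NULL) {
  structure(list(method = method, estimate = estimate, n = n, p = p,
                 ci = ci, statistic = statistic, conf = conf),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: %.3f (n = %d, p = %.4g)\n",
              x$method, x$estimate, x$n, x$p))
  if (!is.null(x$ci))
    cat(sprintf("  %d%% CI [%.3f, %.3f]\n", round(100 * (x$conf %||% 0.95)),
                x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with the usual t-based two-sided p-value
#' (`t = r * sqrt((n-2)/(1-r^2))`, df = n-2) and a confidence interval from
#' the Fisher z transform, `tanh(atanh(r) +/- z_crit / sqrt(n-3))`.
#'
#' @param x,y Aligned numeric vectors, n >= 4, non-constant.
#' @param conf Confidence level (default 0.95).
#' @return A `correlation_result` with fields `estimate`, `n`, `p`, `ci`.
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) vp_stop("`x` and `y` differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) vp_stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    vp_stop("correlation undefined for constant input",
            class = "voxpath_degenerate_error")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  ci <- if (abs(r) >= 1) c(r, r) else {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    crit <- stats::qnorm(1 - (1 - conf) / 2)
    tanh(c(z - crit * se, z + crit * se))
  }
  correlation_result("pearson", r, n, p, ci = ci, conf = conf)
}

#' Kendall rank correlation (tau-b) with tie correction
#'
#' Tau-b from concordant/discordant pair counts with the standard tie
#' corrections, computed from the cross-tabulation of the two rankings;
#' the two-sided p-value uses the normal approximation with the
#' tie-corrected variance of the S statistic.  Suited to heavily tied
#' scales (7- and 10-point ratings).
#'
#' @param x,y Aligned numeric vectors, n >= 3, not all tied.
#' @return A `correlation_result` with fields `estimate` (tau-b), `n`, `p`.
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) vp_stop("`x` and `y` differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) vp_stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    vp_stop("tau undefined when either variable is constant",
            class = "voxpath_degenerate_error")

  ## aggregate over the contingency table of distinct value pairs
  xu <- sort(unique(x)); yu <- sort(unique(y))
  tab <- unclass(table(factor(x, levels = xu), factor(y, levels = yu)))
  R <- nrow(tab); C <- ncol(tab)
  conc <- 0; disc <- 0
  for (i in seq_len(R)) for (j in seq_len(C)) {
    nij <- tab[i, j]
    if (nij == 0) next
    if (i < R && j < C)
      conc <- conc + nij * sum(tab[(i + 1):R, (j + 1):C])
    if (i < R && j > 1)
      disc <- disc + nij * sum(tab[(i + 1):R, 1:(j - 1)])
  }
  S <- conc - disc
  t_i <- rowSums(tab); u_j <- colSums(tab)
  n0 <- n * (n - 1) / 2
  n1 <- sum(t_i * (t_i - 1)) / 2
  n2 <- sum(u_j * (u_j - 1)) / 2
  tau <- S / sqrt((n0 - n1) * (n0 - n2))

  ## tie-corrected variance of S (Kendall 1970), as in the usual normal
  ## approximation for tied data
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(t_i * (t_i - 1) * (2 * t_i + 5))
  vu <- sum(u_j * (u_j - 1) * (2 * u_j + 5))
  v1 <- sum(t_i * (t_i - 1)) * sum(u_j * (u_j - 1)) / (2 * n * (n - 1))
  v2 <- sum(t_i * (t_i - 1) * (t_i - 2)) * sum(u_j * (u_j - 1) * (u_j - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- if (var_s > 0) S / sqrt(var_s) else 0
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  correlation_result("kendall_b", tau, n, min(p, 1), statistic = z)
}

#' Paired t-test
#'
#' One-sample t on the paired differences: `t = mean(d) / (sd(d)/sqrt(n))`,
#' df = n - 1, two-sided p.
#'
#' @param a,b Aligned numeric vectors, n >= 2.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) vp_stop("`a` and `b` differ in length")
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2L) vp_stop("need at least 2 complete pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n))
    vp_stop("zero variance of non-zero differences; t is unbounded",
            class = "voxpath_degenerate_error")
  }
  tt <- mean(d) / (sd_d / sqrt(n))
  list(t = tt, df = n - 1,
       p = 2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE),
       mean_diff = mean(d), n = n)
}

#' Two-factor GLM with Type-III sums of squares and partial eta-squared
#'
#' Fits `dv ~ A * B` (interaction optional) with sum-to-zero contrasts and
#' reports, per term, the Type-III F test (full model vs. the model with
#' that term's columns removed) together with the effect size
#' `partial eta^2 = SS_effect / (SS_effect + SS_error)`.  Estimated
#' marginal means are cell means averaged equally over the other factor's
#' levels.
#'
#' @param dv Numeric response.
#' @param factor_a,factor_b Factors (coerced), >= 2 levels each, no empty
#'   cells.
#' @param include_interaction Include the A:B term (default `TRUE`).
#' @return List of class `anova_result`: `table` (term, df1, df2, F, p,
#'   partial_eta_sq), `emmeans` (per factor), `n`.
#' @export
two_way_anova_partial_eta <- function(dv, factor_a, factor_b,
                                      include_interaction = TRUE) {
  ok <- is.finite(dv) & !is.na(factor_a) & !is.na(factor_b)
  dv <- dv[ok]
  A <- droplevels(as.factor(factor_a[ok]))
  B <- droplevels(as.factor(factor_b[ok]))
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    vp_stop("both factors need at least 2 observed levels")
  if (any(table(A, B) == 0L))
    vp_stop("empty factor cell(s); Type-III tests are not estimable")
  n <- length(dv)

  contrasts(A) <- stats::contr.sum(nlevels(A))
  contrasts(B) <- stats::contr.sum(nlevels(B))
  form <- if (include_interaction) dv ~ A * B else dv ~ A + B
  mf <- stats::model.frame(form, data = data.frame(dv = dv, A = A, B = B))
  X <- stats::model.matrix(form, mf)
  asgn <- attr(X, "assign")
  fit_rss <- function(Xs) sum(stats::residuals(stats::lm.fit(Xs, dv))^2)
  rss_full <- fit_rss(X)
  df_err <- n - ncol(X)
  if (df_err < 1L) vp_stop("no residual degrees of freedom")
  terms_lab <- attr(stats::terms(form), "term.labels")
  rows <- lapply(seq_along(terms_lab), function(ti) {
    keep <- asgn != ti
    rss_red <- fit_rss(X[, keep, drop = FALSE])
    df1 <- sum(asgn == ti)
    ss_eff <- rss_red - rss_full
    Fv <- (ss_eff / df1) / (rss_full / df_err)
    data.frame(term = terms_lab[ti], df1 = df1, df2 = df_err, F = Fv,
               p = stats::pf(Fv, df1, df_err, lower.tail = FALSE),
               partial_eta_sq = ss_eff / (ss_eff + rss_full),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  cell <- tapply(dv, list(A, B), mean)
  emmeans <- list(
    a = rowMeans(cell),
    b = colMeans(cell),
    cells = cell
  )
  structure(list(table = tab, emmeans = emmeans, n = n),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Two-factor GLM (Type III, n = %d)\n", x$n))
  print(transform(x$table, F = round(F, 2), p = signif(p, 3),
                  partial_eta_sq = round(partial_eta_sq, 3)))
  invisible(x)
}
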