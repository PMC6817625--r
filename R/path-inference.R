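## Permutation-null p-values and jackknife stability certification for
## path-model parameters.

prepare_analysis_matrix <- function(data, spec, standardize = TRUE) {
  X <- data[spec$variables]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (standardize) standardize_columns(X) else as.matrix(X)
}

#' Permutation-null p-values for every path-model parameter
#'
#' The null distribution of each standardized coefficient is obtained by
#' refitting the full model on randomized datasets.  Under the default
#' `scheme = "columns"` every variable's column is permuted independently,
#' which destroys all dependencies while preserving each marginal
#' distribution -- the weakest assumption consistent with estimating the
#' model "on a randomized dataset".  The two-sided p-value for parameter
#' theta uses the add-one correction,
#' `p = (1 + #\{|theta*_b| >= |theta_hat|\}) / (B + 1)`,
#' so the smallest attainable value is `1 / (B + 1)`.
#'
#' @param data Data frame with the spec's variables.
#' @param spec A `path_spec`.
#' @param B Number of randomized replicates (default 10000).
#' @param seed Optional integer seed.
#' @param scheme `"columns"` (independent column permutations, default) or
#'   `"joint"` (one shared permutation of all endogenous columns against
#'   the exogenous block).
#' @param max_failure_rate Abort when more than this fraction of replicate
#'   refits fail (default 0.01).
#' @return Named numeric vector of p-values, ordered as the fit's
#'   parameters; attribute `failures` counts failed refits.
#' @export
permutation_pvalues <- function(data, spec, B = 10000, seed = NULL,
                                scheme = c("columns", "joint"),
                                max_failure_rate = 0.01) {
  scheme <- match.arg(scheme)
  if (!is.numeric(B) || B < 1) vp_stop("`B` must be >= 1")
  B <- as.integer(B)
  comp <- compile_spec(spec)
  Z <- prepare_analysis_matrix(data, spec)
  n <- nrow(Z)
  obs <- abs(fit_estimates_from_C(stats::cov(Z), comp))
  if (!is.null(seed)) set.seed(seed)
  endo_cols <- match(names(comp$endo), comp$vars)
  exceed <- integer(length(obs))
  failures <- 0L
  Zp <- Z
  for (b in seq_len(B)) {
    if (scheme == "columns") {
      for (j in seq_len(ncol(Z))) Zp[, j] <- Z[sample.int(n), j]
    } else {
      perm <- sample.int(n)
      Zp <- Z
      Zp[, endo_cols] <- Z[perm, endo_cols]
    }
    est <- tryCatch(fit_estimates_from_C(crossprod(Zp) / (n - 1), comp),
                    error = function(e) NULL)
    if (is.null(est)) { failures <- failures + 1L; next }
    exceed <- exceed + (abs(est) >= obs)
  }
  if (failures > max_failure_rate * B)
    vp_stop(sprintf("%d of %d permutation refits failed (> %.0f%%)",
                    failures, B, 100 * max_failure_rate),
            class = "voxpath_convergence_error")
  eff <- B - failures
  p <- (1 + exceed) / (eff + 1)
  names(p) <- param_labels(spec)
  attr(p, "failures") <- failures
  attr(p, "B") <- eff
  p
}

#' Jackknife stability of path-model parameters
#'
#' Refits the model on every leave-one-out subsample.  A parameter is
#' *stable* when its p-value is below `alpha` in the full sample **and** in
#' every leave-one-out refit -- i.e. no single observation is responsible
#' for its significance.  By default the analytic OLS/correlation p-values
#' are used inside the loop (running permutations within each subsample is
#' available via `p_method = "permutation"` but is far more expensive).
#'
#' @param data Data frame with the spec's variables.
#' @param spec A `path_spec`.
#' @param alpha Significance level for the stability criterion (default
#'   0.05).
#' @param p_method `"analytic"` (default) or `"permutation"`.
#' @param B,seed Permutation settings when `p_method = "permutation"`.
#' @return Data frame with `parameter`, `estimate`, `p_full`, `max_loo_p`,
#'   `n_failures`, `stable`.
#' @export
jackknife_stability <- function(data, spec, alpha = 0.05,
                                p_method = c("analytic", "permutation"),
                                B = 1000, seed = NULL) {
  p_method <- match.arg(p_method)
  if (alpha <= 0 || alpha >= 1) vp_stop("`alpha` must be in (0, 1)")
  comp <- compile_spec(spec)
  X <- data[spec$variables]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 10L) vp_stop("jackknife needs at least 10 complete cases")
  pfun <- function(rows, s) {
    Z <- standardize_columns(X[rows, , drop = FALSE])
    if (p_method == "analytic")
      analytic_pvalues_from_C(stats::cov(Z), length(rows), comp)
    else
      as.numeric(permutation_pvalues(as.data.frame(Z), spec, B = B, seed = s))
  }
  seeds <- if (p_method == "permutation") derive_seeds(seed %||% 1L, n + 1L)
           else rep(NA_integer_, n + 1L)
  Zfull <- standardize_columns(X)
  est <- fit_estimates_from_C(stats::cov(Zfull), comp)
  p_full <- pfun(seq_len(n), seeds[[n + 1L]])
  max_loo <- rep(-Inf, length(p_full))
  fail <- integer(length(p_full))
  for (i in seq_len(n)) {
    pi <- tryCatch(pfun(setdiff(seq_len(n), i), seeds[[i]]),
                   error = function(e) NULL)
    if (is.null(pi)) { fail <- fail + 1L; next }
    max_loo <- pmax(max_loo, pi)
  }
  stable <- p_full < alpha & max_loo < alpha & fail == 0L
  data.frame(parameter = param_labels(spec), estimate = est,
             p_full = p_full, max_loo_p = max_loo, n_failures = fail,
             stable = stable, stringsAsFactors = FALSE)
}
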