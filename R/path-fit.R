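## Fitting the recursive path model.  On standardized data each equation's
## ML estimates are the ordinary least-squares partial regression
## coefficients (a recursive model with diagonal residual covariance
## factorizes equation-wise), exogenous covariances are the sample values,
## and model fit is judged by the normal-theory ML discrepancy chi-square
## against the model-implied covariance.

## Precompile integer indices for fast repeated fitting (permutations,
## jackknife, invariance optimizer all reuse this).
compile_spec <- function(spec) {
  vars <- spec$variables
  p <- length(vars)
  idx <- stats::setNames(seq_len(p), vars)
  endo <- vars[spec$roles != "exogenous"]
  endo <- endo[endo %in% unique(spec$regressions$response)]
  eqs <- lapply(endo, function(v) {
    pred <- spec$regressions$predictor[spec$regressions$response == v]
    list(response = idx[[v]], predictors = unname(idx[pred]))
  })
  ## map each equation coefficient back to its row in spec$regressions;
  ## within-equation predictor order follows the spec's row order
  slots <- vector("list", length(eqs))
  for (e in seq_along(eqs)) {
    rows <- which(spec$regressions$response == endo[[e]])
    slots[[e]] <- rows
    eqs[[e]]$predictors <- unname(idx[spec$regressions$predictor[rows]])
  }
  cov_idx <- cbind(unname(idx[spec$covariances$var1]),
                   unname(idx[spec$covariances$var2]))
  exog <- unname(idx[vars[spec$roles == "exogenous"]])
  list(p = p, vars = vars, idx = idx, endo = stats::setNames(eqs, endo),
       slots = slots, cov_idx = cov_idx, exog = exog,
       n_reg = nrow(spec$regressions), n_cov = nrow(spec$covariances))
}

## Estimates (regressions then covariances) from a covariance matrix.
fit_estimates_from_C <- function(C, comp) {
  est <- numeric(comp$n_reg + comp$n_cov)
  for (e in seq_along(comp$endo)) {
    eq <- comp$endo[[e]]
    b <- solve(C[eq$predictors, eq$predictors, drop = FALSE],
               C[eq$predictors, eq$response])
    est[comp$slots[[e]]] <- b
  }
  if (comp$n_cov)
    est[comp$n_reg + seq_len(comp$n_cov)] <- C[comp$cov_idx]
  est
}

## Residual variances given coefficients, from the same covariance matrix.
residual_variances_from_C <- function(C, comp) {
  rv <- stats::setNames(diag(C), comp$vars)
  for (e in seq_along(comp$endo)) {
    eq <- comp$endo[[e]]
    b <- solve(C[eq$predictors, eq$predictors, drop = FALSE],
               C[eq$predictors, eq$response])
    rv[eq$response] <- C[eq$response, eq$response] -
      drop(crossprod(C[eq$predictors, eq$response], b))
  }
  rv
}

## Analytic OLS p-values for all parameters from C computed on n rows.
## Regression: t with df = n - k - 1 (intercept absorbed by centering);
## covariance (correlation on standardized data): t with df = n - 2.
analytic_pvalues_from_C <- function(C, n, comp) {
  pv <- numeric(comp$n_reg + comp$n_cov)
  for (e in seq_along(comp$endo)) {
    eq <- comp$endo[[e]]
    k <- length(eq$predictors)
    Cpp_inv <- solve(C[eq$predictors, eq$predictors, drop = FALSE])
    b <- drop(Cpp_inv %*% C[eq$predictors, eq$response])
    rv <- C[eq$response, eq$response] -
      drop(crossprod(C[eq$predictors, eq$response], b))
    df <- n - k - 1L
    if (df < 1L) vp_stop("too few observations for analytic inference")
    sigma2 <- rv * (n - 1) / df
    se <- sqrt(diag(Cpp_inv) * sigma2 / (n - 1))
    tt <- b / se
    pv[comp$slots[[e]]] <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  }
  if (comp$n_cov) {
    r <- C[comp$cov_idx] / sqrt(diag(C)[comp$cov_idx[, 1L]] *
                                diag(C)[comp$cov_idx[, 2L]])
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    pv[comp$n_reg + seq_len(comp$n_cov)] <-
      2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  pv
}

#' Model-implied covariance matrix of a path model
#'
#' Uses the reticular-action (RAM) formulation for an all-observed model:
#' `Sigma = (I - A)^-1 S (I - A)^-T`, where `A` holds the regression
#' coefficients (`A[response, predictor]`), and `S` the free exogenous
#' (co)variances plus the residual variances of the endogenous variables on
#' its diagonal.
#'
#' @param params List with `coefficients` (numeric, ordered as
#'   `spec$regressions`), `covariances` (ordered as `spec$covariances`),
#'   and `variances` (named by variable: variances for exogenous, residual
#'   variances for endogenous).
#' @param spec A `path_spec`.
#' @return Symmetric covariance matrix with variable dimnames.
#' @export
implied_covariance <- function(params, spec) {
  comp <- compile_spec(spec)
  p <- comp$p
  if (length(params$coefficients) != comp$n_reg)
    vp_stop("`params$coefficients` length does not match the spec")
  if (length(params$covariances %||% numeric(0)) != comp$n_cov)
    vp_stop("`params$covariances` length does not match the spec")
  v <- params$variances
  if (is.null(names(v)) || !all(comp$vars %in% names(v)))
    vp_stop("`params$variances` must be named with every model variable")
  A <- matrix(0, p, p, dimnames = list(comp$vars, comp$vars))
  A[cbind(match(spec$regressions$response, comp$vars),
          match(spec$regressions$predictor, comp$vars))] <- params$coefficients
  S <- matrix(0, p, p, dimnames = list(comp$vars, comp$vars))
  diag(S) <- v[comp$vars]
  if (comp$n_cov) {
    S[comp$cov_idx] <- params$covariances
    S[comp$cov_idx[, c(2L, 1L), drop = FALSE]] <- params$covariances
  }
  IA <- diag(p) - A
  B <- tryCatch(solve(IA), error = function(e)
    vp_stop("(I - A) is singular; the coefficient matrix is not recursive"))
  Sigma <- B %*% S %*% t(B)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(comp$vars, comp$vars)
  Sigma
}

#' Normal-theory ML discrepancy chi-square
#'
#' `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p`, scaled to the test
#' statistic `(n - 1) * F_ML`.  Zero when the implied and sample
#' covariances coincide; strictly positive otherwise.
#'
#' @param sample_cov,implied_cov Positive-definite p x p matrices.
#' @param n Number of observations behind `sample_cov`.
#' @param p_vars Number of variables (defaults to `nrow(sample_cov)`).
#' @return The chi-square statistic (scalar, `>= 0`).
#' @export
ml_chisquare <- function(sample_cov, implied_cov, n,
                         p_vars = nrow(sample_cov)) {
  S <- as.matrix(sample_cov); Sg <- as.matrix(implied_cov)
  if (!all(dim(S) == dim(Sg)))
    vp_stop("sample and implied covariance dimensions differ")
  ldS <- determinant(S, logarithm = TRUE)
  ldSg <- determinant(Sg, logarithm = TRUE)
  if (ldS$sign <= 0 || ldSg$sign <= 0 ||
      min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0 ||
      min(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    vp_stop("covariance matrices must be positive definite")
  f_ml <- as.numeric(ldSg$modulus) + sum(diag(S %*% solve(Sg))) -
    as.numeric(ldS$modulus) - p_vars
  max(0, (n - 1) * f_ml)
}

## Core fit from a prepared (standardized) data matrix.
fit_from_matrix <- function(Z, spec, comp = compile_spec(spec)) {
  n <- nrow(Z)
  C <- stats::cov(Z)
  est <- fit_estimates_from_C(C, comp)
  rv <- residual_variances_from_C(C, comp)
  params <- list(
    coefficients = est[seq_len(comp$n_reg)],
    covariances = if (comp$n_cov) est[comp$n_reg + seq_len(comp$n_cov)]
                  else numeric(0),
    variances = rv
  )
  Sigma <- implied_covariance(params, spec)
  n_free <- comp$n_reg + comp$n_cov + comp$p
  df <- comp$p * (comp$p + 1) / 2 - n_free
  chi2 <- if (df > 0) ml_chisquare(C, Sigma, n) else 0
  list(estimates = est, params = params, sample_cov = C, implied = Sigma,
       chi_square = chi2, df = df, n = n,
       p_analytic = analytic_pvalues_from_C(C, n, comp))
}

#' Fit a path model
#'
#' Complete cases on the model variables are z-scored (so all estimates are
#' standardized), each regression equation is estimated by ordinary least
#' squares, exogenous covariances are the sample correlations, and the
#' overall chi-square is the normal-theory ML discrepancy between the
#' sample and model-implied covariance matrices.  For a recursive model
#' with uncorrelated residuals these OLS estimates are the maximum
#' likelihood estimates.
#'
#' @param data Data frame containing every variable in `spec`.
#' @param spec A `path_spec` (see [build_path_spec()]).
#' @param standardize z-score the analysis sample first (default `TRUE`;
#'   coefficients are reported standardized).
#' @return An object of class `path_fit`: `estimates` data frame
#'   (`parameter`, `type`, `lhs`, `rhs`, `estimate`, `p_analytic`),
#'   `chi_square`, `df`, `n`, and the fitted parameter list.
#' @export
fit_path_model <- function(data, spec, standardize = TRUE) {
  if (!inherits(spec, "path_spec")) vp_stop("`spec` must be a path_spec")
  missing_cols <- setdiff(spec$variables, names(data))
  if (length(missing_cols))
    vp_stop(paste0("data lacks model variable(s): ",
                   paste(missing_cols, collapse = ", ")))
  X <- data[spec$variables]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  comp <- compile_spec(spec)
  max_k <- max(vapply(comp$endo, function(e) length(e$predictors), integer(1)))
  if (nrow(X) <= max_k + 1L)
    vp_stop(sprintf(
      "only %d complete cases for a largest equation with %d predictors",
      nrow(X), max_k))
  Z <- if (standardize) standardize_columns(X) else as.matrix(X)
  qrk <- qr(Z)
  if (qrk$rank < ncol(Z))
    vp_stop("design is rank deficient; check for collinear or constant variables")
  core <- fit_from_matrix(Z, spec, comp)
  labels <- param_labels(spec)
  est <- data.frame(
    parameter = labels,
    type = c(rep("regression", comp$n_reg), rep("covariance", comp$n_cov)),
    lhs = c(spec$regressions$response, spec$covariances$var1),
    rhs = c(spec$regressions$predictor, spec$covariances$var2),
    estimate = core$estimates,
    p_analytic = core$p_analytic,
    stringsAsFactors = FALSE
  )
  structure(list(estimates = est, params = core$params,
                 sample_cov = core$sample_cov, implied_cov = core$implied,
                 chi_square = core$chi_square, df = core$df, n = core$n,
                 spec = spec),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<path_fit> n = %d, %d regressions + %d covariances, chi^2 = %.2f (df = %d)\n",
    x$n, sum(x$estimates$type == "regression"),
    sum(x$estimates$type == "covariance"), x$chi_square, x$df))
  tab <- x$estimates
  tab$estimate <- round(tab$estimate, digits)
  tab$p_analytic <- signif(tab$p_analytic, 3)
  if (!is.null(tab$permutation_p)) tab$permutation_p <- signif(tab$permutation_p, 3)
  print(utils::head(tab[, setdiff(names(tab), c("lhs", "rhs"))], 12))
  if (nrow(tab) > 12) cat(sprintf("  ... %d more parameters\n", nrow(tab) - 12))
  invisible(x)
}

#' Simulate data from a path specification with known coefficients
#'
#' Builds the model-implied covariance for the supplied standardized
#' coefficients (residual variances chosen so every variable has unit
#' variance) and draws multivariate normal data from it.  Used for
#' parameter-recovery and calibration tests.
#'
#' @param spec A `path_spec`.
#' @param coefficients Numeric vector ordered as `spec$regressions`.
#' @param n Number of rows.
#' @param covariances Exogenous correlations ordered as `spec$covariances`
#'   (default all zero).
#' @param seed Optional integer seed.
#' @return Data frame of `n` rows with the spec's variables.
#' @export
simulate_path_data <- function(spec, coefficients, n, covariances = NULL,
                               seed = NULL) {
  comp <- compile_spec(spec)
  if (length(coefficients) != comp$n_reg)
    vp_stop("`coefficients` length does not match the spec")
  if (is.null(covariances)) covariances <- rep(0, comp$n_cov)
  ## residual variances giving unit total variance, filled in causal order
  topo <- assert_acyclic(spec)
  variances <- stats::setNames(rep(1, comp$p), comp$vars)
  params <- list(coefficients = coefficients, covariances = covariances,
                 variances = variances)
  for (v in topo) {
    if (spec$roles[[v]] == "exogenous" ||
        !v %in% names(comp$endo)) next
    Sigma <- implied_covariance(params, spec)
    eq <- comp$endo[[v]]
    b <- coefficients[comp$slots[[match(v, names(comp$endo))]]]
    expl <- drop(t(b) %*% Sigma[eq$predictors, eq$predictors] %*% b)
    if (expl >= 1)
      vp_stop(sprintf("explained variance of `%s` is >= 1; shrink coefficients", v))
    params$variances[[v]] <- 1 - expl
  }
  Sigma <- implied_covariance(params, spec)
  if (!is.null(seed)) set.seed(seed)
  L <- chol(Sigma)
  Z <- matrix(stats::rnorm(n * comp$p), n, comp$p)
  out <- as.data.frame(Z %*% L)
  names(out) <- comp$vars
  out
}
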