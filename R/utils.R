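#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#'
#' All user-facing validation failures raise a condition of class
#' `voxpath_error` (plus a subclass) so callers and the CLI can map them to
#' exit codes.
#' @noRd
vp_stop <- function(msg, class = "voxpath_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "voxpath_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

assert_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    vp_stop(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}

assert_positive_scalar <- function(x, name) {
  assert_finite_scalar(x, name)
  if (x <= 0) vp_stop(sprintf("`%s` must be strictly positive (got %g)", name, x))
  invisible(x)
}

## round-half-away-from-zero; base round() is banker's rounding
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

## Derive independent substream seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  rng <- local({
    set.seed(as.integer(seed) %% .Machine$integer.max)
    sample.int(.Machine$integer.max - 1L, n)
  })
  rng
}

## z-score columns; constant columns rejected (caller supplies context)
standardize_columns <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(!is.finite(sds)) || any(sds <= 0))
    vp_stop(sprintf(
      "cannot standardize constant or non-finite column(s): %s",
      paste(colnames(x)[!is.finite(sds) | sds <= 0], collapse = ", ")
    ))
  scale(x, center = TRUE, scale = sds)
}

## Nearest positive-definite repair of a correlation matrix by eigenvalue
## clipping, followed by rescaling to unit diagonal.  Returns the input
## untouched when already PD beyond `eps`.
nearest_pd_correlation <- function(R, eps = 1e-6) {
  stopifnot(isSymmetric(unname(R)))
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(list(mat = R, repaired = FALSE,
                                        min_eigenvalue = min(e$values)))
  lam <- pmax(e$values, eps)
  M <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  dimnames(M) <- dimnames(R)
  list(mat = M, repaired = TRUE, min_eigenvalue = min(e$values))
}

## Format numbers with 12 significant digits for CSV output.
format_sig12 <- function(x) {
  if (is.numeric(x)) signif(x, 12) else x
}
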