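## Path model specification: a recursive (acyclic) system of regressions
## among observed variables plus free covariances among the exogenous block.

#' Construct a path model specification
#'
#' Low-level constructor.  Most users want [build_path_spec()], which
#' returns the default vocal-attractiveness model; this constructor is for
#' toy or custom specifications.
#'
#' @param variables Character vector of variable names (column names of the
#'   analysis table), in a valid causal ordering.
#' @param roles Named character vector mapping each variable to one of
#'   `"exogenous"`, `"mediator"`, `"outcome"`, `"final"`.
#' @param regressions Data frame with columns `response`, `predictor`
#'   (directed edges predictor -> response).
#' @param covariances Data frame with columns `var1`, `var2` (free
#'   covariances among exogenous variables).
#' @param mediator_basis `"F0"` or `"VTL"` (informational).
#' @param groups Optional grouping variable name (e.g. `"sex"`).
#' @return An object of class `path_spec`.
#' @export
path_spec <- function(variables, roles, regressions,
                      covariances = NULL, mediator_basis = NA_character_,
                      groups = NULL) {
  if (anyDuplicated(variables)) vp_stop("duplicate variable names")
  if (!all(names(roles) %in% variables) || !all(variables %in% names(roles)))
    vp_stop("`roles` must name every variable exactly once")
  if (!all(roles %in% c("exogenous", "mediator", "outcome", "final")))
    vp_stop("invalid role(s)")
  regressions <- as.data.frame(regressions, stringsAsFactors = FALSE)
  if (!all(c("response", "predictor") %in% names(regressions)))
    vp_stop("`regressions` needs columns response, predictor")
  if (is.null(covariances))
    covariances <- data.frame(var1 = character(), var2 = character(),
                              stringsAsFactors = FALSE)
  covariances <- as.data.frame(covariances, stringsAsFactors = FALSE)
  all_named <- c(regressions$response, regressions$predictor,
                 covariances$var1, covariances$var2)
  if (!all(all_named %in% variables))
    vp_stop(paste0("edge references unknown variable(s): ",
                   paste(setdiff(all_named, variables), collapse = ", ")))
  if (any(roles[regressions$response] == "exogenous"))
    vp_stop("exogenous variables cannot be regression responses")
  if (any(roles[covariances$var1] != "exogenous" |
          roles[covariances$var2] != "exogenous"))
    vp_stop("free covariances are only allowed among exogenous variables")
  spec <- structure(list(
    variables = variables,
    roles = roles[variables],
    regressions = regressions,
    covariances = covariances,
    mediator_basis = mediator_basis,
    groups = groups
  ), class = "path_spec")
  assert_acyclic(spec)
  spec
}

## topological order of the regression graph; errors on a cycle
assert_acyclic <- function(spec) {
  vars <- spec$variables
  incoming <- lapply(stats::setNames(vars, vars), function(v)
    spec$regressions$predictor[spec$regressions$response == v])
  order <- character(0)
  remaining <- vars
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v)
      all(incoming[[v]] %in% order), logical(1))]
    if (!length(ready))
      vp_stop("regression graph contains a cycle; the model must be recursive")
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  invisible(order)
}

#' Build the default vocal-attractiveness path specification
#'
#' The default observed-variable model links four exogenous body/demographic
#' variables (age, height, weight, and a body-shape ratio: waist-to-shoulder
#' for men, waist-to-hip for women), four mediating acoustic qualities
#' (speech and singing mean F0 -- or apparent VTL -- and speech and singing
#' F0 range), the two attractiveness outcomes (speech and singing), and the
#' total sociosexuality score:
#'
#' * each of the 4 mediators is regressed on all 4 exogenous variables
#'   (16 edges);
#' * each attractiveness score is regressed on all 4 mediators and all 4
#'   exogenous variables (16 edges);
#' * the sociosexuality total is regressed on the 4 mediators and both
#'   attractiveness scores (6 edges);
#' * the 6 pairwise covariances among the exogenous variables are free.
#'
#' Totals: 38 regression coefficients + 6 covariances; residual covariances
#' among mediators and among outcomes are fixed at zero, which is what makes
#' the two-group path-invariance test carry 44 constrained parameters.
#'
#' @param mediator_basis `"F0"` (speech/singing mean F0 in semitones) or
#'   `"VTL"` (speech/singing apparent vocal tract length in cm); F0 range
#'   mediators are included either way.
#' @param ratio_kind `"WSR"` (waist-to-shoulder, column `wsr`) or `"WHR"`
#'   (waist-to-hip, column `whr`).
#' @return A `path_spec` with 38 regressions and 6 covariances.
#' @examples
#' spec <- build_path_spec("F0", "WSR")
#' nrow(spec$regressions)  # 38
#' @export
build_path_spec <- function(mediator_basis = c("F0", "VTL"),
                            ratio_kind = c("WSR", "WHR")) {
  mediator_basis <- match.arg(mediator_basis)
  ratio_kind <- match.arg(ratio_kind)
  ratio_var <- if (ratio_kind == "WSR") "wsr" else "whr"
  exog <- c("age", "height_cm", "weight_kg", ratio_var)
  mediators <- if (mediator_basis == "F0")
    c("speech_f0_st", "singing_f0_st", "speech_range_st", "singing_range_st")
  else
    c("speech_vtl_cm", "singing_vtl_cm", "speech_range_st", "singing_range_st")
  outcomes <- c("attract_speech", "attract_singing")
  final <- "soi_total"
  variables <- c(exog, mediators, outcomes, final)
  roles <- stats::setNames(
    c(rep("exogenous", 4L), rep("mediator", 4L), rep("outcome", 2L), "final"),
    variables)
  regressions <- rbind(
    expand.grid(response = mediators, predictor = exog,
                stringsAsFactors = FALSE),
    expand.grid(response = outcomes, predictor = c(mediators, exog),
                stringsAsFactors = FALSE),
    expand.grid(response = final, predictor = c(mediators, outcomes),
                stringsAsFactors = FALSE)
  )
  pairs <- utils::combn(exog, 2L)
  covariances <- data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ],
                            stringsAsFactors = FALSE)
  path_spec(variables, roles, regressions, covariances,
            mediator_basis = mediator_basis)
}

#' @export
print.path_spec <- function(x, ...) {
  cat(sprintf(
    "<path_spec> %d variables, %d regressions, %d covariances (basis: %s)\n",
    length(x$variables), nrow(x$regressions), nrow(x$covariances),
    x$mediator_basis))
  rolecount <- table(x$roles)
  cat("  roles:", paste(sprintf("%s=%d", names(rolecount), rolecount),
                        collapse = ", "), "\n")
  invisible(x)
}

## Canonical parameter labels: regressions then covariances.
param_labels <- function(spec) {
  reg <- if (nrow(spec$regressions))
    paste0(spec$regressions$response, "~", spec$regressions$predictor)
  else character(0)
  cov <- if (nrow(spec$covariances))
    paste0(spec$covariances$var1, "~~", spec$covariances$var2)
  else character(0)
  c(reg, cov)
}

#' Read a path specification from a YAML file
#'
#' Expects keys `variables` (name -> role mapping), `regressions`
#' (list of `response: [predictors]`), and optionally `covariances`
#' (list of two-element pairs) and `mediator_basis`.
#'
#' @param path Path to a YAML file.
#' @return A `path_spec`.
#' @export
read_path_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$variables)) vp_stop("model spec YAML lacks `variables`")
  roles <- unlist(y$variables)
  variables <- names(roles)
  regs <- do.call(rbind, lapply(names(y$regressions), function(resp)
    data.frame(response = resp, predictor = unlist(y$regressions[[resp]]),
               stringsAsFactors = FALSE)))
  covs <- if (!is.null(y$covariances))
    do.call(rbind, lapply(y$covariances, function(p)
      data.frame(var1 = p[[1L]], var2 = p[[2L]], stringsAsFactors = FALSE)))
  path_spec(variables, roles, regs, covs,
            mediator_basis = y$mediator_basis %||% NA_character_)
}
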