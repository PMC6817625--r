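## CSV/JSON/YAML input-output.  Dialect: UTF-8 (BOM tolerated), comma
## separator, dot decimal, mandatory header; numbers serialized with 12
## significant digits.

read_csv_utf8 <- function(path) {
  if (!file.exists(path)) vp_stop(sprintf("input file not found: %s", path))
  utils::read.csv(path, fileEncoding = "UTF-8-BOM",
                  stringsAsFactors = FALSE)
}

#' Write a data frame as CSV with 12 significant digits
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv12 <- function(x, path) {
  x2 <- as.data.frame(lapply(x, function(col)
    if (is.double(col)) signif(col, 12) else col),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(x2) <- names(x)
  utils::write.csv(x2, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a recordings table
#' @param path Path to `recordings.csv`.
#' @return Validated data frame of acoustic records.
#' @export
read_recordings <- function(path) {
  validate_acoustic_records(read_csv_utf8(path))
}

#' Read and validate a cohort table
#' @param path Path to `cohort.csv`.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path) {
  x <- read_csv_utf8(path)
  needed <- c("person_id", "sex", "country", "age", "height_cm", "weight_kg",
              "soi_total")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols))
    vp_stop(paste0("cohort table is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
  dup <- duplicated(x$person_id)
  if (any(dup))
    vp_stop(paste0("duplicate person_id(s): ",
                   paste(unique(x$person_id[dup]), collapse = ", ")))
  if (!all(x$sex %in% c("M", "F")))
    vp_stop("cohort `sex` must be 'M' or 'F'")
  x
}

#' Read and validate a long-format ratings table
#' @param path Path to `ratings.csv`.
#' @return Validated long ratings data frame.
#' @export
read_ratings <- function(path) {
  validate_ratings_long(read_csv_utf8(path))
}

#' Build a pipeline configuration
#'
#' @param recordings,cohort,ratings Paths to the three input CSVs.
#' @param out_dir Output directory.
#' @param mediator_basis `"F0"` or `"VTL"`.
#' @param B Number of permutation replicates (default 10000).
#' @param alpha Significance level for permutation/jackknife calls
#'   (default 0.05).
#' @param seed Master seed.
#' @param permutation_scheme `"columns"` or `"joint"`.
#' @param jackknife Run the leave-one-out stability pass (default `TRUE`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(recordings, cohort, ratings, out_dir,
                            mediator_basis = c("F0", "VTL"),
                            B = 10000, alpha = 0.05, seed = 1L,
                            permutation_scheme = c("columns", "joint"),
                            jackknife = TRUE) {
  mediator_basis <- match.arg(mediator_basis)
  permutation_scheme <- match.arg(permutation_scheme)
  if (B < 1) vp_stop("`B` must be >= 1")
  if (alpha <= 0 || alpha >= 1) vp_stop("`alpha` must be in (0, 1)")
  structure(list(recordings = recordings, cohort = cohort,
                 ratings = ratings, out_dir = out_dir,
                 mediator_basis = mediator_basis, B = as.integer(B),
                 alpha = alpha, seed = as.integer(seed),
                 permutation_scheme = permutation_scheme,
                 jackknife = isTRUE(jackknife)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path Path to a YAML config; relative input paths are resolved
#'   against the config file's directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) vp_stop(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  pipeline_config(
    recordings = resolve(y$recordings %||% "recordings.csv"),
    cohort = resolve(y$cohort %||% "cohort.csv"),
    ratings = resolve(y$ratings %||% "ratings.csv"),
    out_dir = resolve(y$out_dir %||% "results"),
    mediator_basis = y$mediator_basis %||% "F0",
    B = y$B %||% 10000,
    alpha = y$alpha %||% 0.05,
    seed = y$seed %||% 1L,
    permutation_scheme = y$permutation_scheme %||% "columns",
    jackknife = y$jackknife %||% TRUE
  )
}

vp_log <- function(stage, msg, verbose = TRUE) {
  if (verbose)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}
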