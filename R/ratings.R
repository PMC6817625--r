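## Rater-by-target attractiveness matrices: reliability, aggregation, and
## cross-sample agreement.

#' Construct a rating matrix
#'
#' Wraps a raters x targets grid of integer attractiveness scores on a
#' bounded scale (default 1-7) together with rater metadata.
#'
#' @param scores Numeric matrix, raters in rows, targets in columns; every
#'   cell filled and within `scale_bounds`.
#' @param rater_country Optional character vector (one per rater), e.g.
#'   `"BR"`/`"CZ"`.
#' @param display `"speech"` or `"singing"`.
#' @param scale_bounds Integer bounds of the rating scale, default `c(1, 7)`.
#' @return An object of class `rating_matrix`.
#' @export
rating_matrix <- function(scores, rater_country = NULL,
                          display = c("speech", "singing"),
                          scale_bounds = c(1L, 7L)) {
  display <- match.arg(display)
  scores <- as.matrix(scores)
  if (any(!is.finite(scores)))
    vp_stop("rating matrix contains missing or non-finite cells")
  if (any(scores < scale_bounds[1L] | scores > scale_bounds[2L]))
    vp_stop(sprintf("scores outside the %d-%d scale", scale_bounds[1L],
                    scale_bounds[2L]))
  if (any(scores != round(scores)))
    vp_stop("scores must be integers")
  if (!is.null(rater_country) && length(rater_country) != nrow(scores))
    vp_stop("`rater_country` must have one entry per rater (row)")
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("rater", seq_len(nrow(scores)))
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("target", seq_len(ncol(scores)))
  structure(list(scores = scores, rater_country = rater_country,
                 display = display, scale_bounds = scale_bounds),
            class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("<rating_matrix> %d raters x %d targets (%s, scale %d-%d)\n",
              nrow(x$scores), ncol(x$scores), x$display,
              x$scale_bounds[1L], x$scale_bounds[2L]))
  invisible(x)
}

scores_of <- function(matrix) {
  if (inherits(matrix, "rating_matrix")) matrix$scores else as.matrix(matrix)
}

#' Cronbach's alpha of a rater panel
#'
#' Interrater agreement treating raters as parallel "items" and targets as
#' observations: `alpha = k/(k-1) * (1 - sum(var_i) / var_total)` where
#' `var_i` is the variance of rater i's scores across targets and
#' `var_total` the variance of the per-target score sums (sample variances,
#' n-1 denominator).
#'
#' @param matrix A [rating_matrix()] or plain raters x targets matrix with
#'   at least 2 raters and 2 targets.
#' @return Alpha (a scalar `<= 1`).
#' @export
cronbach_alpha <- function(matrix) {
  s <- scores_of(matrix)
  k <- nrow(s)
  if (k < 2L) vp_stop("Cronbach's alpha needs at least 2 raters")
  if (ncol(s) < 2L) vp_stop("Cronbach's alpha needs at least 2 targets")
  total_var <- stats::var(colSums(s))
  if (!is.finite(total_var) || total_var <= 0)
    vp_stop("total score variance is zero; alpha is undefined",
            class = "voxpath_degenerate_error")
  item_var <- sum(apply(s, 1L, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Mean attractiveness per target
#'
#' @param matrix A [rating_matrix()] or raters x targets matrix.
#' @return Named numeric vector of per-target arithmetic means across raters.
#' @export
aggregate_target_means <- function(matrix) {
  s <- scores_of(matrix)
  if (nrow(s) == 0L || ncol(s) == 0L) vp_stop("empty rating matrix")
  colMeans(s)
}

#' Agreement between two rater samples
#'
#' Pearson correlation between the per-target mean ratings of two rater
#' samples over the identical target set, with a Fisher-z confidence
#' interval, as used to justify pooling rater countries.
#'
#' @param means_a,means_b Named numeric vectors of per-target means on the
#'   same targets (names checked when present), length >= 4.
#' @param conf Confidence level (default 0.95).
#' @return A `correlation_result` (see [pearson_with_ci()]).
#' @export
cross_sample_agreement <- function(means_a, means_b, conf = 0.95) {
  if (length(means_a) != length(means_b))
    vp_stop("mean vectors differ in length")
  if (!is.null(names(means_a)) && !is.null(names(means_b)) &&
      !identical(names(means_a), names(means_b)))
    vp_stop("target sets are misaligned between the two rater samples")
  if (length(means_a) < 4L)
    vp_stop("need at least 4 aligned targets")
  pearson_with_ci(means_a, means_b, conf = conf)
}

#' Reliability per rating block
#'
#' Computes Cronbach's alpha separately for each block (recording type x
#' rater set) of a long-format ratings table.
#'
#' @param ratings Long data frame with columns `rater_id`, `rater_country`,
#'   `target_id`, `display`, `score`.
#' @param by Character vector of blocking columns (default
#'   `c("display", "rater_country")`).
#' @return Data frame with `block`, `alpha`, `k_raters`, `n_targets`.
#' @export
reliability_by_block <- function(ratings, by = c("display", "rater_country")) {
  validate_ratings_long(ratings)
  blocks <- split(ratings, interaction(ratings[by], drop = TRUE, sep = ":"))
  out <- list()
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    ## raters who judged different target sets (e.g. male vs. female
    ## recordings) form separate complete sub-blocks
    sig <- vapply(split(b$target_id, b$rater_id), function(t)
      paste(sort(unique(t)), collapse = "\r"), character(1))
    for (s in unique(sig)) {
      sb <- b[b$rater_id %in% names(sig)[sig == s], , drop = FALSE]
      m <- long_to_matrix(sb)
      lab <- if (length(unique(sig)) > 1L)
        paste0(nm, ":set", match(s, unique(sig))) else nm
      out[[length(out) + 1L]] <- data.frame(
        block = lab, alpha = cronbach_alpha(m),
        k_raters = nrow(m), n_targets = ncol(m), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## long -> raters x targets matrix (complete blocks only)
long_to_matrix <- function(ratings) {
  m <- stats::xtabs(score ~ rater_id + target_id, data = ratings)
  cnt <- stats::xtabs(~ rater_id + target_id, data = ratings)
  if (any(cnt != 1L))
    vp_stop("rating block is not complete (missing or duplicated rater-target cells)")
  m <- unclass(m)
  attr(m, "call") <- NULL
  m
}

validate_ratings_long <- function(ratings, scale_bounds = c(1L, 7L)) {
  needed <- c("rater_id", "rater_country", "target_id", "display", "score")
  missing_cols <- setdiff(needed, names(ratings))
  if (length(missing_cols))
    vp_stop(paste0("ratings table is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
  bad <- !is.finite(ratings$score) | ratings$score < scale_bounds[1L] |
    ratings$score > scale_bounds[2L] | ratings$score != round(ratings$score)
  if (any(bad))
    vp_stop(paste0("score outside the ", scale_bounds[1L], "-", scale_bounds[2L],
                   " scale in row(s): ", paste(which(bad), collapse = ", ")))
  bad_display <- !ratings$display %in% c("speech", "singing")
  if (any(bad_display))
    vp_stop(paste0("invalid display in row(s): ",
                   paste(which(bad_display), collapse = ", ")))
  invisible(ratings)
}

#' Aggregate a long ratings table to per-target mean attractiveness
#'
#' Pools raters (by default across countries, mirroring the pooled analysis
#' unit) and returns per target x display means.
#'
#' @param ratings Long ratings table (see [reliability_by_block()]).
#' @param per_country If `TRUE`, keep rater countries separate.
#' @return Data frame `target_id`, `display`, (`rater_country`,)
#'   `mean_rating`, `n_raters`.
#' @export
aggregate_ratings <- function(ratings, per_country = FALSE) {
  validate_ratings_long(ratings)
  keys <- if (per_country) c("target_id", "display", "rater_country")
          else c("target_id", "display")
  agg <- stats::aggregate(ratings["score"], by = ratings[keys], FUN = mean)
  n <- stats::aggregate(ratings["score"], by = ratings[keys], FUN = length)
  agg$n_raters <- n$score
  names(agg)[names(agg) == "score"] <- "mean_rating"
  agg[do.call(order, agg[keys]), , drop = FALSE]
}
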