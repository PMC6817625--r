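## Synthetic cohort, recordings, and rating-matrix generation.

#' Generate a synthetic cohort
#'
#' Draws, per sex-by-country group, body measures and vocal parameters from
#' a multivariate normal whose means/SDs come from the calibration and
#' whose correlation matrix embeds the speech-singing cross-display targets
#' (with nearest-positive-definite repair when needed).  Attractiveness and
#' the sociosexuality total are then generated from the calibration's
#' standardized structural equations plus normal noise, with the residual
#' correlation of the two attractiveness scores solved so their total
#' (latent) correlation equals the calibrated target; liking-to-sing is
#' discretized to the 1-10 scale.
#'
#' @param calib A [default_calibration()]-style `cohort_calibration`.
#' @param seed Integer seed (required for reproducibility).
#' @param sexes Subset of `c("M", "F")` to generate.
#' @param n_total Optional named vector (e.g. `c(M = 73)`) overriding the
#'   total n per sex, split across countries proportionally to the
#'   calibrated group sizes.
#' @return Data frame in the cohort schema: `person_id`, `sex`, `country`,
#'   `age`, `height_cm`, `weight_kg`, `wsr`, `whr`, the six vocal
#'   parameters, `attract_speech`, `attract_singing`, `soi_total`,
#'   `liking_to_sing`.
#' @export
generate_cohort <- function(calib, seed, sexes = c("M", "F"),
                            n_total = NULL) {
  if (!inherits(calib, "cohort_calibration"))
    vp_stop("`calib` must be a cohort_calibration")
  if (missing(seed)) vp_stop("`seed` is required")
  set.seed(as.integer(seed))
  out <- list()
  for (s in sexes) {
    rep <- calibration_correlation(calib, s)
    R <- rep$mat
    gs <- calib$groups[calib$groups$sex == s, , drop = FALSE]
    ns <- gs$n
    if (!is.null(n_total) && s %in% names(n_total)) {
      tot <- n_total[[s]]
      ns <- floor(tot * gs$n / sum(gs$n))
      rem <- tot - sum(ns)
      if (rem > 0) ns[seq_len(rem)] <- ns[seq_len(rem)] + 1L
    }
    lat <- latent_attract_correlation(calib, s)
    for (gi in seq_len(nrow(gs))) {
      g <- gs[gi, ]
      n <- ns[[gi]]
      if (n < 1L) next
      sds <- c(g$age_sd, g$height_sd, g$weight_sd, g$ratio_sd,
               g$f0_speech_sd, g$f0_singing_sd,
               g$range_speech_sd, g$range_singing_sd,
               g$vtl_speech_sd, g$vtl_singing_sd)
      mus <- c(g$age_mean, g$height_mean, g$weight_mean, g$ratio_mean,
               g$f0_speech_mean, g$f0_singing_mean,
               g$range_speech_mean, g$range_singing_mean,
               g$vtl_speech_mean, g$vtl_singing_mean)
      Sigma <- diag(sds) %*% R %*% diag(sds)
      X <- MASS::mvrnorm(n, mu = mus, Sigma = Sigma)
      colnames(X) <- MVN_VARS
      Z <- sweep(sweep(X, 2L, mus), 2L, sds, "/")  # z within group params
      colnames(Z) <- MVN_VARS

      ## attractiveness: structural part + residuals with the solved
      ## residual correlation; scaled to the calibrated mean/SD
      a_sp_model <- structural_part(Z, calib$structural[[s]]$attract_speech)
      a_si_model <- structural_part(Z, calib$structural[[s]]$attract_singing)
      e <- MASS::mvrnorm(n, mu = c(0, 0),
                         Sigma = matrix(c(lat$resid_var_sp,
                                          lat$resid_cov, lat$resid_cov,
                                          lat$resid_var_si), 2L))
      a_sp_z <- a_sp_model + e[, 1L]
      a_si_z <- a_si_model + e[, 2L]
      attract_speech <- g$attract_speech_mean + g$attract_speech_sd * a_sp_z
      attract_singing <- g$attract_singing_mean + g$attract_singing_sd * a_si_z

      Zfull <- cbind(Z, attract_speech = a_sp_z, attract_singing = a_si_z)
      soi_b <- calib$structural[[s]]$soi_total
      soi_model <- structural_part(Zfull, soi_b)
      soi_var <- stats::var(soi_model)
      soi_z <- soi_model + stats::rnorm(n, 0, sqrt(max(1e-6, 1 - min(0.9, soi_var))))
      soi_total <- pmax(9, pmin(81, g$soi_mean + g$soi_sd * soi_z))

      lk_b <- calib$liking_structural[[s]]
      lk_z <- structural_part(Zfull, lk_b) +
        stats::rnorm(n, 0, sqrt(1 - min(0.9, sum(lk_b^2))))
      liking <- pmin(10L, pmax(1L,
        as.integer(round_half_away(g$liking_mean + g$liking_sd * lk_z))))

      out[[length(out) + 1L]] <- data.frame(
        person_id = sprintf("%s_%s_%03d", s, g$country, seq_len(n)),
        sex = s, country = g$country,
        age = X[, "age"], height_cm = X[, "height_cm"],
        weight_kg = X[, "weight_kg"],
        wsr = if (s == "M") X[, "ratio"] else NA_real_,
        whr = if (s == "F") X[, "ratio"] else NA_real_,
        speech_f0_st = X[, "speech_f0_st"],
        singing_f0_st = X[, "singing_f0_st"],
        speech_range_st = X[, "speech_range_st"],
        singing_range_st = X[, "singing_range_st"],
        speech_vtl_cm = X[, "speech_vtl_cm"],
        singing_vtl_cm = X[, "singing_vtl_cm"],
        attract_speech = attract_speech,
        attract_singing = attract_singing,
        soi_total = soi_total,
        liking_to_sing = liking,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "pd_repaired") <- vapply(sexes, function(s)
    calibration_correlation(calib, s)$repaired, logical(1))
  res
}

structural_part <- function(Z, b) {
  if (is.null(b) || !length(b)) return(numeric(nrow(Z)))
  drop(Z[, names(b), drop = FALSE] %*% b)
}

## Latent attractiveness correlation and residual (co)variances for one
## sex.  The printed cross-display attractiveness correlation refers to
## mean ratings; the latent target is therefore inflated by the pooled
## panel reliability (Spearman-Brown), and the residual correlation is
## solved so the latent total correlation hits that target.
latent_attract_correlation <- function(calib, sex) {
  target_obs <- calib$cross_display[[sex]][["attract"]]
  rel <- panel_reliability(calib, sex)
  target_lat <- target_obs / rel
  if (target_lat >= 1)
    vp_stop("attractiveness correlation target infeasible after disattenuation")
  R <- calibration_correlation(calib, sex)$mat
  b_sp <- calib$structural[[sex]]$attract_speech
  b_si <- calib$structural[[sex]]$attract_singing
  quad <- function(b1, b2) {
    if (!length(b1) || !length(b2)) return(0)
    drop(t(b1) %*% R[names(b1), names(b2), drop = FALSE] %*% b2)
  }
  v_sp <- quad(b_sp, b_sp); v_si <- quad(b_si, b_si)
  cov_model <- quad(b_sp, b_si)
  if (v_sp >= 1 || v_si >= 1)
    vp_stop("attractiveness structural coefficients explain >= 100% variance")
  resid_var_sp <- 1 - v_sp; resid_var_si <- 1 - v_si
  rho_e <- (target_lat - cov_model) / sqrt(resid_var_sp * resid_var_si)
  if (abs(rho_e) >= 1)
    vp_stop(sprintf(
      "residual attractiveness correlation infeasible (needed %.3f)", rho_e))
  list(target_latent = target_lat, reliability = rel,
       resid_var_sp = resid_var_sp, resid_var_si = resid_var_si,
       resid_cov = rho_e * sqrt(resid_var_sp * resid_var_si))
}

#' Generate a rater-by-target rating matrix with a target reliability
#'
#' Each rating is `clip(round(true_score + rater_effect + noise))` on the
#' bounded integer scale.  The noise SD is solved numerically (common
#' random numbers inside the solver) so that the expected Cronbach's alpha
#' of the panel equals `target_alpha`; rounding and clipping are part of
#' the solved system, not an afterthought.
#'
#' @param true_scores Named numeric vector of per-target true scores on the
#'   rating scale (e.g. latent mean attractiveness), >= 2 targets with
#'   nonzero variance.
#' @param n_raters Number of raters (>= 2).
#' @param target_alpha Desired panel alpha in (0, 1).
#' @param seed Integer seed.
#' @param scale_bounds Integer scale bounds, default `c(1, 7)`.
#' @param rater_sd SD of the per-rater leniency effect (default 0.3).
#' @param display Display label carried on the result.
#' @param rater_country Optional per-rater country labels.
#' @return A [rating_matrix()].
#' @export
generate_rating_matrix <- function(true_scores, n_raters, target_alpha,
                                   seed, scale_bounds = c(1L, 7L),
                                   rater_sd = 0.3,
                                   display = c("speech", "singing"),
                                   rater_country = NULL) {
  display <- match.arg(display)
  if (length(true_scores) < 2L || stats::sd(true_scores) == 0)
    vp_stop("need >= 2 targets with nonzero true-score variance")
  if (n_raters < 2L) vp_stop("need >= 2 raters")
  if (target_alpha <= 0 || target_alpha >= 1)
    vp_stop("`target_alpha` must be in (0, 1)")
  sigma_e <- solve_rating_noise(true_scores, n_raters, target_alpha,
                                scale_bounds, rater_sd)
  set.seed(as.integer(seed))
  m <- draw_rating_matrix(true_scores, n_raters, sigma_e, scale_bounds,
                          rater_sd)
  rating_matrix(m, rater_country = rater_country, display = display,
                scale_bounds = scale_bounds)
}

draw_rating_matrix <- function(true_scores, k, sigma_e, scale_bounds,
                               rater_sd) {
  t_len <- length(true_scores)
  u <- stats::rnorm(k, 0, rater_sd)
  noise <- matrix(stats::rnorm(k * t_len, 0, sigma_e), k, t_len)
  raw <- matrix(true_scores, k, t_len, byrow = TRUE) + u + noise
  m <- pmin(pmax(round_half_away(raw), scale_bounds[1L]), scale_bounds[2L])
  rownames(m) <- paste0("rater", seq_len(k))
  colnames(m) <- names(true_scores) %||% paste0("target", seq_len(t_len))
  m
}

## Memoized by (k, alpha, scale, rounded mean/SD of the true scores): the
## expected alpha depends on the true scores only through their location
## and spread, and each solve runs a deterministic internal simulation.
.rating_noise_cache <- new.env(parent = emptyenv())

## Solve the noise SD so the expected alpha (including rounding/clipping)
## matches the target; uses a fixed internal RNG stream so the objective is
## deterministic and monotone in sigma_e.
solve_rating_noise <- function(true_scores, k, target_alpha, scale_bounds,
                               rater_sd, n_rep = 20L) {
  ## the expected alpha depends on the true scores only through their
  ## location and spread; solve on a deterministic representative vector
  ## (normal quantiles at the binned mean/SD) so the answer is cacheable
  mu_bin <- round(mean(true_scores) * 4) / 4
  sd_bin <- round(stats::sd(true_scores) * 20) / 20
  rep_scores <- mu_bin + sd_bin * stats::qnorm(stats::ppoints(60L))
  key <- paste(k, target_alpha, paste(scale_bounds, collapse = "-"),
               rater_sd, mu_bin, sd_bin, sep = "|")
  if (!is.null(.rating_noise_cache[[key]]))
    return(.rating_noise_cache[[key]])
  expected_alpha <- function(log_sigma) {
    sigma <- exp(log_sigma)
    vals <- vapply(seq_len(n_rep), function(r) {
      ## common random numbers: reproducible local stream
      m <- withr_seed(1000L + r, draw_rating_matrix(rep_scores, k, sigma,
                                                    scale_bounds, rater_sd))
      tryCatch(cronbach_alpha(m), error = function(e) NA_real_)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  lo <- log(0.02); hi <- log(12)
  if (expected_alpha(lo) < target_alpha)
    vp_stop(sprintf(
      "alpha target %.2f infeasible for %d raters on this scale",
      target_alpha, k))
  root <- stats::uniroot(function(ls) expected_alpha(ls) - target_alpha,
                         lower = lo, upper = hi, tol = 1e-3)
  .rating_noise_cache[[key]] <- exp(root$root)
  exp(root$root)
}

## evaluate `expr` under a temporary seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Simulate a full synthetic study
#'
#' Generates, from one master seed, (1) a cohort table, (2) per-recording
#' acoustic measurements back-synthesized from each person's profile (two
#' recordings per person and display, with formants consistent with the
#' person's VTL via the uniform-tube relation plus small measurement
#' jitter), and (3) long-format opposite-sex rating tables for speech and
#' singing whose per-block reliability targets the calibrated alpha.
#' All randomness flows from named substreams of `seed`.
#'
#' @param calib A `cohort_calibration`.
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, writes `cohort.csv`,
#'   `recordings.csv`, `ratings.csv`.
#' @return List with `cohort`, `recordings`, `ratings` (invisible when
#'   writing).
#' @export
simulate_study <- function(calib = default_calibration(), seed = 1L,
                           out_dir = NULL) {
  seeds <- derive_seeds(seed, 4L)
  cohort <- generate_cohort(calib, seed = seeds[[1L]])
  recordings <- synthesize_recordings(cohort, calib, seed = seeds[[2L]])
  ratings <- synthesize_ratings(cohort, calib, seed = seeds[[3L]])
  res <- list(cohort = cohort, recordings = recordings, ratings = ratings)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv12(cohort, file.path(out_dir, "cohort.csv"))
    write_csv12(recordings, file.path(out_dir, "recordings.csv"))
    write_csv12(ratings, file.path(out_dir, "ratings.csv"))
    return(invisible(res))
  }
  res
}

## two recordings per person x display; F0 stats and uniform-tube formants
## consistent with the person's profile plus jitter
synthesize_recordings <- function(cohort, calib, seed) {
  set.seed(as.integer(seed))
  c_sound <- calib$speed_of_sound_cm_s
  items <- list(speech = c("self-presentation", "anthem-spoken"),
                singing = c("birthday-song", "anthem-sung"))
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    for (display in c("speech", "singing")) {
      f0_st <- if (display == "speech") p$speech_f0_st else p$singing_f0_st
      rng_st <- if (display == "speech") p$speech_range_st else p$singing_range_st
      vtl <- if (display == "speech") p$speech_vtl_cm else p$singing_vtl_cm
      for (item in items[[display]]) {
        st_rec <- f0_st + stats::rnorm(1, 0, 0.5)
        rng_rec <- max(0.5, rng_st + stats::rnorm(1, 0, 1.0))
        mean_hz <- semitone_to_hz(st_rec)
        min_hz <- mean_hz * 2^(-rng_rec / 18)
        max_hz <- min_hz * 2^(rng_rec / 12)
        vtl_rec <- max(8, vtl + stats::rnorm(1, 0, 0.15))
        df <- c_sound / (2 * vtl_rec)
        formants <- (2 * 1:4 - 1) / 2 * df * (1 + stats::rnorm(4, 0, 0.01))
        formants <- sort(formants)
        rows[[length(rows) + 1L]] <- data.frame(
          recording_id = sprintf("%s_%s_%s", p$person_id, display, item),
          person_id = p$person_id, display = display, item = item,
          mean_f0_hz = mean_hz, min_f0_hz = min_hz, max_f0_hz = max_hz,
          f1_hz = formants[1L], f2_hz = formants[2L],
          f3_hz = formants[3L], f4_hz = formants[4L],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

## opposite-sex rating panels in long format, one block per
## target-sex x rater-country x display
synthesize_ratings <- function(cohort, calib, seed) {
  seeds <- derive_seeds(seed, 8L)
  si <- 0L
  long <- list()
  for (s in unique(cohort$sex)) {
    targets <- cohort[cohort$sex == s, ]
    for (display in c("speech", "singing")) {
      true <- stats::setNames(
        if (display == "speech") targets$attract_speech
        else targets$attract_singing, targets$person_id)
      for (ctry in names(calib$rating$raters[[s]])) {
        si <- si + 1L
        k <- calib$rating$raters[[s]][[ctry]]
        rm <- generate_rating_matrix(
          true, n_raters = k, target_alpha = calib$rating$target_alpha,
          seed = seeds[[si]], scale_bounds = calib$rating$scale_bounds,
          rater_sd = calib$rating$rater_sd, display = display)
        m <- rm$scores
        long[[length(long) + 1L]] <- data.frame(
          rater_id = paste0(ctry, "_", s, "_", display, "_",
                            rep(rownames(m), times = ncol(m))),
          rater_country = ctry,
          target_id = rep(colnames(m), each = nrow(m)),
          display = display,
          score = as.integer(m),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, long)
  rownames(res) <- NULL
  res
}
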