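## End-to-end pipeline: acoustic profiles -> rating aggregation ->
## descriptive statistics -> path model inference -> invariance tests,
## with a reproducibility manifest.

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on the three input tables: builds per-person
#' vocal profiles from the recordings, aggregates attractiveness ratings
#' (pooled across rater countries) with per-block reliability, computes
#' the descriptive statistics (cross-display correlations, paired t-tests,
#' sex-by-country GLMs, liking-to-sing rank correlations), fits the path
#' model separately per sex with permutation p-values and jackknife
#' stability, and runs the sex and within-sex country invariance tests.
#'
#' Writes `profiles.csv`, `attractiveness.csv`, `reliability.csv`,
#' `stats.csv`, `pathfit.json`, `invariance.json` and `manifest.json` to
#' `config$out_dir`; on any stage failure the partial outputs are removed
#' and the error re-raised with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress (default `TRUE`).
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "pipeline_config"))
    vp_stop("`config` must be a pipeline_config")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(x, name, json = FALSE) {
    path <- file.path(out_dir, name)
    if (json) jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                   pretty = TRUE)
    else write_csv12(x, path)
    written <<- c(written, path)
    path
  }
  stage <- "read"
  res <- tryCatch({
    vp_log(stage, "reading and validating inputs", verbose)
    recordings <- read_recordings(config$recordings)
    cohort <- read_cohort(config$cohort)
    ratings <- read_ratings(config$ratings)

    stage <- "acoustics"
    vp_log(stage, "building vocal profiles", verbose)
    profiles <- build_vocal_profiles(recordings)
    emit(profiles, "profiles.csv")

    stage <- "ratings"
    vp_log(stage, "aggregating ratings", verbose)
    reliability <- reliability_by_block(ratings)
    attractiveness <- aggregate_ratings(ratings)
    emit(attractiveness, "attractiveness.csv")
    emit(reliability, "reliability.csv")

    stage <- "assemble"
    analysis <- assemble_analysis_table(cohort, profiles, attractiveness)

    stage <- "stats"
    vp_log(stage, "descriptive statistics", verbose)
    stats_tab <- pipeline_stats(analysis)
    emit(stats_tab, "stats.csv")

    stage <- "path_model"
    vp_log(stage, sprintf("fitting path models (B = %d)", config$B), verbose)
    seeds <- derive_seeds(config$seed, 4L)
    fits <- list()
    for (s in c("M", "F")) {
      dat <- analysis[analysis$sex == s, , drop = FALSE]
      spec <- sex_spec(config$mediator_basis, s)
      fit <- fit_path_model(dat, spec)
      perm <- permutation_pvalues(dat, spec, B = config$B,
                                  seed = seeds[[if (s == "M") 1L else 2L]],
                                  scheme = config$permutation_scheme)
      fit$estimates$permutation_p <- as.numeric(perm)
      if (config$jackknife) {
        jk <- jackknife_stability(dat, spec, alpha = config$alpha)
        fit$estimates$stable <- jk$stable
      }
      fits[[s]] <- fit
    }
    pathfit_json <- lapply(fits, function(f) list(
      n = f$n, chi_square = f$chi_square, df = f$df,
      parameters = f$estimates))
    emit(pathfit_json, "pathfit.json", json = TRUE)

    stage <- "invariance"
    vp_log(stage, "invariance tests", verbose)
    inv <- pipeline_invariance(analysis, config$mediator_basis)
    emit(lapply(inv, unclass_invariance), "invariance.json", json = TRUE)

    stage <- "manifest"
    manifest <- list(
      package = "voxpath",
      version = as.character(utils::packageVersion("voxpath")),
      seed = config$seed,
      B = config$B,
      alpha = config$alpha,
      mediator_basis = config$mediator_basis,
      permutation_scheme = config$permutation_scheme,
      inputs = lapply(stats::setNames(
        c(config$recordings, config$cohort, config$ratings),
        c("recordings", "cohort", "ratings")),
        function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
      n_regressions = nrow(sex_spec(config$mediator_basis, "M")$regressions),
      n_covariances = nrow(sex_spec(config$mediator_basis, "M")$covariances),
      invariance_df = inv$sex$df_diff,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, file.path(out_dir, "manifest.json"))
    list(profiles = profiles, reliability = reliability,
         attractiveness = attractiveness, analysis = analysis,
         stats = stats_tab, fits = fits, invariance = inv,
         manifest = manifest)
  }, voxpath_error = function(e) {
    unlink(written)
    vp_stop(sprintf("pipeline stage `%s` failed: %s", stage,
                    conditionMessage(e)),
            class = class(e)[[1L]])
  })
  invisible(res)
}

unclass_invariance <- function(x) {
  x[c("chi2_configural", "chi2_invariant", "chi2_diff", "df_diff", "p",
      "groups", "n_per_group")]
}

## per-sex spec: men use WSR, women WHR; the generic `body_ratio` column of
## the assembled table is copied into the spec's ratio slot
sex_spec <- function(mediator_basis, sex) {
  build_path_spec(mediator_basis, if (sex == "M") "WSR" else "WHR")
}

assemble_analysis_table <- function(cohort, profiles, attractiveness) {
  wide_prof <- stats::reshape(
    profiles[c("person_id", "display", "mean_f0_st", "f0_range_st", "vtl_cm")],
    direction = "wide", idvar = "person_id", timevar = "display")
  names(wide_prof) <- sub("^mean_f0_st\\.(\\w+)$", "\\1_f0_st", names(wide_prof))
  names(wide_prof) <- sub("^f0_range_st\\.(\\w+)$", "\\1_range_st", names(wide_prof))
  names(wide_prof) <- sub("^vtl_cm\\.(\\w+)$", "\\1_vtl_cm", names(wide_prof))
  att <- stats::reshape(attractiveness[c("target_id", "display", "mean_rating")],
                        direction = "wide", idvar = "target_id",
                        timevar = "display")
  names(att) <- sub("^mean_rating\\.(\\w+)$", "attract_\\1", names(att))
  names(att)[names(att) == "target_id"] <- "person_id"
  base_cols <- intersect(
    c("person_id", "sex", "country", "age", "height_cm", "weight_kg",
      "wsr", "whr", "soi_total", "liking_to_sing"), names(cohort))
  out <- merge(cohort[base_cols], wide_prof, by = "person_id", all.x = TRUE)
  out <- merge(out, att, by = "person_id", all.x = TRUE)
  ## one body-shape ratio per person on the sex-appropriate scale
  out$body_ratio <- ifelse(out$sex == "M",
                           out$wsr %||% NA_real_,
                           out$whr %||% NA_real_)
  if (!"wsr" %in% names(out)) out$wsr <- NA_real_
  if (!"whr" %in% names(out)) out$whr <- NA_real_
  out$wsr[out$sex == "M"] <- out$body_ratio[out$sex == "M"]
  out$whr[out$sex == "F"] <- out$body_ratio[out$sex == "F"]
  out
}

pipeline_stats <- function(analysis) {
  rows <- list()
  add <- function(analysis_name, statistic, value, df = NA_real_,
                  p = NA_real_, effect_size = NA_real_, n = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis_name, statistic = statistic, value = value,
      df = df, p = p, effect_size = effect_size, n = n,
      stringsAsFactors = FALSE)
  }
  for (s in c("M", "F")) {
    d <- analysis[analysis$sex == s, ]
    pairs <- list(f0 = c("speech_f0_st", "singing_f0_st"),
                  range = c("speech_range_st", "singing_range_st"),
                  vtl = c("speech_vtl_cm", "singing_vtl_cm"),
                  attract = c("attract_speech", "attract_singing"))
    for (nm in names(pairs)) {
      x <- d[[pairs[[nm]][1L]]]; y <- d[[pairs[[nm]][2L]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) >= 4L) {
        r <- pearson_with_ci(x[ok], y[ok])
        add(paste0("speech_singing_", nm, "_", s), "pearson_r", r$estimate,
            p = r$p, n = r$n)
      }
    }
    ok <- is.finite(d$attract_speech) & is.finite(d$attract_singing)
    if (sum(ok) >= 2L) {
      tt <- paired_t_test(d$attract_speech[ok], d$attract_singing[ok])
      add(paste0("attract_speech_vs_singing_", s), "paired_t", tt$t,
          df = tt$df, p = tt$p, n = tt$n)
    }
    if ("liking_to_sing" %in% names(d)) {
      for (disp in c("speech", "singing")) {
        x <- d$liking_to_sing; y <- d[[paste0("attract_", disp)]]
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) >= 3L) {
          k <- kendall_tau_b(x[ok], y[ok])
          add(paste0("liking_vs_attract_", disp, "_", s), "kendall_tau_b",
              k$estimate, p = k$p, n = k$n)
        }
      }
    }
  }
  for (dv in c("speech_f0_st", "singing_f0_st", "speech_range_st",
               "singing_range_st", "speech_vtl_cm", "singing_vtl_cm")) {
    ok <- is.finite(analysis[[dv]])
    a <- two_way_anova_partial_eta(analysis[[dv]][ok],
                                   analysis$sex[ok], analysis$country[ok])
    for (i in seq_len(nrow(a$table)))
      add(paste0("glm_", dv), paste0("F_", a$table$term[i]), a$table$F[i],
          df = a$table$df2[i], p = a$table$p[i],
          effect_size = a$table$partial_eta_sq[i], n = a$n)
  }
  do.call(rbind, rows)
}

pipeline_invariance <- function(analysis, mediator_basis) {
  ## sex invariance: the generic body_ratio fills the WSR slot for both
  ## sexes (each sex measured on its own ratio scale; fits standardize)
  dat <- analysis
  dat$wsr <- dat$body_ratio
  spec_m <- sex_spec(mediator_basis, "M")
  inv <- list(sex = invariance_test(dat, "sex", spec_m))
  for (s in c("M", "F")) {
    ds <- analysis[analysis$sex == s, , drop = FALSE]
    spec <- sex_spec(mediator_basis, s)
    inv[[paste0("country_", s)]] <-
      tryCatch(invariance_test(ds, "country", spec),
               voxpath_error = function(e) list(error = conditionMessage(e)))
  }
  inv
}
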