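## Acoustic transforms: semitone scale, F0 range, formant spacing, apparent
## vocal tract length, and per-person vocal profiles.

#' Convert frequency in Hz to semitones relative to a reference
#'
#' Maps a fundamental frequency to the logarithmic semitone scale,
#' `12 * log2(f0 / reference)`.  With the default reference of A4 (440 Hz)
#' the value is 0 at 440 Hz, -12 one octave below (220 Hz) and +12 one
#' octave above (880 Hz), reflecting the logarithmic nature of human pitch
#' perception.
#'
#' @param f0_hz Frequency in Hz; strictly positive, finite. Vectorized.
#' @param reference_hz Reference frequency in Hz (default 440, concert A4).
#' @return Semitone offset(s) from the reference (numeric).
#' @examples
#' hz_to_semitone(220)   # -12
#' hz_to_semitone(880)   # +12
#' @export
hz_to_semitone <- function(f0_hz, reference_hz = 440) {
  assert_positive_scalar(reference_hz, "reference_hz")
  if (!is.numeric(f0_hz) || length(f0_hz) == 0L ||
      any(!is.finite(f0_hz)) || any(f0_hz <= 0))
    vp_stop("`f0_hz` must contain only finite, strictly positive frequencies")
  12 * log2(f0_hz / reference_hz)
}

#' Convert semitones relative to a reference back to Hz
#'
#' Inverse of [hz_to_semitone()].
#' @param st Semitone offset(s), finite.
#' @param reference_hz Reference frequency in Hz (default 440).
#' @return Frequency in Hz.
#' @export
semitone_to_hz <- function(st, reference_hz = 440) {
  assert_positive_scalar(reference_hz, "reference_hz")
  if (!is.numeric(st) || any(!is.finite(st)))
    vp_stop("`st` must be finite")
  reference_hz * 2^(st / 12)
}

NOTE_NAMES <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")

#' Label a semitone offset with its musical note
#'
#' Rounds a semitone offset from A4 to the nearest integer (exact halves
#' round away from zero) and returns the note in scientific pitch notation
#' with sharps only (C, C#, ..., B); the octave number increments at C and
#' A4 = 440 Hz.
#'
#' @param st Semitone offset(s) from A4, finite. Vectorized.
#' @return Character vector of note labels, e.g. `"F#2"`.
#' @examples
#' semitone_to_note_label(0)                       # "A4"
#' semitone_to_note_label(hz_to_semitone(92.47))   # "F#2"
#' @export
semitone_to_note_label <- function(st) {
  if (!is.numeric(st) || length(st) == 0L || any(!is.finite(st)))
    vp_stop("`st` must be finite")
  n <- round_half_away(st)
  abs_st <- 57 + n               # semitones above C0 (A4 = 57)
  octave <- abs_st %/% 12
  paste0(NOTE_NAMES[(abs_st %% 12) + 1L], octave)
}

#' Perceptual F0 range in semitones
#'
#' The maximal minus the minimal F0 of a recording on the semitone scale,
#' `12 * log2(max / min)`; invariant to transposing both frequencies by a
#' common factor.
#'
#' @param min_f0_hz,max_f0_hz Minimal and maximal F0 in Hz,
#'   `0 < min_f0_hz <= max_f0_hz`. Vectorized in parallel.
#' @return Range in semitones, `>= 0`.
#' @export
f0_range_semitones <- function(min_f0_hz, max_f0_hz) {
  if (!is.numeric(min_f0_hz) || !is.numeric(max_f0_hz) ||
      length(min_f0_hz) != length(max_f0_hz))
    vp_stop("`min_f0_hz` and `max_f0_hz` must be numeric vectors of equal length")
  if (any(!is.finite(min_f0_hz)) || any(!is.finite(max_f0_hz)) ||
      any(min_f0_hz <= 0))
    vp_stop("frequencies must be finite and strictly positive")
  if (any(max_f0_hz < min_f0_hz))
    vp_stop("`max_f0_hz` must be >= `min_f0_hz`")
  12 * log2(max_f0_hz / min_f0_hz)
}

#' Estimate formant spacing (deltaF) from the first four formants
#'
#' Models the vocal tract as a uniform tube closed at one end, in which the
#' i-th formant sits at `Fi = (2i - 1) / 2 * deltaF`.  The spacing is the
#' through-origin least-squares slope of the measured formants on these
#' odd-quarter-wavelength positions, in closed form
#' `sum(x * F) / sum(x^2)` with `x = (2i - 1) / 2`.
#'
#' @param formants_hz Numeric vector of exactly 4 strictly increasing,
#'   positive median formant frequencies (F1-F4) in Hz.
#' @return Formant spacing deltaF in Hz.
#' @examples
#' estimate_delta_f(c(500, 1500, 2500, 3500))  # 1000
#' @export
estimate_delta_f <- function(formants_hz) {
  if (!is.numeric(formants_hz) || length(formants_hz) != 4L)
    vp_stop("`formants_hz` must be a numeric vector of exactly 4 formants (F1-F4)")
  if (any(!is.finite(formants_hz)) || any(formants_hz <= 0))
    vp_stop("formants must be finite and strictly positive")
  if (any(diff(formants_hz) <= 0))
    vp_stop("formants must be strictly increasing (F1 < F2 < F3 < F4)")
  x <- (2 * seq_len(4L) - 1) / 2
  sum(x * formants_hz) / sum(x^2)
}

#' Apparent vocal tract length from formant spacing
#'
#' `VTL = c / (2 * deltaF)` for a uniform tube with one end closed, where
#' `c` is the speed of sound (default 33,500 cm/s = 335 m/s).
#'
#' @param delta_f_hz Formant spacing in Hz, strictly positive. Vectorized.
#' @param speed_of_sound_cm_s Speed of sound in cm/s (default 33500).
#' @return Apparent vocal tract length in cm.
#' @examples
#' vtl_from_delta_f(1000)  # 16.75 cm
#' @export
vtl_from_delta_f <- function(delta_f_hz, speed_of_sound_cm_s = 33500) {
  assert_positive_scalar(speed_of_sound_cm_s, "speed_of_sound_cm_s")
  if (!is.numeric(delta_f_hz) || any(!is.finite(delta_f_hz)) ||
      any(delta_f_hz <= 0))
    vp_stop("`delta_f_hz` must be finite and strictly positive")
  speed_of_sound_cm_s / (2 * delta_f_hz)
}

#' Validate a table of acoustic records
#'
#' Checks the `recordings.csv` schema: per-recording F0 summaries
#' (mean/min/max in Hz) and four median formants, with
#' `min <= mean <= max` and strictly increasing formants.
#'
#' @param records Data frame with columns `recording_id`, `person_id`,
#'   `display` (`"speech"`/`"singing"`), `item`, `mean_f0_hz`, `min_f0_hz`,
#'   `max_f0_hz`, `f1_hz`, `f2_hz`, `f3_hz`, `f4_hz`.
#' @return The validated data frame, invisibly classed.
#' @export
validate_acoustic_records <- function(records) {
  needed <- c("recording_id", "person_id", "display", "item",
              "mean_f0_hz", "min_f0_hz", "max_f0_hz",
              "f1_hz", "f2_hz", "f3_hz", "f4_hz")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    vp_stop(paste0("recordings table is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
  bad_display <- !records$display %in% c("speech", "singing")
  if (any(bad_display))
    vp_stop(paste0("invalid display value(s) in row(s): ",
                   paste(which(bad_display), collapse = ", ")))
  num <- records[c("mean_f0_hz", "min_f0_hz", "max_f0_hz",
                   "f1_hz", "f2_hz", "f3_hz", "f4_hz")]
  bad <- !stats::complete.cases(num) |
    apply(num, 1L, function(r) any(!is.finite(r) | r <= 0))
  if (any(bad))
    vp_stop(paste0("non-finite or non-positive measurement(s) in row(s): ",
                   paste(which(bad), collapse = ", ")))
  bad_f0 <- records$min_f0_hz > records$mean_f0_hz |
    records$mean_f0_hz > records$max_f0_hz
  if (any(bad_f0))
    vp_stop(paste0("violated min <= mean <= max F0 in row(s): ",
                   paste(which(bad_f0), collapse = ", ")))
  fm <- as.matrix(records[c("f1_hz", "f2_hz", "f3_hz", "f4_hz")])
  bad_fm <- apply(fm, 1L, function(r) any(diff(r) <= 0))
  if (any(bad_fm))
    vp_stop(paste0("formants not strictly increasing in row(s): ",
                   paste(which(bad_fm), collapse = ", ")))
  dup <- duplicated(records$recording_id)
  if (any(dup))
    vp_stop(paste0("duplicate recording_id(s): ",
                   paste(unique(records$recording_id[dup]), collapse = ", ")))
  invisible(records)
}

#' Build one person-by-display vocal profile
#'
#' Each recording is first transformed individually -- mean F0 to semitones
#' re A4, F0 range in semitones, formant spacing deltaF -- and the
#' per-recording values are then averaged (unweighted) across recordings.
#' VTL is converted once from the averaged deltaF (`vtl_from = "mean_delta_f"`,
#' the default); setting `vtl_from = "mean_vtl"` instead averages
#' per-recording VTLs, which by convexity gives a slightly larger value.
#'
#' @param records Data frame of acoustic records for one person and one
#'   display (see [validate_acoustic_records()]).
#' @param speed_of_sound_cm_s Speed of sound in cm/s.
#' @param vtl_from `"mean_delta_f"` (default) or `"mean_vtl"`; averaging
#'   order for the VTL conversion.
#' @return One-row data frame: `person_id`, `display`, `mean_f0_st`,
#'   `f0_range_st`, `delta_f_hz`, `vtl_cm`, `n_recordings`.
#' @export
build_vocal_profile <- function(records, speed_of_sound_cm_s = 33500,
                                vtl_from = c("mean_delta_f", "mean_vtl")) {
  vtl_from <- match.arg(vtl_from)
  if (!is.data.frame(records) || nrow(records) == 0L)
    vp_stop("`records` must be a non-empty data frame of acoustic records")
  validate_acoustic_records(records)
  if (length(unique(records$person_id)) != 1L)
    vp_stop("all records must belong to a single person")
  if (length(unique(records$display)) != 1L)
    vp_stop("all records must share one display (speech or singing)")
  st <- hz_to_semitone(records$mean_f0_hz)
  rng <- f0_range_semitones(records$min_f0_hz, records$max_f0_hz)
  dfs <- apply(as.matrix(records[c("f1_hz", "f2_hz", "f3_hz", "f4_hz")]), 1L,
               estimate_delta_f)
  mean_df <- mean(dfs)
  vtl <- switch(vtl_from,
    mean_delta_f = vtl_from_delta_f(mean_df, speed_of_sound_cm_s),
    mean_vtl = mean(vtl_from_delta_f(dfs, speed_of_sound_cm_s)))
  data.frame(
    person_id = records$person_id[[1L]],
    display = records$display[[1L]],
    mean_f0_st = mean(st),
    f0_range_st = mean(rng),
    delta_f_hz = mean_df,
    vtl_cm = vtl,
    n_recordings = nrow(records),
    stringsAsFactors = FALSE
  )
}

#' Build vocal profiles for a whole recordings table
#'
#' Applies [build_vocal_profile()] to every person-by-display group.
#'
#' @inheritParams build_vocal_profile
#' @return Data frame with one row per person and display.
#' @export
build_vocal_profiles <- function(records, speed_of_sound_cm_s = 33500,
                                 vtl_from = c("mean_delta_f", "mean_vtl")) {
  vtl_from <- match.arg(vtl_from)
  validate_acoustic_records(records)
  pieces <- split(records, interaction(records$person_id, records$display,
                                       drop = TRUE))
  out <- do.call(rbind, lapply(pieces, build_vocal_profile,
                               speed_of_sound_cm_s = speed_of_sound_cm_s,
                               vtl_from = vtl_from))
  rownames(out) <- NULL
  out[order(out$person_id, out$display), , drop = FALSE]
}

#' Voice modulation indices between speech and singing
#'
#' Absolute differences between a person's singing and speaking mean F0,
#' F0 range (both semitones), and apparent VTL (cm).  The larger the
#' absolute difference, the stronger the modulation between the two vocal
#' displays; the index is symmetric in the display order.
#'
#' @param speech,singing One-row vocal profiles of the same person, one per
#'   display (as returned by [build_vocal_profile()]).
#' @return One-row data frame: `person_id`, `abs_df0_st`, `abs_drange_st`,
#'   `abs_dvtl_cm`.
#' @export
modulation_indices <- function(speech, singing) {
  for (p in list(speech, singing))
    if (!is.data.frame(p) || nrow(p) != 1L ||
        !all(c("person_id", "display", "mean_f0_st", "f0_range_st",
               "vtl_cm") %in% names(p)))
      vp_stop("`speech` and `singing` must be one-row vocal profiles")
  if (speech$person_id != singing$person_id)
    vp_stop("profiles belong to different persons")
  if (identical(speech$display, singing$display))
    vp_stop("need one profile per display")
  data.frame(
    person_id = speech$person_id,
    abs_df0_st = abs(singing$mean_f0_st - speech$mean_f0_st),
    abs_drange_st = abs(singing$f0_range_st - speech$f0_range_st),
    abs_dvtl_cm = abs(singing$vtl_cm - speech$vtl_cm),
    stringsAsFactors = FALSE
  )
}
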