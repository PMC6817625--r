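## Shared fixtures, built in code.

## one person's recordings for a given display
make_records <- function(person = "p1", display = "speech",
                         mean_f0 = c(110, 120), min_f0 = mean_f0 * 0.8,
                         max_f0 = mean_f0 * 1.4,
                         delta_f = rep(1000, length(mean_f0))) {
  k <- length(mean_f0)
  fm <- t(vapply(delta_f, function(d) (2 * 1:4 - 1) / 2 * d, numeric(4)))
  data.frame(
    recording_id = paste0(person, "_", display, "_", seq_len(k)),
    person_id = person, display = display, item = paste0("item", seq_len(k)),
    mean_f0_hz = mean_f0, min_f0_hz = min_f0, max_f0_hz = max_f0,
    f1_hz = fm[, 1], f2_hz = fm[, 2], f3_hz = fm[, 3], f4_hz = fm[, 4],
    stringsAsFactors = FALSE
  )
}

## 3-variable chain x -> m -> y
chain_spec <- function() {
  path_spec(c("x", "m", "y"),
            c(x = "exogenous", m = "mediator", y = "outcome"),
            data.frame(response = c("m", "y"), predictor = c("x", "m"),
                       stringsAsFactors = FALSE))
}

## a reduced calibration for fast pipeline tests: same structure as the
## default, smaller groups and panels
small_calibration <- function(n_per_group = 20L, raters = 6L) {
  calib <- default_calibration()
  calib$groups$n <- n_per_group
  calib$rating$raters <- list(M = c(BR = raters, CZ = raters),
                              F = c(BR = raters, CZ = raters))
  calib
}

## brute-force tau-b oracle: explicit loop over all pairs
tau_b_bruteforce <- function(x, y) {
  n <- length(x)
  conc <- disc <- tied_x <- tied_y <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0) tied_x <- tied_x + 1
    if (dy == 0) tied_y <- tied_y + 1
    if (dx != 0 && dy != 0) {
      if (dx == dy) conc <- conc + 1 else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tied_x) * (n0 - tied_y))
}
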