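#' Fixed-cycle Hanning-taper time-frequency decomposition
#'
#' Sliding-window spectral estimate with a frequency-adaptive window: at
#' frequency `f` the window spans `n_cycles / f` seconds (7 cycles by
#' default, so 0.7 s at 10 Hz), tapered with a Hanning window, and shifted
#' in `step`-second steps (5 ms). Power at `(f, t)` is the squared magnitude
#' of the tapered complex dot product centred at `t`. Time points whose
#' window would extend beyond the data edges yield `NA` — edges are never
#' silently zero-padded. When a whole frequency row has no valid time point
#' (series shorter than its window) that row is `NA` with a warning.
#'
#' For a trials x time matrix the decomposition is applied per trial and the
#' power is averaged across trials afterwards.
#'
#' @param x Numeric vector (one trial) or trials x time matrix.
#' @param fs Sampling rate (Hz).
#' @param freqs Frequency grid in Hz (default 5-40 Hz in 2.5 Hz steps).
#' @param n_cycles Cycles per window (default 7).
#' @param step Window step in seconds (default 0.005).
#' @param t0 Time of the first sample (s), default 0.
#' @return Object of class `msna_tfr`: list with `power` (freq x time,
#'   trial-averaged), `freqs`, `times`, `n_trials`.
#' @export
#' @examples
#' x <- sin(2 * pi * 20 * seq(0, 1.5, by = 1 / 200))
#' tf <- tfr_hanning(x, fs = 200, freqs = seq(10, 30, 5))
#' tf$freqs[which.max(tf$power[, 150])]
tfr_hanning <- function(x, fs, freqs = seq(5, 40, by = 2.5),
                        n_cycles = 7, step = 0.005, t0 = 0) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  n_trials <- nrow(x)
  assert_that(step > 0, "step must be positive")

  half_len <- floor(round(fs * n_cycles / freqs) / 2) # samples
  win_len <- 2 * half_len + 1
  if (max(win_len) > n) {
    too_long <- freqs[win_len > n]
    warning("series shorter than the ", n_cycles, "-cycle window at ",
            paste(too_long, collapse = ", "),
            " Hz; those frequency rows are NA")
  }

  step_samp <- step * fs
  centres <- seq(1, n, by = step_samp)
  centres_idx <- round(centres)
  times <- t0 + (centres - 1) / fs
  n_steps <- length(centres)

  N <- stats::nextn(n + max(win_len) - 1, 2)
  X <- matrix(0i, n_trials, N)
  for (tr in seq_len(n_trials)) {
    X[tr, ] <- stats::fft(c(x[tr, ], rep(0, N - n)))
  }

  power <- matrix(NA_real_, length(freqs), n_steps)
  for (fi in seq_along(freqs)) {
    h <- half_len[fi]
    L <- win_len[fi]
    if (L > n) next
    j <- -h:h
    taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
    w <- taper * exp(-1i * 2 * pi * freqs[fi] * j / fs)
    v <- rev(w)
    V <- stats::fft(c(v, rep(0i, N - L)))
    valid <- centres_idx - h >= 1 & centres_idx + h <= n
    if (!any(valid)) next
    acc <- numeric(sum(valid))
    pick <- centres_idx[valid] + h
    for (tr in seq_len(n_trials)) {
      z <- stats::fft(X[tr, ] * V, inverse = TRUE) / N
      acc <- acc + Mod(z[pick])^2
    }
    power[fi, valid] <- acc / n_trials
  }
  structure(
    list(power = power, freqs = freqs, times = times, n_trials = n_trials),
    class = "msna_tfr"
  )
}

#' Baseline-normalize a time-frequency map
#'
#' Expresses post-stimulus power as relative change against the
#' pre-stimulus interval: for each frequency, the baseline map's power is
#' averaged over trials and time (`B_f`) and the condition map becomes
#' `(P - B_f) / B_f`. Because the per-subject baseline divides out, the
#' result is invariant to any overall scaling of that subject's signal.
#'
#' @param tfr An `msna_tfr` for the condition of interest.
#' @param baseline An `msna_tfr` computed on the pre-stimulus epoch.
#' @return An `msna_tfr` whose `power` holds relative power (dimensionless).
#' @export
baseline_normalize <- function(tfr, baseline) {
  assert_that(identical(tfr$freqs, baseline$freqs),
              "condition and baseline must share the frequency grid")
  b <- rowMeans(baseline$power, na.rm = TRUE)
  assert_that(all(b > 0 | is.na(b)), "non-positive baseline power")
  out <- tfr
  out$power <- sweep(sweep(tfr$power, 1, b, "-"), 1, b, "/")
  out$baseline_power <- b
  out
}

#' Stack per-subject maps into a cohort TFR object
#'
#' @param maps List of `msna_tfr` objects (one per subject) sharing grids.
#' @param roi,condition Labels carried along for reporting.
#' @return Object of class `msna_tfr_maps`: `power` (subject x freq x time
#'   array), `freqs`, `times`, `roi`, `condition`.
#' @export
stack_tfr_maps <- function(maps, roi = NA_character_,
                           condition = NA_character_) {
  freqs <- maps[[1]]$freqs
  times <- maps[[1]]$times
  for (m in maps) {
    assert_that(identical(m$freqs, freqs) && length(m$times) == length(times),
                "all subject maps must share the time-frequency grid")
  }
  arr <- array(NA_real_, c(length(maps), length(freqs), length(times)))
  for (i in seq_along(maps)) arr[i, , ] <- maps[[i]]$power
  structure(
    list(power = arr, freqs = freqs, times = times, roi = roi,
         condition = condition),
    class = "msna_tfr_maps"
  )
}
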