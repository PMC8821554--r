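#' Detect bursts in an integrated neurogram
#'
#' Assigns one burst amplitude to every cardiac interval: the neurogram's
#' baseline is estimated by morphological opening (a rolling minimum
#' followed by a rolling maximum over `open_width` seconds, wide enough to
#' swallow a whole burst) smoothed with a rolling 10 s median to absorb
#' slow drift; the peak of the baseline-corrected signal within the reflex
#' latency window attributed to each R-wave is that interval's burst
#' amplitude. Peaks below `threshold_k` times a robust noise SD (MAD of
#' the corrected signal) count as absent bursts and get amplitude exactly
#' 0. Because each interval's amplitude is the maximum over roughly one
#' second of samples, the threshold must clear the expected extreme of the
#' noise (about 3 SD for 100 samples), so the default is 4 SD.
#'
#' @param neurogram An `msna_neurogram` (or a list with `samples`, `fs`,
#'   `r_times`).
#' @param latency_window Post-R search window in seconds (default
#'   `c(0.8, 1.8)`, bracketing the typical peroneal reflex latency).
#' @param open_width Morphological-opening window in seconds (default 0.8;
#'   must exceed the burst width).
#' @param baseline_width Rolling-median smoothing width in seconds
#'   (default 10).
#' @param threshold_k Detection threshold in robust noise SDs (default 4).
#' @return A tibble of class `msna_bursts`: `interval`, `r_time`,
#'   `amplitude` (>= 0; 0 = absent), `detected`.
#' @export
detect_bursts <- function(neurogram, latency_window = c(0.8, 1.8),
                          open_width = 0.8, baseline_width = 10,
                          threshold_k = 4) {
  x <- neurogram$samples
  fs <- neurogram$fs
  r_times <- neurogram$r_times
  assert_that(length(x) > 0, "empty recording")
  assert_that(fs >= 100, "neurogram sampling rate must be >= 100 Hz")
  assert_that(length(r_times) >= 10, "need at least 10 cardiac intervals")
  n <- length(x)
  assert_that(max(r_times) * fs <= n,
              "r_times extend beyond the sampled recording")

  w <- round(open_width * fs)
  opened <- rolling_max(rolling_min(x, w), w)
  k <- round(baseline_width * fs)
  if (k %% 2 == 0) k <- k + 1
  baseline <- stats::runmed(opened, k, endrule = "median")
  corrected <- x - baseline
  noise_sd <- stats::mad(corrected)
  thr <- threshold_k * noise_sd

  lo_off <- round(latency_window[1] * fs)
  hi_off <- round(latency_window[2] * fs)
  amp <- numeric(length(r_times))
  for (i in seq_along(r_times)) {
    c0 <- round(r_times[i] * fs) + 1
    lo <- min(max(1, c0 + lo_off), n)
    hi <- min(n, c0 + hi_off)
    peak <- max(corrected[lo:hi])
    amp[i] <- if (peak > thr) peak else 0
  }
  out <- tibble::tibble(interval = seq_along(r_times), r_time = r_times,
                        amplitude = amp, detected = amp > 0)
  class(out) <- c("msna_bursts", class(out))
  out
}

#' Compute the stimulus-induced MSNA inhibition statistic
#'
#' The statistic compares the average post-stimulus burst amplitude with a
#' control period of 8 cardiac intervals immediately preceding each
#' stimulation:
#' \deqn{inhibition = 100 (1 - \bar A_{post} / \bar A_{base})}
#' where both means pool all trials (grand-mean ratio) and absent bursts
#' contribute zero amplitude. It ranges from large negative values
#' (post-stimulus bursts larger than baseline; -200% corresponds to a
#' post-stimulus mean three times baseline) up to a hard bound of +100%,
#' attained exactly when every post-stimulus burst is absent.
#'
#' The post-stimulus window defaults to the cardiac interval carrying each
#' pulse of a trial (one interval per pulse, pooled over the trial's
#' pulses); set `pulses` to restrict it, e.g. `pulses = 1` for the
#' first-pulse-only window.
#'
#' @param bursts An `msna_bursts` tibble (or any tibble with `interval` and
#'   `amplitude`).
#' @param protocol An `msna_protocol` tibble.
#' @param n_baseline Control intervals preceding each trial (default 8).
#' @param pulses Which pulses of each trial define the post-stimulus window
#'   (default all).
#' @param per_trial If `TRUE`, average per-trial ratios instead of the
#'   grand-mean ratio (provided as a sensitivity switch; the grand-mean form
#'   is robust when single trials have burst-free control windows).
#' @return A tibble of class `msna_inhibition` with one row: `inhibition`
#'   (%), `group`, `n_trials_used`, `mean_post`, `mean_base`, `unreliable`
#'   (TRUE when fewer than 5 baseline bursts support the estimate).
#' @export
#' @examples
#' bursts <- tibble::tibble(interval = 1:20,
#'                          amplitude = rep(c(2, 0), 10))
#' # a protocol-like table: one trial, pulses on intervals 9:11
#' prot <- tibble::tibble(trial = 1, pulse = 1:3, interval = c(9, 10, 11))
#' compute_inhibition(bursts, prot)$inhibition
compute_inhibition <- function(bursts, protocol, n_baseline = 8,
                               pulses = NULL, per_trial = FALSE) {
  amp <- bursts$amplitude
  n_int <- max(bursts$interval)
  stim_intervals <- unique(protocol$interval)
  prot <- if (is.null(pulses)) protocol else
    protocol[protocol$pulse %in% pulses, , drop = FALSE]

  first_pulse <- tapply(protocol$interval, protocol$trial, min)
  base_idx_by_trial <- lapply(as.integer(first_pulse), function(i0) {
    idx <- (i0 - n_baseline):(i0 - 1)
    idx[idx >= 1]
  })
  names(base_idx_by_trial) <- names(first_pulse)
  ok <- vapply(base_idx_by_trial, function(idx) {
    length(idx) == n_baseline && !any(idx %in% stim_intervals)
  }, logical(1))
  assert_that(any(ok),
              "no trial has a clean stimulus-free control period")

  post_idx_by_trial <- split(prot$interval, prot$trial)
  trials <- intersect(names(base_idx_by_trial)[ok],
                      names(post_idx_by_trial))
  base_all <- unlist(base_idx_by_trial[trials])
  post_all <- unlist(post_idx_by_trial[trials])
  post_all <- post_all[post_all <= n_int]

  if (per_trial) {
    ratios <- vapply(trials, function(tr) {
      b <- mean(amp[base_idx_by_trial[[tr]]])
      p <- mean(amp[post_idx_by_trial[[tr]]])
      if (b == 0) NA_real_ else p / b
    }, numeric(1))
    ratio <- mean(ratios, na.rm = TRUE)
    mean_base <- mean(amp[base_all])
    mean_post <- mean(amp[post_all])
  } else {
    mean_base <- mean(amp[base_all])
    mean_post <- mean(amp[post_all])
    if (mean_base == 0) {
      stop("undefined inhibition statistic: no baseline burst activity",
           call. = FALSE)
    }
    ratio <- mean_post / mean_base
  }
  inhibition <- 100 * (1 - ratio)
  out <- tibble::tibble(
    inhibition = inhibition,
    group = classify_inhibitor(inhibition),
    n_trials_used = length(trials),
    mean_post = mean_post,
    mean_base = mean_base,
    unreliable = sum(amp[base_all] > 0) < 5
  )
  class(out) <- c("msna_inhibition", class(out))
  out
}

#' Classify subjects as Inhibitors or Non-inhibitors
#'
#' Strictly-greater rule: inhibition above the threshold (default 30%, the
#' bound covering 95% of dummy-trigger variability) makes an Inhibitor;
#' exactly 30% or anything below — including strongly negative values
#' reflecting sympathetic excitation — is a Non-inhibitor.
#'
#' @param inhibition Numeric vector of inhibition values (%).
#' @param threshold Classification threshold (%); default 30.
#' @return Character vector, `"Inhibitor"` or `"Non-inhibitor"`.
#' @export
#' @examples
#' classify_inhibitor(c(30, 30.0001, -132, 100))
classify_inhibitor <- function(inhibition, threshold = 30) {
  assert_that(all(is.finite(inhibition)),
              "inhibition must be finite (no NaN/NA)")
  ifelse(inhibition > threshold, "Inhibitor", "Non-inhibitor")
}

#' Resting burst incidence and burst frequency
#'
#' Burst incidence (BI) is bursts per 100 heartbeats; burst frequency (BF)
#' is bursts per minute. Both are computed over stimulus-free intervals
#' only when a protocol is supplied.
#'
#' @param bursts An `msna_bursts` tibble.
#' @param cardiac The matching cardiac series.
#' @param protocol Optional protocol; its stimulated intervals (and the
#'   control windows are kept — only pulse-carrying intervals are dropped)
#'   are excluded from the resting segment.
#' @return Tibble with `burst_incidence`, `burst_frequency`, `n_bursts`,
#'   `n_beats`, `minutes`.
#' @export
resting_metrics <- function(bursts, cardiac, protocol = NULL) {
  keep <- rep(TRUE, nrow(bursts))
  if (!is.null(protocol)) keep[bursts$interval %in% protocol$interval] <- FALSE
  n_beats <- sum(keep)
  n_bursts <- sum(bursts$amplitude[keep] > 0)
  rr <- mean(diff(cardiac$r_time))
  minutes <- n_beats * rr / 60
  tibble::tibble(
    burst_incidence = 100 * n_bursts / n_beats,
    burst_frequency = n_bursts / minutes,
    n_bursts = n_bursts, n_beats = n_beats, minutes = minutes
  )
}

#' Calibrate the dummy-trigger variability bound
#'
#' Computes the inhibition statistic against dummy triggers (R-wave-timed
#' trigger schedules without stimulation) for each subject and returns the
#' symmetric bound covering 95% of subjects: the empirical 95th percentile
#' (linear interpolation) of the absolute deviations. This is the
#' calibration behind the 30% Inhibitor threshold.
#'
#' @param burst_series List of `msna_bursts` tibbles, one per subject.
#' @param dummy_protocols List of matching dummy `msna_protocol` tables.
#' @param n_baseline Control intervals (default 8).
#' @return Tibble of class `msna_dummy_cal`: `bound` (%), `n_subjects`, and
#'   list-column `deviations`.
#' @export
calibrate_dummy <- function(burst_series, dummy_protocols, n_baseline = 8) {
  assert_that(length(burst_series) == length(dummy_protocols),
              "one dummy protocol per burst series required")
  if (length(burst_series) < 5) {
    warning("dummy calibration on fewer than 5 subjects is unstable")
  }
  deviations <- vapply(seq_along(burst_series), function(i) {
    compute_inhibition(burst_series[[i]], dummy_protocols[[i]],
                       n_baseline = n_baseline)$inhibition
  }, numeric(1))
  bound <- unname(stats::quantile(abs(deviations), 0.95, type = 7))
  out <- tibble::tibble(bound = bound, n_subjects = length(deviations),
                        deviations = list(deviations))
  class(out) <- c("msna_dummy_cal", class(out))
  out
}
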