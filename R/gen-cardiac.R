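#' Generate an ECG R-wave event series
#'
#' RR intervals are drawn log-normally around `60 / heart_rate` with a small
#' multiplicative jitter, so the series has realistic beat-to-beat
#' variability while its long-run rate equals the requested heart rate.
#' Successive R-times are strictly increasing with RR > 0.3 s.
#'
#' @param duration Recording length in seconds.
#' @param heart_rate Mean heart rate in beats/min.
#' @param seed Integer seed.
#' @param rr_jitter_sdlog SD of log(RR) around its target (default 0.05).
#' @return A tibble with columns `interval` (1-based cardiac interval index)
#'   and `r_time` (seconds).
#' @export
#' @examples
#' cardiac <- gen_cardiac(duration = 60, heart_rate = 60, seed = 1)
#' head(cardiac)
gen_cardiac <- function(duration, heart_rate, seed, rr_jitter_sdlog = 0.05) {
  assert_that(duration > 0, "duration must be positive")
  assert_that(heart_rate > 0, "heart_rate must be positive")
  rr_target <- 60 / heart_rate
  n_max <- ceiling(duration / rr_target * 1.3) + 10
  with_seed(seed, {
    rr <- rr_target * exp(stats::rnorm(n_max, -rr_jitter_sdlog^2 / 2,
                                       rr_jitter_sdlog))
    rr <- pmax(rr, 0.301)
    r_time <- cumsum(rr)
    r_time <- r_time[r_time <= duration]
    tibble::tibble(interval = seq_along(r_time), r_time = r_time)
  })
}

#' Generate an R-wave-locked stimulation protocol
#'
#' Builds the trial/pulse schedule used in the experiments: every pulse is
#' triggered 200 ms after an R-wave. The microneurography variant delivers a
#' train of 5 shocks on 5 consecutive cardiac intervals per trial; the MEG
#' variant delivers 3 pulses on every other heartbeat (so two stimulus-free
#' intervals never separate pulses within a trial, and a full post-pulse
#' analysis window fits before the next pulse). Trials are separated by an
#' inter-trial interval drawn from `iti_menu`; the drawn ITI sequence is a
#' property of the session, so passing the same `iti_sequence` to every
#' subject reproduces the shared-schedule design.
#'
#' @param cardiac A cardiac series from [gen_cardiac()].
#' @param variant `"microneurography"` (5 consecutive-interval shocks) or
#'   `"meg"` (3 pulses on alternating heartbeats).
#' @param n_trials Number of trials (default 72).
#' @param iti_menu Allowed inter-trial intervals in seconds (default 30/45/60).
#' @param seed Seed for the ITI draw (ignored when `iti_sequence` is given).
#' @param iti_sequence Optional explicit ITI sequence (length `n_trials`),
#'   shared across subjects.
#' @param pulse_delay Post-R pulse latency in seconds (default 0.200).
#' @param n_baseline Stimulus-free cardiac intervals required before each
#'   trial (default 8, the control window of the inhibition statistic).
#' @return A tibble of class `msna_protocol` with columns `trial`, `pulse`,
#'   `interval` (cardiac interval index carrying the pulse), `r_time` and
#'   `onset_s`; attributes `variant` and `iti_sequence`.
#' @export
gen_protocol <- function(cardiac,
                         variant = c("meg", "microneurography"),
                         n_trials = 72,
                         iti_menu = c(30, 45, 60),
                         seed = 1,
                         iti_sequence = NULL,
                         pulse_delay = 0.200,
                         n_baseline = 8) {
  variant <- match.arg(variant)
  assert_that(n_trials >= 1, "n_trials must be >= 1")
  n_pulses <- if (variant == "microneurography") 5L else 3L
  stride <- if (variant == "microneurography") 1L else 2L
  if (is.null(iti_sequence)) {
    iti_sequence <- with_seed(seed,
      sample_iti(iti_menu, n_trials))
  }
  assert_that(length(iti_sequence) >= n_trials,
              "iti_sequence shorter than n_trials")
  r_time <- cardiac$r_time
  n_beats <- length(r_time)
  rows <- vector("list", n_trials)
  next_allowed_time <- r_time[min(n_baseline + 1L, n_beats)]
  for (tr in seq_len(n_trials)) {
    i0 <- which(r_time >= next_allowed_time)[1]
    last_needed <- if (is.na(i0)) NA else i0 + (n_pulses - 1L) * stride
    if (is.na(i0) || last_needed > n_beats) {
      stop("cardiac series too short for the requested protocol ",
           "(truncated at trial ", tr, " of ", n_trials, ")", call. = FALSE)
    }
    idx <- i0 + (seq_len(n_pulses) - 1L) * stride
    rt <- r_time[idx]
    rows[[tr]] <- tibble::tibble(
      trial = tr,
      pulse = seq_len(n_pulses),
      interval = idx,
      r_time = rt,
      onset_s = rt + pulse_delay
    )
    next_allowed_time <- r_time[last_needed] + iti_sequence[tr]
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "variant") <- variant
  attr(out, "iti_sequence") <- iti_sequence[seq_len(n_trials)]
  attr(out, "pulse_delay") <- pulse_delay
  attr(out, "n_baseline") <- n_baseline
  class(out) <- c("msna_protocol", class(out))
  out
}
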