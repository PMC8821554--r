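#' Generate an integrated MSNA neurogram
#'
#' Renders a rectified/integrated sympathetic neurogram as a non-negative
#' sample train: bursts are Gaussian humps (FWHM 0.3 s) at a fixed reflex
#' latency after a random subset of R-waves, with log-normal amplitude
#' variability, riding on a small noise floor (an offset Gaussian clipped
#' at zero, keeping the integrated signal non-negative). Burst occurrence
#' follows the resting burst incidence; stimulus-induced inhibition acts on
#' the amplitude expectation of bursts in the post-stimulus window — the
#' expected amplitude is scaled by `(1 - inhibition/100)`, and draws that
#' underflow a detection floor become absent bursts (amplitude exactly 0).
#' So `inhibition = 100` silences every post-stimulus burst while
#' `inhibition = -200` triples their expected magnitude.
#'
#' @param cardiac Cardiac series from [gen_cardiac()].
#' @param inhibition Subject-level ground-truth inhibition in percent
#'   (must be <= 100).
#' @param protocol Optional [gen_protocol()] table; when `NULL` the recording
#'   is stimulus-free (used for resting metrics and dummy calibration).
#' @param spec A [cohort_spec()] supplying burst incidence, amplitude CV and
#'   neurogram sampling rate.
#' @param seed Integer seed.
#' @param burst_latency Reflex burst latency after the R-wave (s).
#' @param burst_fwhm Burst full width at half maximum (s).
#' @param noise_sd SD of the noise floor (amplitude units; burst amplitudes
#'   have mean 1); the floor rides at 3 x `noise_sd` above zero.
#' @param amplitude_floor Amplitudes below this value register as absent.
#' @return An object of class `msna_neurogram`: list with `samples`
#'   (non-negative numeric), `fs`, `r_times`, and `truth` (a tibble of
#'   per-interval ground-truth burst amplitudes; zero = absent).
#' @export
gen_neurogram <- function(cardiac, inhibition, protocol = NULL, spec,
                          seed, burst_latency = 1.3, burst_fwhm = 0.3,
                          noise_sd = 0.01, amplitude_floor = 0.05) {
  assert_that(inhibition <= 100,
              "inhibition cannot exceed 100% (complete burst absence)")
  fs <- spec$neurogram_fs
  r_times <- cardiac$r_time
  n_int <- length(r_times)
  cv <- spec$burst_amplitude_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2 # mean amplitude 1

  with_seed(seed, {
    present <- stats::runif(n_int) < spec$burst_incidence / 100
    amp <- ifelse(present, stats::rlnorm(n_int, meanlog, sdlog), 0)
    if (!is.null(protocol)) {
      post <- unique(protocol$interval)
      post <- post[post <= n_int]
      amp[post] <- amp[post] * (1 - inhibition / 100)
    }
    amp[amp < amplitude_floor] <- 0

    duration <- max(r_times) + 2.5
    n_samp <- ceiling(duration * fs)
    t <- seq(0, by = 1 / fs, length.out = n_samp)
    samples <- pmax(0, stats::rnorm(n_samp, 3 * noise_sd, noise_sd))
    sigma <- burst_fwhm / (2 * sqrt(2 * log(2)))
    # truncate the hump at 2.5 sigma so bursts stay a minority of samples
    # and a rolling-median baseline sees true inter-burst floor
    half_w <- ceiling(2.5 * sigma * fs)
    kernel_t <- (-half_w:half_w) / fs
    kernel <- exp(-kernel_t^2 / (2 * sigma^2))
    for (k in which(amp > 0)) {
      centre <- round((r_times[k] + burst_latency) * fs) + 1
      lo <- centre - half_w
      hi <- centre + half_w
      if (lo < 1 || hi > n_samp) next
      samples[lo:hi] <- samples[lo:hi] + amp[k] * kernel
    }
    structure(
      list(
        samples = samples,
        fs = fs,
        r_times = r_times,
        truth = tibble::tibble(interval = seq_len(n_int),
                               r_time = r_times,
                               amplitude = amp)
      ),
      class = "msna_neurogram"
    )
  })
}

#' @export
print.msna_neurogram <- function(x, ...) {
  cat("<msna_neurogram>", length(x$samples), "samples @", x$fs, "Hz,",
      length(x$r_times), "cardiac intervals,",
      sum(x$truth$amplitude > 0), "bursts\n")
  invisible(x)
}
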