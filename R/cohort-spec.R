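#' Define a synthetic cohort specification
#'
#' A `cohort_spec` fixes every parameter of the synthetic study: cohort size,
#' the distribution of stimulus-induced MSNA inhibition across subjects,
#' resting cardiovascular and sympathetic characteristics, and the strength of
#' the ground-truth couplings that downstream stages are asked to recover.
#' Identical specs (including `seed`) generate bit-identical cohorts.
#'
#' Defaults mirror the resting characteristics of the study cohort the
#' generator emulates: heart rate 56 +/- 7.8 beats/min and resting burst
#' incidence 44.3 bursts per 100 heartbeats. The inhibition distribution is
#' normal with its mean placed at the 30% classification threshold, which
#' reproduces an even Inhibitor / Non-inhibitor split in expectation; draws
#' are truncated at the +100% physical bound (a burst cannot be more than
#' completely absent).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed; the single source of randomness for the cohort.
#' @param inhibition_mean,inhibition_sd Mean and SD (percent) of the normal
#'   distribution of subject-level MSNA inhibition.
#' @param outlier_inhibition Optional percent value; when given, exactly one
#'   subject is forced to this ground-truth inhibition (emulating the rare
#'   strongly excitatory outlier).
#' @param heart_rate_mean,heart_rate_sd Resting heart rate distribution
#'   (beats/min) across subjects.
#' @param burst_incidence Resting burst incidence, bursts per 100 heartbeats.
#' @param burst_amplitude_cv Coefficient of variation of log-normal burst
#'   amplitudes (dimensionless).
#' @param rebound_coupling Strength in `[0, 1]` of the monotone coupling
#'   between a subject's inhibition and their post-stimulus beta-rebound
#'   power.
#' @param thickness_coupling Strength in `[-1, 1]` of the (negative) coupling
#'   between rostral-ACC cortical thickness and inhibition.
#' @param bp_rise_nonin Peak mean-arterial-pressure rise (mmHg) at cardiac
#'   interval 6 in Non-inhibitors.
#' @param bp_noise_sd Beat-to-beat additive pressure noise SD (mmHg).
#' @param neurogram_fs Sampling rate of the integrated neurogram (Hz).
#' @param epoch_fs Sampling rate of source/sensor epochs (Hz).
#'
#' @return An object of class `cohort_spec` (a named list).
#' @seealso [gen_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 4, seed = 1)
#' spec$inhibition_mean
cohort_spec <- function(n_subjects = 20,
                        seed = 1,
                        inhibition_mean = 30,
                        inhibition_sd = 35,
                        outlier_inhibition = NULL,
                        heart_rate_mean = 56,
                        heart_rate_sd = 7.8,
                        burst_incidence = 44.3,
                        burst_amplitude_cv = 1.0,
                        rebound_coupling = 0.8,
                        thickness_coupling = 0.6,
                        bp_rise_nonin = 4,
                        bp_noise_sd = 2,
                        neurogram_fs = 100,
                        epoch_fs = 200) {
  assert_that(is.numeric(n_subjects) && n_subjects >= 2,
              "n_subjects must be >= 2")
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  assert_that(inhibition_sd > 0, "inhibition_sd must be positive")
  assert_that(heart_rate_mean > 0, "heart_rate_mean must be positive")
  assert_that(burst_incidence >= 0 && burst_incidence <= 100,
              "burst_incidence must lie in [0, 100]")
  assert_that(rebound_coupling >= 0 && rebound_coupling <= 1,
              "rebound_coupling must lie in [0, 1]")
  assert_that(thickness_coupling >= -1 && thickness_coupling <= 1,
              "thickness_coupling must lie in [-1, 1]")
  if (!is.null(outlier_inhibition)) {
    assert_that(is.numeric(outlier_inhibition) && outlier_inhibition <= 100,
                "outlier_inhibition must be a percent value <= 100")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      seed = as.integer(seed),
      inhibition_mean = inhibition_mean,
      inhibition_sd = inhibition_sd,
      outlier_inhibition = outlier_inhibition,
      heart_rate_mean = heart_rate_mean,
      heart_rate_sd = heart_rate_sd,
      burst_incidence = burst_incidence,
      burst_amplitude_cv = burst_amplitude_cv,
      rebound_coupling = rebound_coupling,
      thickness_coupling = thickness_coupling,
      bp_rise_nonin = bp_rise_nonin,
      bp_noise_sd = bp_noise_sd,
      neurogram_fs = neurogram_fs,
      epoch_fs = epoch_fs
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_subjects, "subjects, seed", x$seed, "\n")
  cat("  inhibition ~ N(", x$inhibition_mean, ", ", x$inhibition_sd,
      "^2) %, truncated at +100\n", sep = "")
  cat("  couplings: rebound", x$rebound_coupling,
      "| thickness", x$thickness_coupling, "\n")
  invisible(x)
}
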