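#' Generate beat-aligned blood-pressure trials
#'
#' Produces per-trial beat series around each stimulus train: beats -8..-1
#' are the pre-stimulus control window, beat 1 is the first stimulated
#' cardiac cycle. In Non-inhibitors the mean arterial pressure rises
#' transiently with its peak at cardiac interval 6 (amplitude
#' `spec$bp_rise_nonin`, carried mainly by diastolic pressure); Inhibitor
#' series stay flat apart from beat noise. Systolic, diastolic, heart-rate
#' and pulse-pressure channels are emitted alongside MAP.
#'
#' @param subjects Tibble with columns `subject`, `group`
#'   (`"Inhibitor"`/`"Non-inhibitor"`) and `heart_rate`.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param n_trials Trials per subject (default 72).
#' @param beats Beat indices relative to stimulus onset (default -8..15).
#' @return Long tibble: `subject`, `group`, `trial`, `beat`, `map`, `sbp`,
#'   `dbp`, `hr`, `pulse_pressure` (pressures mmHg, heart rate beats/min).
#' @export
gen_bp_series <- function(subjects, spec, seed, n_trials = 72,
                          beats = -8:15) {
  with_seed(seed, {
    rows <- vector("list", nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      base_dbp <- stats::rnorm(1, 65, 6)
      base_sbp <- base_dbp + stats::rnorm(1, 53, 6)
      base_hr <- subjects$heart_rate[i]
      is_nonin <- subjects$group[i] == "Non-inhibitor"
      rise <- if (is_nonin) {
        spec$bp_rise_nonin * gauss_bump(beats, 6, 2) * (beats >= 1)
      } else {
        rep(0, length(beats))
      }
      nb <- length(beats)
      g <- tidyr::expand_grid(trial = seq_len(n_trials), beat = beats)
      n <- nrow(g)
      dbp <- base_dbp + rep(rise, n_trials) * 0.9 +
        stats::rnorm(n, 0, spec$bp_noise_sd)
      sbp <- base_sbp + rep(rise, n_trials) * 1.2 +
        stats::rnorm(n, 0, spec$bp_noise_sd * 1.2)
      hr <- base_hr + stats::rnorm(n, 0, 1.5)
      rows[[i]] <- tibble::tibble(
        subject = subjects$subject[i],
        group = subjects$group[i],
        trial = g$trial,
        beat = g$beat,
        map = dbp + (sbp - dbp) / 3,
        sbp = sbp,
        dbp = dbp,
        hr = hr,
        pulse_pressure = sbp - dbp
      )
    }
    dplyr::bind_rows(rows)
  })
}

#' Generate a per-subject ROI cortical-thickness table
#'
#' Rostral-ACC thickness is negatively coupled to inhibition through a
#' subject latent that mixes the inhibition z-score with independent noise
#' at strength `spec$thickness_coupling`; the insula and Rolandic ROIs vary
#' independently of inhibition. Values are clipped to the plausible cortical
#' range 1.5-4.5 mm. The same table shape as a FreeSurfer Qdec ROI export is
#' used, so a real export drops in.
#'
#' @param inhibition Numeric vector of subject ground-truth inhibition (%).
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param thickness_scale mm of rACC thickness per unit latent (default 0.25).
#' @param measurement_sd Measurement noise SD in mm (default 0.05).
#' @return Tibble of class `msna_thickness` with columns `subject`,
#'   `racc_left`, `racc_right`, `insula_left`, `insula_right`, `rolandic`
#'   (mm); attribute `latent` stores the realized coupling latent per
#'   subject (ground truth, not consumed by analysis).
#' @export
gen_thickness <- function(inhibition, spec, seed,
                          thickness_scale = 0.25, measurement_sd = 0.05) {
  n <- length(inhibition)
  with_seed(seed, {
    z <- (inhibition - spec$inhibition_mean) / spec$inhibition_sd
    c_t <- spec$thickness_coupling
    latent <- c_t * z + sqrt(max(0, 1 - c_t^2)) * stats::rnorm(n)
    clip <- function(x) pmin(pmax(x, 1.5), 4.5)
    racc_base <- 2.9 - thickness_scale * latent
    out <- tibble::tibble(
      subject = seq_len(n),
      racc_left = clip(racc_base + stats::rnorm(n, 0, measurement_sd)),
      racc_right = clip(racc_base + stats::rnorm(n, 0, measurement_sd)),
      insula_left = clip(3.0 + stats::rnorm(n, 0, 0.25)),
      insula_right = clip(3.0 + stats::rnorm(n, 0, 0.25)),
      rolandic = clip(2.6 + stats::rnorm(n, 0, 0.25))
    )
    attr(out, "latent") <- latent
    class(out) <- c("msna_thickness", class(out))
    out
  })
}
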