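# Source- and sensor-level epoch generators.

# 1/f ("pink") noise via spectral shaping of white noise.
pink_noise <- function(n, alpha = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # two-sided frequency index
  W <- W / f^(alpha / 2)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

gauss_bump <- function(t, centre, width) exp(-(t - centre)^2 / (2 * width^2))

#' Generate ROI source-space oscillatory epochs
#'
#' Emulates the single-trial ROI time series that source reconstruction
#' yields: broadband 1/f background plus a beta-band (~19 Hz) oscillation
#' whose envelope shows early desynchronization (0-0.4 s) followed by a
#' rebound (0.5-1.2 s) after each pulse. The rebound gain is a monotone
#' function of a subject-level latent that mixes the subject's inhibition
#' with independent noise at strength `spec$rebound_coupling`; with coupling
#' 1 and no noise the across-subject rank correlation between rebound power
#' and inhibition is exactly 1, with coupling 0 the two are independent.
#'
#' Condition structure mirrors the experiment: a stationary pre-stimulus
#' baseline epoch plus one 1.5 s epoch after each of the three pulses. The
#' rostral ACC receives a rebound only after pulses 2 and 3; the Rolandic
#' region after all three; the insula responds but its gain is uncoupled
#' from inhibition.
#'
#' @param inhibition Subject ground-truth inhibition (percent).
#' @param protocol A 3-pulse protocol table (only its trial count is used).
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param rois Character vector of ROI labels to generate.
#' @param rebound_latent Optional pre-drawn subject latent (used by
#'   [gen_cohort()] so the realized coupling can be stored as ground truth);
#'   when `NULL` it is drawn here.
#' @param window Epoch length in seconds (1.5).
#' @param beta_freq Carrier frequency of the beta oscillation (Hz).
#' @param beta_amp Baseline beta envelope amplitude (noise SD is 1).
#' @param desync_depth Fractional envelope suppression at the trough.
#' @param rebound_gain Envelope gain scale of the rebound.
#' @return Object of class `msna_source_epochs`: list with `epochs`
#'   (`epochs[[roi]][[condition]]` = trials x time matrix for conditions
#'   `baseline`, `p1`, `p2`, `p3`), `fs`, `times`, `roi_labels`,
#'   `rebound_latent`.
#' @export
gen_source_epochs <- function(inhibition, protocol, spec, seed,
                              rois = c("racc", "insula", "rolandic"),
                              rebound_latent = NULL,
                              window = 1.5,
                              beta_freq = 19,
                              beta_amp = 1,
                              desync_depth = 0.6,
                              rebound_gain = 0.8) {
  fs <- spec$epoch_fs
  n_t <- round(window * fs)
  times <- seq(0, by = 1 / fs, length.out = n_t)
  n_trials <- max(protocol$trial)
  conds <- c("baseline", "p1", "p2", "p3")

  with_seed(seed, {
    if (is.null(rebound_latent)) {
      z <- (inhibition - spec$inhibition_mean) / spec$inhibition_sd
      c_r <- spec$rebound_coupling
      rebound_latent <- c_r * z + sqrt(max(0, 1 - c_r^2)) * stats::rnorm(1)
    }
    gain_coupled <- rebound_gain * exp(0.5 * rebound_latent)
    gain_flat <- rebound_gain

    desync_env <- 1 - desync_depth * gauss_bump(times, 0.20, 0.12)
    rebound_shape <- gauss_bump(times, 0.85, 0.18)

    epochs <- lapply(rois, function(roi) {
      out <- lapply(conds, function(cond) {
        has_response <- cond != "baseline" &&
          !(roi == "racc" && cond == "p1")
        g <- if (!has_response) 0
             else if (roi == "insula") gain_flat
             else gain_coupled
        env <- if (cond == "baseline") rep(beta_amp, n_t)
               else beta_amp * desync_env * (1 + g * rebound_shape)
        m <- matrix(0, n_trials, n_t)
        for (tr in seq_len(n_trials)) {
          phase <- stats::runif(1, 0, 2 * pi)
          f_tr <- beta_freq + stats::rnorm(1, 0, 0.8)
          carrier <- sin(2 * pi * f_tr * times + phase)
          m[tr, ] <- pink_noise(n_t) + env * carrier
        }
        m
      })
      names(out) <- conds
      out
    })
    names(epochs) <- rois
    structure(
      list(epochs = epochs, fs = fs, times = times, roi_labels = rois,
           rebound_latent = rebound_latent),
      class = "msna_source_epochs"
    )
  })
}

#' Generate a toy leadfield model
#'
#' Grid points are laid out at 5 mm spacing within each ROI; each point gets
#' a forward vector of unit norm (fixed orientation) or a channels x 3
#' orientation matrix. These toy leadfields stand in for a realistic forward
#' model, which is out of scope; they are synthetic by construction and only
#' support testing the inverse machinery.
#'
#' @param n_channels Number of sensors.
#' @param rois ROI labels.
#' @param points_per_roi Grid points per ROI.
#' @param seed Integer seed.
#' @param fixed_orientation If `TRUE` (default) each point's leadfield is a
#'   single channel vector; otherwise a channels x 3 matrix.
#' @return A tibble of class `msna_leadfields` with columns `point`, `roi`,
#'   `x`, `y`, `z` (mm, 5 mm spacing) and list-column `leadfield`.
#' @export
gen_leadfields <- function(n_channels = 24,
                           rois = c("racc", "insula", "rolandic"),
                           points_per_roi = 5,
                           seed = 1,
                           fixed_orientation = TRUE) {
  with_seed(seed, {
    rows <- list()
    pt <- 0L
    for (ri in seq_along(rois)) {
      for (k in seq_len(points_per_roi)) {
        pt <- pt + 1L
        lf <- if (fixed_orientation) {
          v <- stats::rnorm(n_channels)
          v / sqrt(sum(v^2))
        } else {
          m <- matrix(stats::rnorm(n_channels * 3), n_channels, 3)
          sweep(m, 2, sqrt(colSums(m^2)), "/")
        }
        rows[[pt]] <- tibble::tibble(
          point = pt, roi = rois[ri],
          x = ri * 100, y = (k - 1) * 5, z = 0,
          leadfield = list(lf)
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("msna_leadfields", class(out))
    out
  })
}

#' Project source epochs to sensors
#'
#' Forms `sensors = leadfield x source + white noise`: for every condition,
#' each ROI's trial time series is placed at one generating grid point and
#' projected through that point's forward vector; independent Gaussian noise
#' is added so that the ratio of projected-signal variance to noise variance
#' equals `snr`.
#'
#' @param source A [gen_source_epochs()] object.
#' @param leadfields A [gen_leadfields()] tibble (fixed orientation).
#' @param snr Signal-to-noise variance ratio (`Inf` for noise-free).
#' @param seed Integer seed for the sensor noise.
#' @param source_points Named integer vector mapping ROI -> generating point
#'   (defaults to the middle grid point of each ROI).
#' @return Object of class `msna_sensor_epochs`: list with `epochs`
#'   (`epochs[[condition]]` = trials x channels x time array), `fs`, `times`,
#'   `source_points`, and `excise` (logical mask over time, TRUE = excised
#'   +/-5 ms around the stimulus at epoch onset for pulse conditions).
#' @export
gen_sensor_epochs <- function(source, leadfields, snr = 1, seed = 1,
                              source_points = NULL) {
  rois <- source$roi_labels
  lf_rois <- unique(leadfields$roi)
  assert_that(all(rois %in% lf_rois),
              "leadfields missing one or more source ROIs")
  n_channels <- length(leadfields$leadfield[[1]])
  assert_that(is.null(dim(leadfields$leadfield[[1]])),
              "gen_sensor_epochs requires fixed-orientation leadfields")
  if (is.null(source_points)) {
    source_points <- vapply(rois, function(r) {
      pts <- leadfields$point[leadfields$roi == r]
      pts[ceiling(length(pts) / 2)]
    }, integer(1))
  }
  conds <- names(source$epochs[[1]])
  n_t <- length(source$times)

  with_seed(seed, {
    # projected signal variance, pooled over conditions, for noise scaling
    sig_var <- 0; n_var <- 0
    proj <- lapply(conds, function(cond) {
      n_trials <- nrow(source$epochs[[1]][[cond]])
      arr <- array(0, c(n_trials, n_channels, n_t))
      for (r in rois) {
        lf <- leadfields$leadfield[[which(leadfields$point ==
                                            source_points[[r]])]]
        s <- source$epochs[[r]][[cond]]
        for (ch in seq_len(n_channels)) {
          arr[, ch, ] <- arr[, ch, ] + lf[ch] * s
        }
      }
      arr
    })
    names(proj) <- conds
    sig_var <- stats::var(as.vector(proj[[length(proj)]]))
    noise_sd <- if (is.infinite(snr)) 0 else sqrt(sig_var / snr)
    epochs <- lapply(proj, function(arr) {
      if (noise_sd > 0) {
        arr <- arr + array(stats::rnorm(length(arr), 0, noise_sd), dim(arr))
      }
      arr
    })
    excise <- source$times <= 0.005
    structure(
      list(epochs = epochs, fs = source$fs, times = source$times,
           source_points = source_points, excise = excise,
           noise_sd = noise_sd),
      class = "msna_sensor_epochs"
    )
  })
}
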