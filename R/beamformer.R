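#' Sensor covariance over all conditions combined
#'
#' Pools every condition (baseline and the three post-pulse windows) into a
#' single channel covariance so that one common, unbiased spatial filter
#' serves all conditions. Epochs are demeaned per channel, samples under the
#' excision mask (+/-5 ms around the stimulus) are omitted, and the result
#' is symmetric positive semi-definite.
#'
#' @param sensor An `msna_sensor_epochs` object, or a named list of
#'   trials x channels x time arrays.
#' @param excise Optional logical mask over time samples (`TRUE` = omit);
#'   taken from the object when present.
#' @return List of class `msna_covariance`: `cov` (channels x channels),
#'   `n_samples`, `rank_deficient` flag.
#' @export
compute_covariance <- function(sensor, excise = NULL) {
  epochs <- if (inherits(sensor, "msna_sensor_epochs")) sensor$epochs
            else sensor
  if (is.null(excise) && inherits(sensor, "msna_sensor_epochs")) {
    excise <- sensor$excise
  }
  n_ch <- dim(epochs[[1]])[2]
  acc <- matrix(0, n_ch, n_ch)
  n_tot <- 0L
  for (cond in names(epochs)) {
    arr <- epochs[[cond]]
    keep <- if (is.null(excise) || cond == "baseline") {
      rep(TRUE, dim(arr)[3])
    } else {
      !excise
    }
    assert_that(any(keep), "excision removed every sample")
    for (tr in seq_len(dim(arr)[1])) {
      x <- arr[tr, , keep, drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, nrow = n_ch)
      x <- x - rowMeans(x)
      acc <- acc + tcrossprod(x)
      n_tot <- n_tot + ncol(x)
    }
  }
  assert_that(n_tot >= n_ch + 1,
              "need more effective samples than channels")
  C <- acc / n_tot
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  structure(
    list(cov = C, n_samples = n_tot,
         rank_deficient = min(ev) < max(ev) * 1e-12),
    class = "msna_covariance"
  )
}

#' LCMV spatial filter for one grid point
#'
#' Linearly constrained minimum-variance beamformer weights
#' \deqn{w = C^{-1} l / (l^T C^{-1} l)}
#' with unit gain `w'l = 1` at the target leadfield. For a free-orientation
#' (channels x 3) leadfield the scalar filter uses the max-power
#' orientation: the principal eigenvector of `(L' C^{-1} L)^{-1}`. The
#' covariance is regularized as `C + lambda * mean(diag(C)) * I`.
#'
#' @param leadfield Channel vector (fixed orientation) or channels x 3
#'   matrix.
#' @param covariance An `msna_covariance` or a plain covariance matrix.
#' @param lambda Regularization as a fraction of mean sensor variance
#'   (default 0.05).
#' @return List of class `msna_lcmv`: `weights`, `orientation` (NULL for
#'   fixed-orientation input), `leadfield` (scalar leadfield used).
#' @export
#' @examples
#' lcmv_filter(c(1, 1), diag(c(2, 1)), lambda = 0)$weights # (1/3, 2/3)
lcmv_filter <- function(leadfield, covariance, lambda = 0.05) {
  C <- if (inherits(covariance, "msna_covariance")) covariance$cov
       else covariance
  n_ch <- nrow(C)
  Creg <- C + lambda * mean(diag(C)) * diag(n_ch)
  Ci <- tryCatch(solve(Creg), error = function(e) {
    stop("covariance singular after regularization", call. = FALSE)
  })
  orientation <- NULL
  if (is.matrix(leadfield) && ncol(leadfield) > 1) {
    G <- t(leadfield) %*% Ci %*% leadfield
    # max-power orientation: principal eigenvector of G^{-1}
    eg <- eigen(solve(G), symmetric = TRUE)
    orientation <- eg$vectors[, 1]
    leadfield <- as.vector(leadfield %*% orientation)
  }
  l <- as.numeric(leadfield)
  denom <- as.numeric(t(l) %*% Ci %*% l)
  assert_that(denom > 0, "degenerate leadfield (zero projected power)")
  w <- as.vector(Ci %*% l) / denom
  structure(list(weights = w, orientation = orientation, leadfield = l),
            class = "msna_lcmv")
}

#' Build spatial filters for every grid point
#'
#' @param leadfields An `msna_leadfields` tibble.
#' @param covariance An `msna_covariance`.
#' @param lambda Regularization fraction.
#' @return The leadfields tibble with an added list-column `filter`.
#' @export
lcmv_filters <- function(leadfields, covariance, lambda = 0.05) {
  leadfields$filter <- lapply(leadfields$leadfield, lcmv_filter,
                              covariance = covariance, lambda = lambda)
  leadfields
}

# mean squared filter output over trials and (non-excised) samples
filter_power <- function(w, arr, keep) {
  n_trials <- dim(arr)[1]
  p <- 0
  for (tr in seq_len(n_trials)) {
    y <- as.vector(w %*% arr[tr, , keep, drop = TRUE])
    y <- y - mean(y)
    p <- p + mean(y^2)
  }
  p / n_trials
}

#' Baseline-contrasted source power per grid point
#'
#' Applies each point's spatial filter to the epochs of every pulse
#' condition and to the baseline, and returns the relative power change
#' `(P_cond - P_base) / P_base` per point and condition.
#'
#' @param filters Tibble from [lcmv_filters()].
#' @param sensor An `msna_sensor_epochs` object.
#' @param conditions Pulse conditions to contrast (default all non-baseline
#'   conditions present).
#' @return Long tibble: `point`, `roi`, `condition`, `power`,
#'   `power_baseline`, `contrast`.
#' @export
source_power_contrast <- function(filters, sensor, conditions = NULL) {
  epochs <- sensor$epochs
  if (is.null(conditions)) {
    conditions <- setdiff(names(epochs), "baseline")
  }
  keep_base <- rep(TRUE, length(sensor$times))
  keep_stim <- if (is.null(sensor$excise)) keep_base else !sensor$excise
  rows <- purrr::map_dfr(seq_len(nrow(filters)), function(i) {
    w <- filters$filter[[i]]$weights
    p_base <- filter_power(w, epochs$baseline, keep_base)
    purrr::map_dfr(conditions, function(cond) {
      p <- filter_power(w, epochs[[cond]], keep_stim)
      tibble::tibble(point = filters$point[i], roi = filters$roi[i],
                     condition = cond, power = p, power_baseline = p_base,
                     contrast = (p - p_base) / p_base)
    })
  })
  rows
}

#' Select reliably activated vertices and extract ROI trial series
#'
#' Within each ROI, keeps the grid points whose baseline-contrasted power
#' reaches at least `threshold` (default 60%) of the ROI's peak response
#' (contrast is pooled over pulse conditions by max), then averages the
#' single-trial filter outputs over the kept points to obtain one time
#' series per ROI, trial and condition. If no point shows a positive
#' response the single peak point is used with a warning.
#'
#' @param filters Tibble from [lcmv_filters()].
#' @param contrasts Tibble from [source_power_contrast()].
#' @param sensor An `msna_sensor_epochs` object.
#' @param roi ROI label to extract.
#' @param threshold Fraction of the ROI peak response (default 0.60).
#' @return List of class `msna_roi_series`: `roi`, `points` (kept grid
#'   points), `series` (list: condition -> trials x time matrix), `fs`,
#'   `times`.
#' @export
select_vertices_and_extract <- function(filters, contrasts, sensor, roi,
                                        threshold = 0.60) {
  cc <- contrasts[contrasts$roi == roi, ]
  assert_that(nrow(cc) > 0, paste("empty ROI:", roi))
  per_point <- cc |>
    dplyr::summarise(contrast = max(.data$contrast), .by = "point")
  peak <- max(per_point$contrast)
  if (peak <= 0) {
    warning("no positive response in ROI ", roi,
            "; falling back to single peak point")
    kept <- per_point$point[which.max(per_point$contrast)]
  } else {
    kept <- per_point$point[per_point$contrast >= threshold * peak]
  }
  fl <- filters[filters$point %in% kept, ]
  conds <- names(sensor$epochs)
  series <- lapply(conds, function(cond) {
    arr <- sensor$epochs[[cond]]
    n_trials <- dim(arr)[1]
    n_t <- dim(arr)[3]
    out <- matrix(0, n_trials, n_t)
    for (i in seq_len(nrow(fl))) {
      w <- fl$filter[[i]]$weights
      for (tr in seq_len(n_trials)) {
        out[tr, ] <- out[tr, ] + as.vector(w %*% arr[tr, , ])
      }
    }
    out / nrow(fl)
  })
  names(series) <- conds
  structure(
    list(roi = roi, points = kept, series = series,
         fs = sensor$fs, times = sensor$times),
    class = "msna_roi_series"
  )
}
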