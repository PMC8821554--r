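#' Correlation of power in a fixed time-frequency window with inhibition
#'
#' Averages relative power over a generic search window (default the beta
#' band, 13-25 Hz, at 0.5-1.2 s after the pulse) per subject and computes
#' the Spearman correlation with inhibition. The window is clipped to the
#' map's valid extent; an empty intersection is an error.
#'
#' @param maps An `msna_tfr_maps` object.
#' @param inhibition Per-subject inhibition values.
#' @param band Frequency window in Hz (default `c(13, 25)`).
#' @param window Time window in seconds (default `c(0.5, 1.2)`).
#' @return One-row tibble: `r`, `p_value`, `n`, plus the window actually
#'   used (`freq_lo`, `freq_hi`, `time_lo`, `time_hi`) and `roi`,
#'   `condition` labels.
#' @export
generic_window_corr <- function(maps, inhibition, band = c(13, 25),
                                window = c(0.5, 1.2)) {
  fsel <- which(maps$freqs >= band[1] & maps$freqs <= band[2])
  tsel <- which(maps$times >= window[1] & maps$times <= window[2])
  assert_that(length(fsel) > 0 && length(tsel) > 0,
              "window does not intersect the map grid")
  sub <- maps$power[, fsel, tsel, drop = FALSE]
  pw <- apply(sub, 1, mean, na.rm = TRUE)
  assert_that(all(is.finite(pw)),
              "window contains no valid (non-edge) power for some subject")
  st <- spearman_test(pw, inhibition)
  dplyr::mutate(st,
                freq_lo = min(maps$freqs[fsel]),
                freq_hi = max(maps$freqs[fsel]),
                time_lo = min(maps$times[tsel]),
                time_hi = max(maps$times[tsel]),
                roi = maps$roi, condition = maps$condition)
}

#' Group-averaged beta-band power time courses
#'
#' Averages relative power over the beta band per subject and time point,
#' then summarises per group (Inhibitors vs Non-inhibitors) as mean +/- SEM
#' and marks time points with an uncorrected two-tailed t-test group
#' difference at p < 0.05 and p < 0.01. The marks are visual guidance only
#' — no multiplicity correction is applied, by design.
#'
#' @param maps An `msna_tfr_maps` object.
#' @param groups Character vector of per-subject group labels.
#' @param band Frequency band in Hz (default 13-25).
#' @return Tibble of class `msna_beta_course`: `time`, `group`, `mean`,
#'   `sem`, `n`, and per-time `p_value`, `sig05`, `sig01` (duplicated
#'   across the two group rows of each time point).
#' @export
group_beta_timecourse <- function(maps, groups, band = c(13, 25)) {
  assert_that(length(groups) == dim(maps$power)[1],
              "one group label per subject required")
  fsel <- which(maps$freqs >= band[1] & maps$freqs <= band[2])
  # subject x time beta-band mean
  bt <- apply(maps$power[, fsel, , drop = FALSE], c(1, 3), mean,
              na.rm = TRUE)
  nt <- ncol(bt)
  out <- vector("list", nt)
  for (ti in seq_len(nt)) {
    v <- bt[, ti]
    if (all(is.nan(v))) next
    p <- tryCatch(stats::t.test(v ~ groups)$p.value,
                  error = function(e) NA_real_)
    per_group <- tibble::tibble(group = unique(groups)) |>
      dplyr::mutate(
        mean = vapply(.data$group, function(g) mean(v[groups == g]),
                      numeric(1), USE.NAMES = FALSE),
        sem = vapply(.data$group, function(g) {
          stats::sd(v[groups == g]) / sqrt(sum(groups == g))
        }, numeric(1), USE.NAMES = FALSE),
        n = vapply(.data$group, function(g) sum(groups == g), integer(1),
                   USE.NAMES = FALSE),
        time = maps$times[ti],
        p_value = p,
        sig05 = !is.na(p) & p < 0.05,
        sig01 = !is.na(p) & p < 0.01
      )
    out[[ti]] <- per_group
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("msna_beta_course", class(res))
  res
}
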