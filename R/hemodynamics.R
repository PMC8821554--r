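#' Align beat-by-beat pressure trials to stimulus onset
#'
#' Converts per-trial beat series into trial-averaged change-from-baseline
#' curves per subject: for every trial and measure, the mean over the
#' pre-stimulus control beats (default -8..-1, mirroring the 8-interval
#' MSNA control window) is subtracted, then trials are averaged. Beat 1 is
#' the first stimulated cardiac cycle. Trials missing any beat in the
#' analysis range are dropped with a message.
#'
#' @param bp Long tibble as from [gen_bp_series()]: `subject`, `group`,
#'   `trial`, `beat`, plus measure columns (`map`, `sbp`, `dbp`, `hr`,
#'   `pulse_pressure`).
#' @param baseline_beats Beats defining the pre-stimulus baseline.
#' @param measures Measure columns to align.
#' @return Tibble of class `msna_beats`: `subject`, `group`, `beat`,
#'   `measure`, `change` (trial-averaged change from baseline), `n_trials`.
#' @export
align_beats <- function(bp, baseline_beats = -8:-1,
                        measures = c("map", "sbp", "dbp", "hr",
                                     "pulse_pressure")) {
  measures <- intersect(measures, names(bp))
  beats_all <- sort(unique(bp$beat))
  long <- tidyr::pivot_longer(
    bp[, c("subject", "group", "trial", "beat", measures)],
    cols = dplyr::all_of(measures),
    names_to = "measure", values_to = "value"
  )
  # drop trials not covering the full beat range
  complete <- long |>
    dplyr::summarise(n_beat = dplyr::n_distinct(.data$beat),
                     .by = c("subject", "trial"))
  bad <- complete[complete$n_beat < length(beats_all), ]
  if (nrow(bad) > 0) {
    message(nrow(bad), " trial(s) dropped: incomplete beat coverage")
    long <- dplyr::anti_join(long, bad[, c("subject", "trial")],
                             by = c("subject", "trial"))
  }
  base <- long |>
    dplyr::filter(.data$beat %in% baseline_beats) |>
    dplyr::summarise(base = mean(.data$value),
                     .by = c("subject", "trial", "measure"))
  out <- long |>
    dplyr::left_join(base, by = c("subject", "trial", "measure")) |>
    dplyr::mutate(change = .data$value - .data$base) |>
    dplyr::summarise(change = mean(.data$change),
                     n_trials = dplyr::n(),
                     .by = c("subject", "group", "beat", "measure"))
  class(out) <- c("msna_beats", class(out))
  out
}

#' Compare groups at one cardiac interval
#'
#' Two-sided Wilcoxon rank-sum test of the change-from-baseline between
#' Inhibitors and Non-inhibitors at a given post-stimulus beat (default
#' cardiac interval 6, where the pressure effect of a present or absent
#' sympathetic burst peaks). The exact null distribution is used when the
#' combined sample size is at most 20 and the data are tie-free; otherwise
#' the normal approximation with continuity correction applies.
#'
#' @param beats An `msna_beats` tibble from [align_beats()].
#' @param beat Post-stimulus cardiac interval to test (default 6).
#' @param measure Measure to test (default `"map"`).
#' @param exact_max Combined-n switch between exact and asymptotic
#'   rank-sum (default 20).
#' @return One-row tibble: `measure`, `beat`, `statistic` (rank-sum W),
#'   `p_value`, `n_inhibitor`, `n_noninhibitor`, `method`.
#' @export
compare_groups <- function(beats, beat = 6, measure = "map",
                           exact_max = 20) {
  d <- beats[beats$beat == beat & beats$measure == measure, ]
  x <- d$change[d$group == "Non-inhibitor"]
  y <- d$change[d$group == "Inhibitor"]
  assert_that(length(x) > 0 && length(y) > 0,
              "both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (ties && length(unique(c(x, y))) == 1) {
    warning("all values tied; p = 1")
    return(tibble::tibble(measure = measure, beat = beat,
                          statistic = NA_real_, p_value = 1,
                          n_inhibitor = length(y),
                          n_noninhibitor = length(x),
                          method = "degenerate (all tied)"))
  }
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided")
  )
  tibble::tibble(measure = measure, beat = beat,
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_inhibitor = length(y), n_noninhibitor = length(x),
                 method = if (use_exact) "exact rank-sum"
                          else "asymptotic rank-sum")
}

#' Screen post-stimulus beats for group differences
#'
#' One rank-sum test per beat per measure over the post-stimulus beats that
#' show a visible mean-pressure difference (default 1-15), by default for
#' heart rate and pulse pressure. No multiplicity correction is applied
#' when every raw p-value is already >= 0.05 (none is then needed); the raw
#' p-values are always returned so any correction can be applied downstream.
#'
#' @param beats An `msna_beats` tibble.
#' @param beat_range Beats to screen (default 1:15).
#' @param measures Measures to screen (default heart rate, pulse pressure).
#' @inheritParams compare_groups
#' @return Tibble with one row per beat x measure.
#' @export
screen_beats <- function(beats, beat_range = 1:15,
                         measures = c("hr", "pulse_pressure"),
                         exact_max = 20) {
  grid <- tidyr::expand_grid(measure = measures, beat = beat_range)
  purrr::pmap_dfr(grid, function(measure, beat) {
    compare_groups(beats, beat = beat, measure = measure,
                   exact_max = exact_max)
  })
}

#' Correlate MSNA inhibition with the pressure response
#'
#' Spearman correlation (two-sided) across subjects between individual
#' inhibition and the change-from-baseline of a pressure measure at one
#' post-stimulus beat.
#'
#' @param profiles Tibble with `subject` and `inhibition` columns.
#' @param beats An `msna_beats` tibble.
#' @param beat Beat index (default 6).
#' @param measure Measure (default `"map"`).
#' @return One-row tibble: `r`, `p_value`, `n`, `measure`, `beat`.
#' @export
correlate_inhibition_bp <- function(profiles, beats, beat = 6,
                                    measure = "map") {
  d <- beats[beats$beat == beat & beats$measure == measure, ]
  d <- dplyr::inner_join(d, profiles[, c("subject", "inhibition")],
                         by = "subject")
  spearman_test(d$change, d$inhibition) |>
    dplyr::mutate(measure = measure, beat = beat)
}

# Shared Spearman helper: exact p for n <= 10 tie-free data, t-approximation
# otherwise; mid-ranks for ties.
spearman_test <- function(x, y) {
  n <- length(x)
  assert_that(n >= 5, "need at least 5 paired observations")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (n <= 10 && !ties))
  )
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}
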