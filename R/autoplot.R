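# ggplot2 autoplot() methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a time-frequency map
#'
#' Heat map of relative power, subject-averaged for map stacks.
#'
#' @param object An `msna_tfr` or `msna_tfr_maps` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msna_tfr <- function(object, ...) {
  d <- tidy.msna_tfr(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$freq,
                                  fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "power") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.msna_tfr
#' @export
autoplot.msna_tfr_maps <- function(object, ...) {
  d <- tidy.msna_tfr_maps(object) |>
    dplyr::summarise(power = mean(.data$power, na.rm = TRUE),
                     .by = c("freq", "time"))
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$freq,
                                  fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(
      x = "time after pulse (s)", y = "frequency (Hz)",
      fill = "relative\npower",
      title = paste0(object$roi, " / ", object$condition,
                     " — grand-average relative power")) +
    ggplot2::theme_minimal()
}

#' Plot the observed correlation map with cluster outlines
#'
#' @param object An `msna_clusters` result.
#' @param ... Unused.
#' @return A ggplot of the per-bin Spearman r with significant-cluster bins
#'   outlined.
#' @export
autoplot.msna_clusters <- function(object, ...) {
  nf <- length(object$freqs)
  d <- tibble::tibble(
    freq = rep(object$freqs, times = length(object$times)),
    time = rep(object$times, each = nf),
    r = as.vector(object$r_map)
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$freq,
                                       fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "Spearman r") +
    ggplot2::theme_minimal()
  sig <- object$clusters[object$clusters$significant, ]
  if (nrow(sig) > 0) {
    bins <- purrr::map_dfr(seq_len(nrow(sig)), function(i) {
      b <- sig$bins[[i]]
      tibble::tibble(freq = object$freqs[(b - 1) %% nf + 1],
                     time = object$times[(b - 1) %/% nf + 1])
    })
    p <- p + ggplot2::geom_tile(data = bins, fill = NA, colour = "black",
                                linewidth = 0.2)
  }
  p
}

#' Plot group beta-band time courses
#'
#' Mean +/- SEM per group with guidance marks where the uncorrected
#' two-tailed t-test falls below 0.05 (grey) or 0.01 (black).
#'
#' @param object An `msna_beta_course` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msna_beta_course <- function(object, ...) {
  marks <- object |>
    dplyr::distinct(.data$time, .data$sig05, .data$sig01)
  y0 <- min(object$mean - object$sem, na.rm = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$mean,
                                       colour = .data$group,
                                       fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = marks[marks$sig05, ],
                        ggplot2::aes(y = y0 - 0.02), inherit.aes = FALSE,
                        colour = "grey50", size = 0.6) +
    ggplot2::geom_point(data = marks[marks$sig01, ],
                        ggplot2::aes(y = y0 - 0.04), inherit.aes = FALSE,
                        colour = "black", size = 0.6) +
    ggplot2::labs(x = "time after pulse (s)",
                  y = "beta-band relative power",
                  colour = NULL, fill = NULL,
                  caption = "marks: uncorrected t-test, visual guidance only") +
    ggplot2::theme_minimal()
}

#' Plot beat-aligned group blood-pressure responses
#'
#' @param object An `msna_beats` tibble from [align_beats()].
#' @param measure Measure to show (default `"map"`).
#' @param ... Unused.
#' @return A ggplot of group mean +/- SEM change by beat.
#' @export
autoplot.msna_beats <- function(object, measure = "map", ...) {
  d <- object[object$measure == measure, ] |>
    dplyr::summarise(m = mean(.data$change),
                     sem = stats::sd(.data$change) / sqrt(dplyr::n()),
                     .by = c("group", "beat"))
  ggplot2::ggplot(d, ggplot2::aes(.data$beat, .data$m,
                                  colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$m - .data$sem,
                                          ymax = .data$m + .data$sem),
                             size = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cardiac cycle relative to stimulus",
                  y = paste("Δ", measure, "(mmHg)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
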