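# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a time-frequency map stack into a long tibble
#'
#' @param x An `msna_tfr_maps` object.
#' @param ... Unused.
#' @return Tibble: `subject`, `freq`, `time`, `power` (relative power),
#'   plus `roi` and `condition` labels.
#' @export
tidy.msna_tfr_maps <- function(x, ...) {
  d <- dim(x$power)
  tibble::tibble(
    subject = rep(seq_len(d[1]), times = d[2] * d[3]),
    freq = rep(rep(x$freqs, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    power = as.vector(x$power),
    roi = x$roi,
    condition = x$condition
  )
}

#' Tidy a single-trial TFR
#' @param x An `msna_tfr` object.
#' @param ... Unused.
#' @return Tibble: `freq`, `time`, `power`.
#' @export
tidy.msna_tfr <- function(x, ...) {
  tibble::tibble(
    freq = rep(x$freqs, times = length(x$times)),
    time = rep(x$times, each = length(x$freqs)),
    power = as.vector(x$power)
  )
}

#' Tidy a cluster permutation result
#'
#' @param x An `msna_clusters` object.
#' @param ... Unused.
#' @return The clusters tibble without the `bins` list-column.
#' @export
tidy.msna_clusters <- function(x, ...) {
  x$clusters[, setdiff(names(x$clusters), "bins")]
}

#' @rdname tidy.msna_clusters
#' @export
glance.msna_clusters <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters) > 0) min(x$clusters$p_value) else NA_real_,
    n_perm = x$n_perm,
    alpha = x$alpha,
    n_subjects = x$n_subjects
  )
}

#' Tidy a study result into its headline statistics
#'
#' One row per reported statistic: the beat-6 MAP group comparison, the
#' inhibition-BP correlation, per-ROI/pulse generic-window correlations,
#' per-ROI/pulse significant-cluster correlations, and thickness
#' correlations.
#'
#' @param x An `msna_study` object.
#' @param ... Unused.
#' @return Tibble: `analysis`, `term`, `estimate`, `p_value`.
#' @export
tidy.msna_study <- function(x, ...) {
  rows <- list()
  if (!is.null(x$bp)) {
    rows$bp <- tibble::tibble(
      analysis = "bp_rank_sum", term = "map_beat6",
      estimate = x$bp$beat6$statistic, p_value = x$bp$beat6$p_value)
    rows$bpcor <- tibble::tibble(
      analysis = "bp_inhibition_spearman", term = "map_beat6",
      estimate = x$bp$correlation$r, p_value = x$bp$correlation$p_value)
  }
  if (!is.null(x$window_corr)) {
    rows$win <- tibble::tibble(
      analysis = "generic_window_spearman",
      term = paste(x$window_corr$roi, x$window_corr$condition, sep = "_"),
      estimate = x$window_corr$r, p_value = x$window_corr$p_value)
  }
  if (!is.null(x$clusters)) {
    for (r in names(x$clusters)) {
      for (p in names(x$clusters[[r]])) {
        cc <- x$clusters[[r]][[p]]$cluster_correlations
        if (nrow(cc) > 0) {
          rows[[paste0("cl_", r, p)]] <- tibble::tibble(
            analysis = "cluster_power_spearman",
            term = paste(r, p, "cluster", cc$cluster, sep = "_"),
            estimate = cc$r, p_value = cc$p_value)
        }
      }
    }
  }
  if (!is.null(x$thickness_cor)) {
    rows$th <- tibble::tibble(
      analysis = "thickness_spearman", term = x$thickness_cor$roi,
      estimate = x$thickness_cor$r, p_value = x$thickness_cor$p_bonferroni)
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.msna_study
#' @export
glance.msna_study <- function(x, ...) {
  n_sig_clusters <- 0L
  if (!is.null(x$clusters)) {
    n_sig_clusters <- sum(vapply(unlist(x$clusters, recursive = FALSE),
                                 function(cl) sum(cl$clusters$significant),
                                 integer(1)))
  }
  tibble::tibble(
    n_subjects = x$spec$n_subjects,
    seed = x$manifest$seed,
    n_inhibitors = if (!is.null(x$profiles))
      sum(x$profiles$group == "Inhibitor") else
      sum(x$ground_truth$group == "Inhibitor"),
    bp_beat6_p = if (!is.null(x$bp)) x$bp$beat6$p_value else NA_real_,
    n_significant_clusters = n_sig_clusters,
    config_hash = x$manifest$config_hash
  )
}
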