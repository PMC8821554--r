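#' Bilateral rostral-ACC thickness
#'
#' Emulates a bilateral rostral-ACC region by averaging the left and right
#' label estimates per subject. Both hemispheres must be present — a
#' missing hemisphere is an error, never a silent single-side fallback.
#'
#' @param thickness A thickness table with `subject`, `racc_left`,
#'   `racc_right` columns (mm).
#' @return Tibble: `subject`, `racc` (mm).
#' @export
#' @examples
#' bilateral_racc(tibble::tibble(subject = 1, racc_left = 2.8,
#'                               racc_right = 3.0))
bilateral_racc <- function(thickness) {
  assert_that(all(c("racc_left", "racc_right") %in% names(thickness)),
              "both rACC hemispheres are required (racc_left, racc_right)")
  assert_that(!anyNA(thickness$racc_left) && !anyNA(thickness$racc_right),
              "missing hemisphere thickness value")
  tibble::tibble(subject = thickness$subject,
                 racc = (thickness$racc_left + thickness$racc_right) / 2)
}

#' Correlate ROI cortical thickness with MSNA inhibition
#'
#' Spearman correlations (mid-ranks for ties; exact p for n <= 10, t
#' approximation above) between each pre-selected ROI's thickness and
#' subject inhibition, Bonferroni-corrected over the number of pre-selected
#' ROIs (default 3: insula, rostral ACC, Rolandic).
#'
#' The bilateral rACC estimate is the left/right mean; the insula is
#' reported bilaterally and per hemisphere (the side used in the
#' electrophysiological analysis is the one contralateral to stimulation).
#'
#' @param thickness Thickness table (see [gen_thickness()] for the shape).
#' @param inhibition Per-subject inhibition values, aligned with
#'   `thickness$subject` order.
#' @param n_rois Number of pre-selected ROIs for the Bonferroni factor
#'   (default 3).
#' @param rois Named list mapping reported ROI name -> column(s) averaged
#'   to form its thickness estimate.
#' @return Tibble of class `msna_thickness_cor`: `roi`, `r`, `p_value`,
#'   `p_bonferroni` (`= min(1, n_rois * p)`), `n`, `in_correction` (whether
#'   the ROI is one of the pre-selected set the correction covers).
#' @examples
#' # tables in the shape of a FreeSurfer Qdec ROI export drop in directly;
#' # a small synthetic example ships with the package:
#' path <- system.file("extdata", "thickness_synthetic.csv",
#'                     package = "msnacor")
#' tab <- utils::read.csv(path)
#' thickness_correlation(tab[, 1:6], tab$inhibition)
#' @export
thickness_correlation <- function(thickness, inhibition, n_rois = 3,
                                  rois = NULL) {
  assert_that(length(inhibition) == nrow(thickness),
              "one inhibition value per table row required")
  if (is.null(rois)) {
    rois <- list(
      racc = c("racc_left", "racc_right"),
      insula = c("insula_left", "insula_right"),
      rolandic = "rolandic",
      insula_left = "insula_left",
      insula_right = "insula_right"
    )
  }
  preselected <- c("racc", "insula", "rolandic")
  purrr::imap_dfr(rois, function(cols, name) {
    vals <- rowMeans(thickness[, cols, drop = FALSE])
    st <- spearman_test(vals, inhibition)
    tibble::tibble(
      roi = name, r = st$r, p_value = st$p_value,
      p_bonferroni = min(1, n_rois * st$p_value),
      n = st$n,
      in_correction = name %in% preselected
    )
  }) -> out
  class(out) <- c("msna_thickness_cor", class(out))
  out
}
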