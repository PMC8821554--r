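#' Generate a complete synthetic cohort
#'
#' Draws subject-level ground truth (inhibition, group, coupling latents)
#' and then every recording the pipeline consumes: cardiac R-wave series,
#' integrated neurograms under both stimulation variants, beat-aligned blood
#' pressure, ROI source epochs, and a cortical-thickness table. All draws
#' derive deterministically from `spec$seed` via per-subject, per-stage
#' sub-streams, so identical specs give bit-identical cohorts and single
#' stages can be regenerated independently.
#'
#' Subject inhibition is drawn from the truncated normal
#' `N(inhibition_mean, inhibition_sd^2)` capped at +100%; when
#' `spec$outlier_inhibition` is set, exactly one subject (the last) is forced
#' to that value. Group labels apply the strict `> 30%` Inhibitor rule to the
#' ground-truth inhibition. The inter-trial-interval sequence is drawn once
#' and shared by all subjects, as in the experimental design.
#'
#' @param spec A [cohort_spec()].
#' @param n_trials Trials per session (default 72).
#' @param iti_menu Inter-trial-interval menu in seconds (default 30/45/60).
#' @param components Character subset of
#'   `c("neurogram", "bp", "source", "thickness")` selecting which heavy
#'   recordings to generate (cardiac series and protocols are always
#'   produced). Defaults to all.
#' @param rois ROI labels for source epochs.
#' @return Object of class `msna_cohort`: list with
#'   * `spec`, `n_trials`, `iti_sequence`
#'   * `subjects`: tibble (`subject`, `inhibition`, `group`, `heart_rate`,
#'     list-columns `cardiac`, `protocol_micro`, `protocol_meg`, and, when
#'     generated, `neurogram`, `source_epochs`)
#'   * `bp_beats`, `thickness` tibbles (when generated)
#'   * `ground_truth`: list with per-subject inhibition, group, coupling
#'     latents and the injected cluster window — never consumed by analysis
#'     stages.
#' @export
#' @examples
#' cohort <- gen_cohort(cohort_spec(n_subjects = 3, seed = 1), n_trials = 4,
#'                      components = "thickness")
#' cohort$subjects$inhibition
gen_cohort <- function(spec,
                       n_trials = 72,
                       iti_menu = c(30, 45, 60),
                       components = c("neurogram", "bp", "source",
                                      "thickness"),
                       rois = c("racc", "insula", "rolandic")) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  components <- match.arg(components, several.ok = TRUE)
  n <- spec$n_subjects
  seed <- spec$seed

  # subject-level ground truth
  truth <- with_seed(stage_seed(seed, 0L, stage_codes[["inhibition"]]), {
    draw_trunc <- function(k) {
      x <- numeric(0)
      while (length(x) < k) {
        y <- stats::rnorm(k, spec$inhibition_mean, spec$inhibition_sd)
        x <- c(x, y[y <= 100])
      }
      x[seq_len(k)]
    }
    inhibition <- draw_trunc(n)
    if (!is.null(spec$outlier_inhibition)) {
      inhibition[n] <- spec$outlier_inhibition
    }
    heart_rate <- pmax(40, stats::rnorm(n, spec$heart_rate_mean,
                                        spec$heart_rate_sd))
    list(inhibition = inhibition, heart_rate = heart_rate)
  })
  inhibition <- truth$inhibition
  group <- classify_inhibitor(inhibition)

  # shared ITI schedule
  iti_sequence <- with_seed(stage_seed(seed, 0L, stage_codes[["protocol"]]),
                            sample_iti(iti_menu, n_trials))

  rr_nominal <- 60 / spec$heart_rate_mean
  duration <- 30 + sum(iti_sequence) + n_trials * 8 * rr_nominal * 1.2 + 60

  subjects <- tibble::tibble(
    subject = seq_len(n),
    inhibition = inhibition,
    group = group,
    heart_rate = truth$heart_rate
  )
  subjects$cardiac <- lapply(seq_len(n), function(i) {
    gen_cardiac(duration, truth$heart_rate[i],
                stage_seed(seed, i, stage_codes[["cardiac"]]))
  })
  subjects$protocol_micro <- lapply(seq_len(n), function(i) {
    gen_protocol(subjects$cardiac[[i]], "microneurography",
                 n_trials = n_trials, iti_sequence = iti_sequence)
  })
  subjects$protocol_meg <- lapply(seq_len(n), function(i) {
    gen_protocol(subjects$cardiac[[i]], "meg",
                 n_trials = n_trials, iti_sequence = iti_sequence)
  })

  if ("neurogram" %in% components) {
    subjects$neurogram <- lapply(seq_len(n), function(i) {
      gen_neurogram(subjects$cardiac[[i]], inhibition[i],
                    subjects$protocol_micro[[i]], spec,
                    stage_seed(seed, i, stage_codes[["neurogram"]]))
    })
  }

  rebound_latent <- rep(NA_real_, n)
  if ("source" %in% components) {
    # draw latents in a dedicated stream so they are part of ground truth
    eps <- with_seed(stage_seed(seed, 0L, stage_codes[["source"]]),
                     stats::rnorm(n))
    z <- (inhibition - spec$inhibition_mean) / spec$inhibition_sd
    c_r <- spec$rebound_coupling
    rebound_latent <- c_r * z + sqrt(max(0, 1 - c_r^2)) * eps
    subjects$source_epochs <- lapply(seq_len(n), function(i) {
      gen_source_epochs(inhibition[i], subjects$protocol_meg[[i]], spec,
                        stage_seed(seed, i, stage_codes[["source"]]),
                        rois = rois, rebound_latent = rebound_latent[i])
    })
  }

  bp_beats <- NULL
  if ("bp" %in% components) {
    bp_beats <- gen_bp_series(subjects, spec,
                              stage_seed(seed, 0L, stage_codes[["bp"]]),
                              n_trials = n_trials)
  }

  thickness <- NULL
  thickness_latent <- rep(NA_real_, n)
  if ("thickness" %in% components) {
    thickness <- gen_thickness(inhibition, spec,
                               stage_seed(seed, 0L,
                                          stage_codes[["thickness"]]))
    thickness_latent <- attr(thickness, "latent")
  }

  rank_cor <- function(x, y) {
    if (anyNA(x) || anyNA(y)) return(NA_real_)
    stats::cor(rank(x), rank(y))
  }
  ground_truth <- list(
    inhibition = inhibition,
    group = group,
    rebound_latent = rebound_latent,
    thickness_latent = thickness_latent,
    cluster_window = list(time = c(0.5, 1.2), freq = c(13, 25)),
    target_rank_corr = list(
      rebound = rank_cor(rebound_latent, inhibition),
      thickness = -rank_cor(thickness_latent, inhibition)
    )
  )

  structure(
    list(spec = spec, n_trials = n_trials, iti_sequence = iti_sequence,
         subjects = subjects, bp_beats = bp_beats, thickness = thickness,
         ground_truth = ground_truth),
    class = "msna_cohort"
  )
}

#' @export
print.msna_cohort <- function(x, ...) {
  cat("<msna_cohort>", nrow(x$subjects), "subjects, seed", x$spec$seed,
      "|", sum(x$subjects$group == "Inhibitor"), "Inhibitors /",
      sum(x$subjects$group == "Non-inhibitor"), "Non-inhibitors\n")
  cat("  components:",
      paste(intersect(c("neurogram", "source_epochs"),
                      names(x$subjects)), collapse = ", "),
      if (!is.null(x$bp_beats)) "bp_beats",
      if (!is.null(x$thickness)) "thickness", "\n")
  invisible(x)
}
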