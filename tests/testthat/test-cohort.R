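spec_small <- function(...) {
  cohort_spec(n_subjects = 4, seed = 11, ...)
}

test_that("identical specs generate bit-identical cohorts", {
  a <- gen_cohort(spec_small(), n_trials = 4, iti_menu = 10,
                  components = c("neurogram", "bp", "thickness"))
  b <- gen_cohort(spec_small(), n_trials = 4, iti_menu = 10,
                  components = c("neurogram", "bp", "thickness"))
  expect_identical(a$subjects$inhibition, b$subjects$inhibition)
  expect_identical(a$subjects$neurogram[[2]]$samples,
                   b$subjects$neurogram[[2]]$samples)
  expect_identical(a$bp_beats, b$bp_beats)
  expect_identical(a$thickness, b$thickness)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  expect_error(cohort_spec(inhibition_sd = 0), "inhibition_sd")
  expect_error(cohort_spec(burst_incidence = 120), "burst_incidence")
  expect_error(cohort_spec(outlier_inhibition = 150), "outlier")
})

test_that("the outlier subject is injected exactly once", {
  co <- gen_cohort(cohort_spec(n_subjects = 20, seed = 3,
                               outlier_inhibition = -132),
                   n_trials = 2, iti_menu = 5, components = "thickness")
  expect_equal(sum(co$subjects$inhibition == -132), 1)
  expect_equal(co$subjects$group[co$subjects$inhibition == -132],
               "Non-inhibitor")
})

test_that("inhibitor fraction matches the truncated-normal tail", {
  co <- gen_cohort(cohort_spec(n_subjects = 1000, seed = 5,
                               inhibition_mean = 40, inhibition_sd = 20),
                   n_trials = 1, iti_menu = 5, components = "thickness")
  frac <- mean(co$subjects$inhibition > 30)
  p <- (pnorm(100, 40, 20) - pnorm(30, 40, 20)) / pnorm(100, 40, 20)
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(frac - p), 3 * se)
  expect_true(all(co$subjects$inhibition <= 100))
  # group labels equal the classifier applied to ground truth
  expect_identical(co$subjects$group,
                   classify_inhibitor(co$subjects$inhibition))
})

test_that("protocols respect the R-wave-locked timing rules", {
  cardiac <- gen_cardiac(4200, heart_rate = 60, seed = 2)
  meg <- gen_protocol(cardiac, "meg", seed = 7)
  expect_equal(max(meg$trial), 72)
  expect_equal(nrow(meg), 72 * 3)
  expect_equal(meg$onset_s - meg$r_time, rep(0.2, nrow(meg)))
  expect_true(all(attr(meg, "iti_sequence") %in% c(30, 45, 60)))
  # alternating heartbeats: within-trial pulse intervals differ by 2
  strides <- meg |>
    dplyr::summarise(d = list(diff(interval)), .by = trial)
  expect_true(all(unlist(strides$d) == 2))
  # no two pulses share a cardiac interval within a trial
  expect_false(any(duplicated(meg[, c("trial", "interval")])))

  micro <- gen_protocol(cardiac, "microneurography", n_trials = 20,
                        iti_menu = 30, seed = 7)
  expect_equal(nrow(micro), 20 * 5)
  strides <- micro |>
    dplyr::summarise(d = list(diff(interval)), .by = trial)
  expect_true(all(unlist(strides$d) == 1))
  expect_true(all(attr(micro, "iti_sequence") == 30))
})

test_that("a too-short cardiac series raises a truncation error", {
  cardiac <- gen_cardiac(60, heart_rate = 60, seed = 2)
  expect_error(gen_protocol(cardiac, "meg", n_trials = 72, seed = 1),
               "too short")
})

test_that("neurogram inhibition scaling matches its definition", {
  spec <- cohort_spec(n_subjects = 2, seed = 9)
  cardiac <- gen_cardiac(1400, heart_rate = 60, seed = 4)
  prot <- gen_protocol(cardiac, "microneurography", n_trials = 72,
                       iti_menu = 10, seed = 4)
  post <- unique(prot$interval)

  # complete inhibition silences every post-stimulus burst
  ng100 <- gen_neurogram(cardiac, 100, prot, spec, seed = 21)
  expect_true(all(ng100$truth$amplitude[post] == 0))
  expect_true(all(ng100$samples >= 0))

  # -200% triples the post-stimulus mean amplitude (3 SE over 360 intervals)
  ng <- gen_neurogram(cardiac, -200, prot, spec, seed = 22)
  base_idx <- setdiff(seq_len(nrow(ng$truth)), post)
  m_base <- mean(ng$truth$amplitude[base_idx])
  m_post <- mean(ng$truth$amplitude[post])
  se <- stats::sd(ng$truth$amplitude[post]) / sqrt(length(post))
  expect_lt(abs(m_post - 3 * m_base), 3 * se)

  # zero inhibition leaves the post-window distribution at baseline
  ng0 <- gen_neurogram(cardiac, 0, prot, spec, seed = 23)
  ks <- suppressWarnings(
    stats::ks.test(ng0$truth$amplitude[post],
                   ng0$truth$amplitude[base_idx]))
  expect_gt(ks$p.value, 0.01)

  expect_error(gen_neurogram(cardiac, 150, prot, spec, seed = 1),
               "cannot exceed")
})

test_that("source epoch rebound couples to inhibition as configured", {
  prot <- tibble::tibble(trial = rep(1:6, each = 3), pulse = rep(1:3, 6),
                         interval = seq_len(18))
  n <- 20
  inh <- seq(-80, 90, length.out = n)

  # coupling 1 with dominant oscillation: rank correlation exactly 1
  spec1 <- cohort_spec(n_subjects = n, seed = 1, rebound_coupling = 1)
  pow1 <- vapply(seq_len(n), function(i) {
    src <- gen_source_epochs(inh[i], prot, spec1, seed = 100 + i,
                             rois = "rolandic", beta_amp = 1000)
    window_var(src$epochs$rolandic$p2, src$times, 0.6, 1.1)
  }, numeric(1))
  expect_equal(cor(rank(pow1), rank(inh)), 1)

  # coupling 0: no systematic relation
  spec0 <- cohort_spec(n_subjects = n, seed = 1, rebound_coupling = 0)
  pow0 <- vapply(seq_len(n), function(i) {
    src <- gen_source_epochs(inh[i], prot, spec0, seed = 300 + i,
                             rois = "rolandic", beta_amp = 1000)
    window_var(src$epochs$rolandic$p2, src$times, 0.6, 1.1)
  }, numeric(1))
  expect_lt(abs(cor(pow0, inh, method = "spearman")), 0.45)

  # rebound window exceeds desynchronization window for responding epochs
  src <- gen_source_epochs(60, prot, spec1, seed = 5, rois = "rolandic",
                           beta_amp = 3)
  reb <- window_var(src$epochs$rolandic$p2, src$times, 0.6, 1.1)
  des <- window_var(src$epochs$rolandic$p2, src$times, 0.05, 0.4)
  expect_gt(reb, des)

  # rACC specificity: no rebound after pulse 1
  src_acc <- gen_source_epochs(60, prot, spec1, seed = 6, rois = "racc",
                               beta_amp = 1000)
  reb1 <- window_var(src_acc$epochs$racc$p1, src_acc$times, 0.6, 1.1)
  reb2 <- window_var(src_acc$epochs$racc$p2, src_acc$times, 0.6, 1.1)
  expect_gt(reb2, reb1 * 1.5)
})

test_that("sensor projection follows the forward model", {
  prot <- tibble::tibble(trial = rep(1:4, each = 3), pulse = rep(1:3, 4),
                         interval = seq_len(12))
  spec <- cohort_spec(n_subjects = 2, seed = 1)
  src <- gen_source_epochs(50, prot, spec, seed = 2, rois = "rolandic")
  lf <- gen_leadfields(n_channels = 8, rois = "rolandic",
                       points_per_roi = 3, seed = 3)

  # noise-free single source: sensor data has rank 1
  sens <- gen_sensor_epochs(src, lf, snr = Inf, seed = 4)
  x <- sens$epochs$p1[1, , ]
  sv <- svd(x)$d
  expect_lt(sv[2] / sv[1], 1e-10)

  # with noise: covariance ~ l P l' + sigma^2 I (Frobenius within 15%)
  sens_n <- gen_sensor_epochs(src, lf, snr = 2, seed = 5)
  cv <- compute_covariance(sens_n)
  pt <- sens_n$source_points[["rolandic"]]
  l <- lf$leadfield[[which(lf$point == pt)]]
  p_src <- mean(vapply(names(src$epochs$rolandic), function(cn) {
    mean(apply(src$epochs$rolandic[[cn]], 1, var))
  }, numeric(1)))
  pred <- tcrossprod(l) * p_src + diag(8) * sens_n$noise_sd^2
  rel <- norm(cv$cov - pred, "F") / norm(pred, "F")
  expect_lt(rel, 0.15)

  expect_error(gen_sensor_epochs(src, gen_leadfields(8, "racc", 2, 1),
                                 snr = 1, seed = 1), "missing")
})

test_that("blood-pressure generator produces the group-specific rise", {
  spec <- cohort_spec(n_subjects = 10, seed = 2, bp_rise_nonin = 5)
  subjects <- tibble::tibble(
    subject = 1:10,
    group = rep(c("Inhibitor", "Non-inhibitor"), each = 5),
    heart_rate = rep(60, 10))
  bp <- gen_bp_series(subjects, spec, seed = 8, n_trials = 30)
  beats <- align_beats(bp)
  at6 <- beats[beats$beat == 6 & beats$measure == "map", ]
  m_in <- mean(at6$change[at6$group == "Inhibitor"])
  m_non <- mean(at6$change[at6$group == "Non-inhibitor"])
  expect_lt(abs(m_in), 0.5)        # Inhibitors flat at beat 6
  expect_gt(m_non, 3)              # Non-inhibitors rise toward bp_rise

  # zero effect size: groups indistinguishable more often than not
  spec0 <- cohort_spec(n_subjects = 10, seed = 2, bp_rise_nonin = 0)
  ps <- vapply(1:10, function(k) {
    bp0 <- gen_bp_series(subjects, spec0, seed = 100 + k, n_trials = 10)
    compare_groups(align_beats(bp0), beat = 6)$p_value
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.3)
})

test_that("thickness tables respect coupling and physical range", {
  spec1 <- cohort_spec(n_subjects = 20, seed = 4, thickness_coupling = 1)
  inh <- seq(-60, 90, length.out = 20)
  th <- gen_thickness(inh, spec1, seed = 5, measurement_sd = 0)
  racc <- bilateral_racc(th)$racc
  expect_equal(cor(racc, inh, method = "spearman"), -1)

  spec0 <- cohort_spec(n_subjects = 20, seed = 4, thickness_coupling = 0)
  th0 <- gen_thickness(inh, spec0, seed = 6)
  expect_lt(abs(cor(bilateral_racc(th0)$racc, inh, method = "spearman")),
            0.45)

  # plausible range enforced over many draws
  spec_big <- cohort_spec(n_subjects = 2000, seed = 1,
                          thickness_coupling = 0.5)
  th_big <- gen_thickness(rnorm(2000, 30, 35), spec_big, seed = 7,
                          measurement_sd = 0.5)
  vals <- unlist(th_big[, -1])
  expect_true(all(vals >= 1.5 & vals <= 4.5))
})
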