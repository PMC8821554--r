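test_that("inhibition statistic reproduces its defining worked examples", {
  # complete post-stimulus absence -> +100%
  fx <- make_trial_bursts(72, base_amp = 2, post_amp = 0)
  expect_equal(compute_inhibition(fx$bursts, fx$protocol)$inhibition, 100)

  # post equal to baseline -> 0%
  fx <- make_trial_bursts(72, base_amp = 2, post_amp = 2)
  expect_equal(compute_inhibition(fx$bursts, fx$protocol)$inhibition, 0)

  # post at three times baseline (bursts 2x higher than baseline) -> -200%
  fx <- make_trial_bursts(72, base_amp = 2, post_amp = 6)
  expect_equal(compute_inhibition(fx$bursts, fx$protocol)$inhibition, -200)

  # baseline 2, post 1 -> 50% (hand arithmetic)
  fx <- make_trial_bursts(10, base_amp = 2, post_amp = 1)
  expect_equal(compute_inhibition(fx$bursts, fx$protocol)$inhibition, 50)

  # zero baseline activity is an undefined statistic, not a number
  fx <- make_trial_bursts(5, base_amp = 0, post_amp = 1)
  expect_error(compute_inhibition(fx$bursts, fx$protocol), "undefined")
})

test_that("inhibition is scale invariant and monotone in post amplitudes", {
  fx <- make_trial_bursts(20, base_amp = 2, post_amp = 1.2)
  i0 <- compute_inhibition(fx$bursts, fx$protocol)$inhibition
  for (c_scale in c(0.1, 3, 250)) {
    scaled <- fx$bursts
    scaled$amplitude <- scaled$amplitude * c_scale
    expect_equal(compute_inhibition(scaled, fx$protocol)$inhibition, i0)
  }
  # decreasing any single post amplitude never decreases inhibition
  post_ints <- fx$protocol$interval
  for (k in post_ints[c(1, 7, 20)]) {
    dec <- fx$bursts
    dec$amplitude[dec$interval == k] <- 0.2
    expect_gte(compute_inhibition(dec, fx$protocol)$inhibition, i0)
  }
  # the statistic never exceeds 100 and hits it only at total absence
  expect_lte(i0, 100)
})

test_that("classification applies the strict 30% rule", {
  expect_equal(classify_inhibitor(c(30.0001, 30, -132, 100)),
               c("Inhibitor", "Non-inhibitor", "Non-inhibitor", "Inhibitor"))
  # boundary sits exactly at the configured threshold for any threshold
  for (thr in c(0, 15, 30, 62.5)) {
    eps <- 1e-9
    expect_equal(classify_inhibitor(thr, thr), "Non-inhibitor")
    expect_equal(classify_inhibitor(thr + eps, thr), "Inhibitor")
    expect_equal(classify_inhibitor(thr - eps, thr), "Non-inhibitor")
  }
  expect_error(classify_inhibitor(NaN), "finite")
})

test_that("burst detection recovers noiseless amplitudes", {
  spec <- cohort_spec(n_subjects = 2, seed = 1, burst_incidence = 60)
  cardiac <- gen_cardiac(120, heart_rate = 60, seed = 3)
  ng <- gen_neurogram(cardiac, 0, NULL, spec, seed = 4, noise_sd = 0)
  det <- detect_bursts(ng)
  truth <- ng$truth
  present <- truth$amplitude > 0
  # detected amplitudes within 2% of ground truth, absences exact
  expect_true(all(abs(det$amplitude[present] - truth$amplitude[present]) /
                    truth$amplitude[present] < 0.02))
  expect_true(all(det$amplitude[!present] == 0))
})

test_that("flat and degenerate recordings are handled", {
  flat <- structure(list(samples = rep(0, 3000), fs = 100,
                         r_times = seq(1, 25, by = 1)),
                    class = "msna_neurogram")
  det <- detect_bursts(flat)
  expect_true(all(det$amplitude == 0))
  expect_error(detect_bursts(list(samples = numeric(0), fs = 100,
                                  r_times = 1:20)), "empty")
  expect_error(detect_bursts(list(samples = rep(0, 100), fs = 100,
                                  r_times = c(1, 2))), "10 cardiac")
  expect_error(detect_bursts(list(samples = rep(0, 100), fs = 100,
                                  r_times = seq_len(20))),
               "beyond")
})

test_that("resting metrics follow their definitions", {
  # 25 bursts over 50 beats in 60 s -> BI 50, BF 25
  bursts <- tibble::tibble(interval = 1:50,
                           amplitude = rep(c(1, 0), 25))
  cardiac <- tibble::tibble(interval = 1:50,
                            r_time = seq(1.2, by = 1.2, length.out = 50))
  rm <- resting_metrics(bursts, cardiac)
  expect_equal(rm$burst_incidence, 50)
  expect_equal(rm$burst_frequency, 25)

  # zero bursts
  none <- tibble::tibble(interval = 1:50, amplitude = rep(0, 50))
  rm0 <- resting_metrics(none, cardiac)
  expect_equal(rm0$burst_incidence, 0)
  expect_equal(rm0$burst_frequency, 0)

  # 44 of 100 intervals -> BI 44.0
  b44 <- tibble::tibble(interval = 1:100,
                        amplitude = c(rep(1, 44), rep(0, 56)))
  c100 <- tibble::tibble(interval = 1:100, r_time = seq_len(100))
  expect_equal(resting_metrics(b44, c100)$burst_incidence, 44)

  # generator-level recovery at large n (binomial sampling error)
  spec <- cohort_spec(n_subjects = 2, seed = 1, burst_incidence = 44.3)
  cardiac_l <- gen_cardiac(3600, heart_rate = 60, seed = 9)
  ng <- gen_neurogram(cardiac_l, 0, NULL, spec, seed = 10)
  det <- detect_bursts(ng)
  est <- resting_metrics(det, cardiac_l)$burst_incidence
  n_beats <- nrow(cardiac_l)
  se <- 100 * sqrt(0.443 * 0.557 / n_beats)
  expect_lt(abs(est - 44.3), 3 * se + 1) # +1%: detection floor losses
})

test_that("dummy calibration computes the 95% deviation bound", {
  # engineered deviations {-31,...,29} x2 -> hand-enumerated bound 31
  devs <- c(-31, -10, -5, 0, 2, 4, 8, 12, 20, 29)
  mk <- function(d) {
    amp <- rep(2, 30)
    amp[10] <- 2 * (1 - d / 100)
    list(bursts = tibble::tibble(interval = 1:30, amplitude = amp),
         protocol = tibble::tibble(trial = 1, pulse = 1, interval = 10))
  }
  subj <- lapply(rep(devs, 2), mk)
  cal <- calibrate_dummy(lapply(subj, `[[`, "bursts"),
                         lapply(subj, `[[`, "protocol"))
  expect_equal(sort(abs(unlist(cal$deviations))),
               sort(rep(abs(devs), 2)))
  expect_equal(cal$bound, 31) # 95th percentile of the 20 absolute values
  expect_gte(cal$bound, 0)

  # all-zero deviations -> bound 0
  subj0 <- lapply(rep(0, 6), mk)
  expect_equal(calibrate_dummy(lapply(subj0, `[[`, "bursts"),
                               lapply(subj0, `[[`, "protocol"))$bound, 0)

  expect_warning(calibrate_dummy(lapply(subj0[1:3], `[[`, "bursts"),
                                 lapply(subj0[1:3], `[[`, "protocol")),
                 "unstable")
})

test_that("null-subject variability calibrates near the 30% bound", {
  # dummy triggers on unstimulated neurograms: the 95% bound of the
  # inhibition statistic's sampling noise should sit near the 30% threshold
  spec <- cohort_spec(n_subjects = 2, seed = 1)
  n_sub <- 24
  series <- vector("list", n_sub)
  prots <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    cardiac <- gen_cardiac(1250, heart_rate = 62, seed = 500 + i)
    prot <- gen_protocol(cardiac, "microneurography", n_trials = 72,
                         iti_menu = 8, seed = 600 + i)
    ng <- gen_neurogram(cardiac, 0, NULL, spec, seed = 700 + i)
    bursts <- ng$truth
    bursts$detected <- bursts$amplitude > 0
    series[[i]] <- bursts
    prots[[i]] <- prot
  }
  cal <- calibrate_dummy(series, prots)
  expect_gt(cal$bound, 15)
  expect_lt(cal$bound, 45)
})

test_that("estimated inhibition tracks ground truth across its range", {
  # with burst-amplitude CV 1 (the dummy-bound calibration) the statistic
  # itself has sampling SD ~15% x |ratio| at 60 trials; tolerances reflect
  # that inherent noise, not detector error
  spec <- cohort_spec(n_subjects = 2, seed = 1)
  truths <- c(-150, 0, 50, 100)
  ests <- vapply(seq_along(truths), function(k) {
    cardiac <- gen_cardiac(1100, heart_rate = 60, seed = 40 + k)
    prot <- gen_protocol(cardiac, "microneurography", n_trials = 60,
                         iti_menu = 10, seed = 40 + k)
    ng <- gen_neurogram(cardiac, truths[k], prot, spec, seed = 50 + k,
                        noise_sd = 0.005)
    prof <- compute_inhibition(detect_bursts(ng), prot)
    expect_equal(prof$n_trials_used, 60)
    prof$inhibition
  }, numeric(1))
  # complete absence: exact up to rare noise peaks crossing the detector
  expect_gt(ests[4], 99.5)
  expect_true(all(abs(ests - truths) < 3 * 15 * pmax(1, 1 - truths / 100)))
  expect_equal(order(ests), order(truths))
})
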