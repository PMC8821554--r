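# Toy single-source sensor data: one leadfield column times a source time
# series plus optional white noise, as trials x channels x time arrays.
toy_sensor <- function(l, src_base, src_cond, noise_sd = 0, seed = 1) {
  set.seed(seed)
  build <- function(s) {
    n_tr <- nrow(s); n_ch <- length(l); n_t <- ncol(s)
    arr <- array(0, c(n_tr, n_ch, n_t))
    for (tr in seq_len(n_tr)) {
      arr[tr, , ] <- outer(l, s[tr, ]) +
        matrix(rnorm(n_ch * n_t, 0, noise_sd), n_ch, n_t)
    }
    arr
  }
  make_sensor_epochs(list(baseline = build(src_base), p1 = build(src_cond)),
                     fs = 100, times = seq(0, by = 0.01,
                                           length.out = ncol(src_base)))
}

test_that("LCMV weights match the hand-inverted closed form", {
  # C = diag(2, 1), l = (1, 1): w = C^-1 l / (l' C^-1 l) = (1/3, 2/3)
  w <- lcmv_filter(c(1, 1), diag(c(2, 1)), lambda = 0)$weights
  expect_equal(w, c(1 / 3, 2 / 3), tolerance = 1e-12)
  # identity covariance, unit leadfield: w = e1
  expect_equal(lcmv_filter(c(1, 0, 0), diag(3), lambda = 0)$weights,
               c(1, 0, 0), tolerance = 1e-12)
})

test_that("unit-gain constraint holds to 1e-10 over random problems", {
  set.seed(11)
  for (rep in 1:20) {
    n_ch <- sample(4:12, 1)
    A <- matrix(rnorm(n_ch^2), n_ch)
    C <- crossprod(A) + diag(n_ch)
    l <- rnorm(n_ch)
    f <- lcmv_filter(l, C, lambda = 0.05)
    expect_lt(abs(sum(f$weights * f$leadfield) - 1), 1e-10)
  }
  # free-orientation leadfield: unit gain along the chosen orientation
  L <- matrix(rnorm(8 * 3), 8, 3)
  C <- crossprod(matrix(rnorm(64), 8)) + diag(8)
  f <- lcmv_filter(L, C, lambda = 0.05)
  expect_equal(length(f$orientation), 3)
  expect_lt(abs(sum(f$weights * (L %*% f$orientation)) - 1), 1e-10)
})

test_that("covariance estimation is unbiased and excision-aware", {
  set.seed(5)
  arr <- array(rnorm(40 * 6 * 50, 0, 2), c(40, 6, 50))
  cv <- compute_covariance(list(baseline = arr))
  expect_equal(mean(diag(cv$cov)), 4, tolerance = 0.1)
  expect_lt(max(abs(cv$cov[upper.tri(cv$cov)])), 0.3)
  expect_true(isSymmetric(cv$cov))
  ev <- eigen(cv$cov, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))

  # one common signal: top eigenvalue dominates per l P l' + sigma^2 I
  l <- rnorm(6)
  s <- matrix(rnorm(40 * 50), 40, 50)
  arr2 <- array(0, c(40, 6, 50))
  for (tr in 1:40) arr2[tr, , ] <- outer(l, s[tr, ]) +
    matrix(rnorm(300, 0, 0.1), 6, 50)
  cv2 <- compute_covariance(list(baseline = arr2))
  ev2 <- eigen(cv2$cov, only.values = TRUE)$values
  expect_gt(ev2[1] / ev2[2], 50)

  # excising every sample is an error
  sens <- make_sensor_epochs(list(p1 = arr), fs = 100,
                             times = seq_len(50) / 100,
                             excise = rep(TRUE, 50))
  expect_error(compute_covariance(sens), "every sample")
})

test_that("source power contrast isolates condition changes", {
  set.seed(21)
  l <- rnorm(6); l <- l / sqrt(sum(l^2))
  s_base <- matrix(rnorm(30 * 100), 30, 100)
  sens_same <- toy_sensor(l, s_base, s_base, noise_sd = 0)
  lf <- tibble::tibble(point = 1L, roi = "rolandic", x = 0, y = 0, z = 0,
                       leadfield = list(l))
  cv <- compute_covariance(sens_same)
  fl <- lcmv_filters(lf, cv)
  contr <- source_power_contrast(fl, sens_same)
  expect_equal(contr$contrast, 0, tolerance = 1e-10)

  # condition variance doubled -> contrast ~ +1; halved -> negative
  sens_up <- toy_sensor(l, s_base, s_base * sqrt(2), noise_sd = 0)
  c_up <- source_power_contrast(lcmv_filters(lf, compute_covariance(sens_up)),
                                sens_up)
  expect_equal(c_up$contrast, 1, tolerance = 0.05)
  sens_dn <- toy_sensor(l, s_base, s_base * 0.5, noise_sd = 0)
  c_dn <- source_power_contrast(lcmv_filters(lf, compute_covariance(sens_dn)),
                                sens_dn)
  expect_lt(c_dn$contrast, 0)
})

test_that("vertex selection keeps points above 60% of the ROI peak", {
  contrasts <- tibble::tibble(point = 1:3, roi = "racc", condition = "p1",
                              power = 1, power_baseline = 1,
                              contrast = c(100, 70, 50))
  lf <- tibble::tibble(point = 1:3, roi = "racc", x = 0, y = 0, z = 0,
                       leadfield = lapply(1:3, function(i) {
                         v <- rep(0, 4); v[i] <- 1; v
                       }))
  arr <- array(rnorm(2 * 4 * 10), c(2, 4, 10))
  sens <- make_sensor_epochs(list(baseline = arr, p1 = arr), fs = 100,
                             times = seq_len(10) / 100)
  fl <- lcmv_filters(lf, compute_covariance(sens))
  rs <- select_vertices_and_extract(fl, contrasts, sens, "racc")
  expect_setequal(rs$points, c(1, 2))

  # single-point ROI keeps its point
  rs1 <- select_vertices_and_extract(fl[1, ], contrasts[1, ], sens, "racc")
  expect_equal(rs1$points, 1)

  # all-negative contrasts fall back to the peak with a warning
  neg <- dplyr::mutate(contrasts, contrast = c(-3, -1, -2))
  expect_warning(rs_neg <- select_vertices_and_extract(fl, neg, sens, "racc"),
                 "falling back")
  expect_equal(rs_neg$points, 2)
})

test_that("noiseless single sources localize to the true grid point", {
  set.seed(31)
  hits <- 0
  for (rep in 1:20) {
    lf <- gen_leadfields(n_channels = 8, rois = "rolandic",
                         points_per_roi = 6, seed = rep)
    true_pt <- sample(6, 1)
    s_base <- matrix(rnorm(20 * 80, 0, 0.3), 20, 80)
    s_act <- matrix(rnorm(20 * 80, 0, 1.5), 20, 80)
    l <- lf$leadfield[[true_pt]]
    sens <- toy_sensor(l, s_base, s_act, noise_sd = 0.02, seed = 40 + rep)
    fl <- lcmv_filters(lf, compute_covariance(sens))
    contr <- source_power_contrast(fl, sens)
    if (contr$point[which.max(contr$contrast)] == true_pt) hits <- hits + 1
  }
  expect_equal(hits, 20)
})

test_that("extracted trial series recover the injected source", {
  set.seed(41)
  lf <- gen_leadfields(n_channels = 8, rois = "rolandic",
                       points_per_roi = 4, seed = 3)
  l <- lf$leadfield[[2]]
  s_base <- matrix(rnorm(10 * 80, 0, 0.3), 10, 80)
  s_act <- matrix(rnorm(10 * 80, 0, 2), 10, 80)
  sens <- toy_sensor(l, s_base, s_act, noise_sd = 0.01, seed = 8)
  fl <- lcmv_filters(lf, compute_covariance(sens))
  contr <- source_power_contrast(fl, sens)
  rs <- select_vertices_and_extract(fl, contr, sens, "rolandic")
  for (tr in c(1, 5)) {
    expect_gt(abs(cor(rs$series$p1[tr, ], s_act[tr, ])), 0.95)
  }
})

test_that("results are invariant to a consistent channel permutation", {
  set.seed(51)
  lf <- gen_leadfields(n_channels = 6, rois = "rolandic",
                       points_per_roi = 3, seed = 4)
  l <- lf$leadfield[[1]]
  s_base <- matrix(rnorm(8 * 60, 0, 0.5), 8, 60)
  s_act <- matrix(rnorm(8 * 60, 0, 1.5), 8, 60)
  sens <- toy_sensor(l, s_base, s_act, noise_sd = 0.05, seed = 9)
  contr <- source_power_contrast(
    lcmv_filters(lf, compute_covariance(sens)), sens)

  perm <- sample(6)
  lf_p <- lf
  lf_p$leadfield <- lapply(lf$leadfield, function(v) v[perm])
  sens_p <- sens
  sens_p$epochs <- lapply(sens$epochs, function(a) a[, perm, , drop = FALSE])
  contr_p <- source_power_contrast(
    lcmv_filters(lf_p, compute_covariance(sens_p)), sens_p)
  expect_equal(contr$contrast, contr_p$contrast, tolerance = 1e-10)
})
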