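# Cluster-based permutation correlation on time-frequency maps.

# Union-find connected-component labelling of supra-threshold bins on the
# freq x time lattice (4-neighbourhood, no diagonals). `idx` holds linear
# (column-major, frequency fastest) indices of the bins of one sign.
# Returns an integer root id per bin.
label_components <- function(idx, nf, nt) {
  m <- length(idx)
  if (m == 0) return(integer(0))
  pos <- integer(nf * nt)
  pos[idx] <- seq_len(m)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  fi <- (idx - 1L) %% nf + 1L
  for (k in seq_len(m)) {
    b <- idx[k]
    if (fi[k] < nf && pos[b + 1L] > 0L) { # neighbour up the freq axis
      ra <- find(k); rb <- find(pos[b + 1L])
      if (ra != rb) parent[rb] <- ra
    }
    if (b + nf <= nf * nt && pos[b + nf] > 0L) { # neighbour in time
      ra <- find(k); rb <- find(pos[b + nf])
      if (ra != rb) parent[rb] <- ra
    }
  }
  vapply(seq_len(m), find, integer(1))
}

# max |cluster mass| for one t-map (vector over the full grid, NA/0 = sub-
# threshold handled by caller passing supra indices).
max_cluster_mass <- function(tvec, t_crit, nf, nt) {
  best <- 0
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(tvec) & sgn * tvec > t_crit)
    if (length(idx) == 0) next
    roots <- label_components(idx, nf, nt)
    mass <- vapply(split(tvec[idx], roots), sum, numeric(1))
    best <- max(best, max(abs(mass)))
  }
  best
}

#' Cluster-based permutation correlation against MSNA inhibition
#'
#' Tests whether time-frequency power across subjects correlates with the
#' inhibition covariate while controlling the family-wise error over the
#' whole map. Per bin, the Spearman correlation between subjects' relative
#' power and inhibition is converted to a t statistic; bins exceeding the
#' two-sided cluster-forming threshold (`cluster_alpha`) are clustered by
#' 4-neighbourhood adjacency separately by sign; a cluster's mass is the
#' sum of its bin statistics. The null distribution of the maximum absolute
#' cluster mass (pooled over signs, two-sided) is built from `n_perm`
#' random permutations of the inhibition values, and each observed cluster
#' gets `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' For clusters significant at `alpha`, the relative power is averaged over
#' the cluster's bins per subject and its Spearman correlation with
#' inhibition is reported — the cluster-averaged-power correlation.
#'
#' @param maps An `msna_tfr_maps` object or a subject x freq x time array.
#' @param inhibition Numeric vector of per-subject inhibition values.
#' @param n_perm Number of permutations (default 1000, minimum 100).
#' @param alpha Cluster significance level (default 0.05, two-sided).
#' @param cluster_alpha Per-bin cluster-forming threshold (default 0.05,
#'   two-sided, via the t approximation for the Spearman coefficient).
#' @param seed Seed for the permutation draw.
#' @return Object of class `msna_clusters`: list with `clusters` tibble
#'   (`cluster`, `sign`, `n_bins`, `mass`, `p_value`, `significant`,
#'   `freq_lo`, `freq_hi`, `time_lo`, `time_hi`, list-column `bins`),
#'   `subject_power` tibble for significant clusters (`cluster`, `subject`,
#'   `power`, `inhibition`), `cluster_correlations` tibble (`cluster`, `r`,
#'   `p_value`, `n`), `r_map` (freq x time observed Spearman r), `null_max`,
#'   plus the configuration.
#' @export
cluster_perm_corr <- function(maps, inhibition, n_perm = 1000,
                              alpha = 0.05, cluster_alpha = 0.05,
                              seed = 1) {
  assert_that(n_perm >= 100, "n_perm must be at least 100")
  if (inherits(maps, "msna_tfr_maps")) {
    arr <- maps$power; freqs <- maps$freqs; times <- maps$times
  } else {
    arr <- maps
    freqs <- seq_len(dim(arr)[2]); times <- seq_len(dim(arr)[3])
  }
  ns <- dim(arr)[1]; nf <- dim(arr)[2]; nt <- dim(arr)[3]
  assert_that(ns >= 8, "need at least 8 subjects")
  assert_that(length(inhibition) == ns,
              "one inhibition value per subject required")
  assert_that(stats::sd(inhibition) > 0,
              "inhibition is constant: ranks undefined")

  X <- matrix(arr, ns, nf * nt) # bin = (t-1)*nf + f
  valid <- which(colSums(is.na(X)) == 0)
  assert_that(length(valid) > 0, "no bin is valid across all subjects")
  Xv <- X[, valid, drop = FALSE]
  Rv <- apply(Xv, 2, rank)
  const <- apply(Rv, 2, stats::sd) == 0
  rank_inh <- rank(inhibition)

  t_crit <- stats::qt(1 - cluster_alpha / 2, df = ns - 2)
  r_to_t <- function(r) {
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    r * sqrt((ns - 2) / (1 - r^2))
  }
  expand_t <- function(r_row) {
    r_row[is.na(r_row) | const] <- 0
    tfull <- rep(NA_real_, nf * nt)
    tfull[valid] <- r_to_t(r_row)
    tfull
  }

  r_obs <- as.vector(suppressWarnings(stats::cor(rank_inh, Rv)))
  t_obs <- expand_t(r_obs)

  # observed clusters
  clusters <- list(); masses <- numeric(0); signs <- integer(0)
  bins_list <- list()
  for (sgn in c(1L, -1L)) {
    idx <- which(!is.na(t_obs) & sgn * t_obs > t_crit)
    if (length(idx) == 0) next
    roots <- label_components(idx, nf, nt)
    for (r0 in unique(roots)) {
      b <- idx[roots == r0]
      masses <- c(masses, sum(t_obs[b]))
      signs <- c(signs, sgn)
      bins_list <- c(bins_list, list(b))
    }
  }

  # permutation null of max |mass|
  perm <- with_seed(seed, {
    replicate(n_perm, sample(rank_inh))
  })
  r_null <- suppressWarnings(stats::cor(perm, Rv)) # n_perm x nv
  null_max <- vapply(seq_len(n_perm), function(p) {
    max_cluster_mass(expand_t(r_null[p, ]), t_crit, nf, nt)
  }, numeric(1))

  if (length(masses) > 0) {
    p_vals <- vapply(abs(masses), function(m) {
      (1 + sum(null_max >= m)) / (n_perm + 1)
    }, numeric(1))
    ord <- order(abs(masses), decreasing = TRUE)
    cl_tbl <- tibble::tibble(
      cluster = seq_along(ord),
      sign = signs[ord],
      n_bins = lengths(bins_list)[ord],
      mass = masses[ord],
      p_value = p_vals[ord],
      significant = p_vals[ord] <= alpha,
      freq_lo = vapply(bins_list[ord], function(b)
        min(freqs[(b - 1) %% nf + 1]), numeric(1)),
      freq_hi = vapply(bins_list[ord], function(b)
        max(freqs[(b - 1) %% nf + 1]), numeric(1)),
      time_lo = vapply(bins_list[ord], function(b)
        min(times[(b - 1) %/% nf + 1]), numeric(1)),
      time_hi = vapply(bins_list[ord], function(b)
        max(times[(b - 1) %/% nf + 1]), numeric(1)),
      bins = bins_list[ord]
    )
  } else {
    cl_tbl <- tibble::tibble(
      cluster = integer(0), sign = integer(0), n_bins = integer(0),
      mass = numeric(0), p_value = numeric(0), significant = logical(0),
      freq_lo = numeric(0), freq_hi = numeric(0), time_lo = numeric(0),
      time_hi = numeric(0), bins = list()
    )
  }

  subject_power <- tibble::tibble(cluster = integer(0), subject = integer(0),
                                  power = numeric(0),
                                  inhibition = numeric(0))
  cluster_correlations <- tibble::tibble(cluster = integer(0), r = numeric(0),
                                         p_value = numeric(0),
                                         n = integer(0))
  for (ci in which(cl_tbl$significant)) {
    b <- cl_tbl$bins[[ci]]
    pw <- rowMeans(X[, b, drop = FALSE])
    subject_power <- dplyr::bind_rows(subject_power, tibble::tibble(
      cluster = ci, subject = seq_len(ns), power = pw,
      inhibition = inhibition))
    st <- spearman_test(pw, inhibition)
    cluster_correlations <- dplyr::bind_rows(
      cluster_correlations,
      tibble::tibble(cluster = ci, r = st$r, p_value = st$p_value,
                     n = st$n))
  }

  structure(
    list(clusters = cl_tbl, subject_power = subject_power,
         cluster_correlations = cluster_correlations,
         r_map = matrix(replace(rep(NA_real_, nf * nt), valid, r_obs),
                        nf, nt),
         freqs = freqs, times = times,
         null_max = null_max, n_perm = n_perm, alpha = alpha,
         cluster_alpha = cluster_alpha, t_crit = t_crit, n_subjects = ns),
    class = "msna_clusters"
  )
}

#' @export
print.msna_clusters <- function(x, ...) {
  cat("<msna_clusters>", nrow(x$clusters), "cluster(s),",
      sum(x$clusters$significant), "significant at alpha =", x$alpha,
      "(", x$n_perm, "permutations )\n")
  if (nrow(x$clusters) > 0) {
    print(x$clusters[, c("cluster", "sign", "n_bins", "mass", "p_value",
                         "significant")])
  }
  invisible(x)
}
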