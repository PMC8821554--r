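# Fixtures and independent oracles used across the suite.

# Burst series with a repeated trial structure: `n_base` control intervals
# at `base_amp`, then one stimulated interval per pulse at `post_amp`,
# then `gap` quiet intervals before the next trial. Returns the series and
# the matching minimal protocol table.
make_trial_bursts <- function(n_trials, base_amp = 2, post_amp = 0,
                              n_base = 8, n_pulses = 1, gap = 2) {
  block <- n_base + n_pulses + gap
  n_int <- n_trials * block + n_base
  amp <- rep(base_amp, n_int)
  prot <- list()
  for (tr in seq_len(n_trials)) {
    first <- (tr - 1) * block + n_base + 1
    idx <- first:(first + n_pulses - 1)
    amp[idx] <- post_amp
    prot[[tr]] <- tibble::tibble(trial = tr, pulse = seq_len(n_pulses),
                                 interval = idx)
  }
  list(
    bursts = tibble::tibble(interval = seq_len(n_int), amplitude = amp),
    protocol = dplyr::bind_rows(prot)
  )
}

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n1+n2, n1) group assignments (independent of stats::wilcox.test).
enumerate_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  w_null <- apply(combs, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(y) / 2
  mean(abs(w_null - mu) >= abs(w_obs - mu) - 1e-9)
}

# Spearman rho by the textbook d^2 formula (no ties) — independent of cor().
brute_spearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Band power of a trials x time matrix in a time window: mean variance of
# the signal restricted to the window (used as a TFR-free rebound proxy).
window_var <- function(m, times, lo, hi) {
  sel <- times >= lo & times <= hi
  mean(apply(m[, sel, drop = FALSE], 1, stats::var))
}

# A minimal sensor-epochs object built from explicit arrays.
make_sensor_epochs <- function(epochs, fs, times, excise = NULL) {
  structure(list(epochs = epochs, fs = fs, times = times,
                 excise = excise, source_points = NULL),
            class = "msna_sensor_epochs")
}
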