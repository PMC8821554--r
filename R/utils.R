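# Internal helpers shared across modules.

# Deterministic sub-seed for a (cohort seed, subject, stage) triple so that
# stages can be regenerated independently while the whole cohort stays
# bit-identical under one spec seed. Kept strictly below 2^31 - 1.
stage_seed <- function(seed, subject = 0L, stage = 0L) {
  s <- (as.double(seed) %% 1000003) * 1009 + as.double(subject) * 101 +
    as.double(stage) * 13 + 17
  as.integer(s %% 2147483647)
}

stage_codes <- c(
  inhibition = 1L, cardiac = 2L, protocol = 3L, neurogram = 4L,
  source = 5L, sensor = 6L, bp = 7L, thickness = 8L, leadfield = 9L
)

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# FNV-1a style 32-bit hash of a deparsed object; used for run manifests.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# O(n) sliding-window minimum (van Herk block decomposition). Window = 2h+1
# with h = w %/% 2; edge windows are clamped (approximately, to block
# bounds), which is fine for envelope/baseline estimation.
rolling_min <- function(x, w) {
  n <- length(x)
  if (w <= 1) return(x)
  h <- w %/% 2
  w <- 2L * h + 1L
  pad <- ceiling(n / w) * w
  xp <- c(x, rep(Inf, pad - n))
  m <- matrix(xp, nrow = w)
  left <- as.vector(apply(m, 2, cummin))
  right <- as.vector(apply(m[w:1, , drop = FALSE], 2,
                           cummin)[w:1, , drop = FALSE])
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(pad, seq_len(n) + h)
  pmin(right[lo], left[hi])
}

rolling_max <- function(x, w) -rolling_min(-x, w)

# sample() treats a length-1 numeric as 1:n; guard for singleton ITI menus
sample_iti <- function(menu, n) {
  if (length(menu) == 1) rep(menu, n) else sample(menu, n, replace = TRUE)
}
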