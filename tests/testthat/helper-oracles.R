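# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (no rank(), no cor(), no p.adjust()).

# midranks by explicit counting
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Pearson correlation from explicit sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# BH rejections by exhaustive search over all step-up cutoffs k
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- sort(p)
  ks <- which(ord <= (seq_len(m) / m) * q)
  if (length(ks) == 0L) return(rep(FALSE, m))
  p <= ord[max(ks)]
}

# ICC(3,1) from explicit sums of squares
oracle_icc31 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  ss_tot <- sum((m - grand)^2)
  ms_r <- ss_rows / (n - 1)
  ms_e <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
}

# per-label and pooled Dice by explicit set counts
oracle_dice <- function(a, b) {
  labs <- sort(union(unique(a[a != 0]), unique(b[b != 0])))
  per <- vapply(labs, function(l) {
    nA <- sum(a == l); nB <- sum(b == l); nAB <- sum(a == l & b == l)
    2 * nAB / (nA + nB)
  }, numeric(1))
  nA <- sum(a != 0); nB <- sum(b != 0); nAB <- sum(a != 0 & a == b)
  list(global = 2 * nAB / (nA + nB), per_region = setNames(per, labs))
}

# small phantom shared by several test files (generated once per run)
tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_phantom(phantom_spec(
        n_subjects = 10, n_contrasts = 3, grid_shape = c(20, 20, 14),
        n_regions = 8, n_repeat_subjects = 5, seed = 42))
    }
    cache
  }
})
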