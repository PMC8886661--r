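#' Spearman rank correlation with midranks and pairwise-complete filtering
#'
#' Pearson correlation of average (mid-)ranks. Pairs with a missing value in
#' either vector are dropped first; if either remaining vector is constant the
#' rank correlation is undefined and `NA` is returned.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_n Minimum number of complete pairs required (default 3).
#' @return A single correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @examples
#' spearman_rho(c(1, 2, 3), c(3, 1, 2))
#' @export
spearman_rho <- function(x, y, min_n = 3L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < min_n) {
    stop("fewer than ", min_n, " complete pairs after filtering")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Non-parametric (median/MAD) normalisation
#'
#' Robust analogue of the Z-score: `(x - Md(x)) / MAD(x)` where `MAD` is the
#' raw median absolute deviation about the median, *without* the 1.4826
#' Gaussian consistency factor. By construction the output has median 0 and
#' MAD 1. A vector with `MAD = 0` cannot be normalised; all values become
#' `NA` and a warning is raised.
#'
#' @param x Numeric vector, length at least 2. `NA`s are ignored for the
#'   centre/scale and propagate through.
#' @return An object of class `mad_normalized`: the normalised numeric vector
#'   with attributes `center` (the median) and `scale` (the raw MAD).
#' @examples
#' mad_normalize(1:5)
#' @export
mad_normalize <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values")
  md <- stats::median(x, na.rm = TRUE)
  s <- stats::median(abs(x - md), na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    warning("MAD is zero; normalisation undefined, returning NA")
    out <- rep(NA_real_, length(x))
  } else {
    out <- (x - md) / s
  }
  structure(out, center = md, scale = s, class = "mad_normalized")
}

#' @export
print.mad_normalized <- function(x, ...) {
  cat("<mad_normalized> center =", attr(x, "center"),
      "scale =", attr(x, "scale"), "\n")
  print(as.numeric(x), ...)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values with rejection flags at level `q`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @param q FDR level (default 0.05).
#' @return A tibble with columns `p`, `p_adj`, `reject`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adj = adj, reject = !is.na(adj) & adj <= q)
}

#' Intraclass correlation for test-retest consistency
#'
#' Consistency of single measurements from a subjects-by-sessions table.
#' The default is the two-way ICC(3,1) of Shrout and Fleiss,
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)` with the
#' session effect removed; `model = "oneway"` gives the one-way ICC(1,1)
#' where session differences count as error.
#'
#' @param measurements Numeric matrix, subjects in rows, sessions in columns
#'   (at least 2 of each, no missing values).
#' @param model `"twoway"` (ICC(3,1), default) or `"oneway"` (ICC(1,1)).
#' @return A single ICC value, or `NA_real_` if all measurements are equal.
#' @export
icc_consistency <- function(measurements, model = c("twoway", "oneway")) {
  model <- match.arg(model)
  m <- as.matrix(measurements)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 subjects and >= 2 sessions")
  if (anyNA(m)) stop("missing values not allowed")
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  if (all(m == m[1L])) return(NA_real_)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ms_rows <- ss_rows / (n - 1)
  if (model == "twoway") {
    ss_err <- ss_tot - ss_rows - ss_cols
    ms_err <- ss_err / ((n - 1) * (k - 1))
  } else {
    ss_err <- ss_tot - ss_rows
    ms_err <- ss_err / (n * (k - 1))
  }
  denom <- ms_rows + (k - 1) * ms_err
  if (denom == 0) return(NA_real_)
  (ms_rows - ms_err) / denom
}

# two-sided p-value for a Spearman rho via the t approximation; returns NA for
# undefined rho or n < 4
spearman_p <- function(rho, n) {
  ifelse(
    is.na(rho) | n < 4L | abs(rho) >= 1,
    ifelse(!is.na(rho) & abs(rho) >= 1 & n >= 4L, 0, NA_real_),
    2 * stats::pt(abs(rho) * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps)),
                  df = n - 2, lower.tail = FALSE)
  )
}
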