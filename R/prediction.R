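#' Age-stratified cross-validation folds
#'
#' Sorts subjects by age, forms consecutive age blocks of size `k`, and deals
#' each block's members one per fold in a seeded random within-block order,
#' so every fold spans the full age range and fold sizes differ by at most
#' one.
#'
#' @param ages Numeric vector of ages.
#' @param k Number of folds (default 5, must be >= 2).
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k), aligned with `ages`.
#' @export
stratified_folds <- function(ages, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  n <- length(ages)
  if (n < k) stop("need at least k subjects")
  set.seed(seed)
  ord <- order(ages, sample.int(n)) # random tie-break for equal ages
  folds <- integer(n)
  blocks <- split(ord, ceiling(seq_along(ord) / k))
  for (b in blocks) {
    folds[b] <- sample(seq_len(k), length(b))
  }
  folds
}

#' Edge-wise explained variance of age and sex
#'
#' For every MSN edge, fits `edge ~ intercept + age + sex` by least squares
#' on the training folds and scores the held-out fold with the explained
#' variance score `1 - SS_res / SS_tot` (SS_tot about the held-out mean);
#' reports the median score across folds per edge. A fold whose held-out
#' edge values have zero variance contributes a missing score.
#'
#' @param msns List of `region_network`s, one per subject, aligned with
#'   `metadata` rows.
#' @param metadata Tibble with columns `subject`, `age`, `sex` (sex coded
#'   0/1).
#' @param folds Integer fold assignment from [stratified_folds()] (or any
#'   partition into >= 2 folds).
#' @return An `edge_regression` tibble: `region_a`, `region_b`,
#'   `median_score`, plus one `score_fold<k>` column per fold.
#' @export
edgewise_explained_variance <- function(msns, metadata, folds) {
  n <- length(msns)
  stopifnot(n == nrow(metadata), n == length(folds), n >= 10L)
  if (!all(metadata$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  edges <- network_edges(msns[[1L]])
  Y <- vapply(msns, function(net) network_edges(net)$weight,
              numeric(nrow(edges)))
  Y <- t(Y) # subjects x edges
  X <- cbind(1, metadata$age, metadata$sex)
  ks <- sort(unique(folds))
  scores <- matrix(NA_real_, nrow(edges), length(ks))
  for (f in seq_along(ks)) {
    test <- folds == ks[f]
    Xtr <- X[!test, , drop = FALSE]
    beta <- qr.coef(qr(Xtr), Y[!test, , drop = FALSE])
    beta[is.na(beta)] <- 0
    pred <- X[test, , drop = FALSE] %*% beta
    obs <- Y[test, , drop = FALSE]
    ss_tot <- colSums(sweep(obs, 2L, colMeans(obs))^2)
    ss_res <- colSums((obs - pred)^2)
    s <- 1 - ss_res / ss_tot
    s[ss_tot == 0] <- NA_real_
    scores[, f] <- s
  }
  out <- tibble::tibble(region_a = edges$region_a, region_b = edges$region_b,
                        median_score = apply(scores, 1L, stats::median,
                                             na.rm = TRUE))
  for (f in seq_along(ks)) out[[paste0("score_fold", ks[f])]] <- scores[, f]
  class(out) <- c("edge_regression", class(out))
  out
}
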