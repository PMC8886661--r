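#' Cross-modality correspondence map
#'
#' For every shared feature (voxel or region column), the Spearman
#' correlation across subjects between the two modalities, with
#' Benjamini-Hochberg adjustment across features. P-values use the t
#' approximation for the rank correlation.
#'
#' @param table_a,table_b Feature tibbles from [feature_table()] with
#'   matching subjects and feature columns.
#' @param q FDR level (default 0.05).
#' @param min_n Minimum complete pairs per feature (default 3).
#' @return A tibble with columns `feature`, `n`, `rho`, `p`, `p_adj`,
#'   `reject`.
#' @export
correspondence_map <- function(table_a, table_b, q = 0.05, min_n = 3L) {
  ab <- align_subject_tables(table_a, table_b)
  ma <- ab$a
  mb <- ab$b
  res <- purrr::map_dfr(seq_len(ncol(ma)), function(j) {
    ok <- is.finite(ma[, j]) & is.finite(mb[, j])
    n <- sum(ok)
    rho <- if (n >= min_n) {
      tryCatch(spearman_rho(ma[, j], mb[, j], min_n = min_n),
               error = function(e) NA_real_)
    } else NA_real_
    tibble::tibble(feature = colnames(ma)[j], n = n, rho = rho,
                   p = spearman_p(rho, n))
  })
  adj <- fdr_bh(res$p, q)
  res$p_adj <- adj$p_adj
  res$reject <- adj$reject
  res
}

# align two subject-by-feature tibbles on shared subjects and features
align_subject_tables <- function(table_a, table_b) {
  ma <- feature_matrix(table_a)
  mb <- feature_matrix(table_b)
  subjects <- intersect(rownames(ma), rownames(mb))
  if (length(subjects) == 0L) stop("subject sets are disjoint")
  feats <- intersect(colnames(ma), colnames(mb))
  if (length(feats) == 0L) stop("no shared features")
  list(a = ma[subjects, feats, drop = FALSE],
       b = mb[subjects, feats, drop = FALSE])
}

#' Subject-by-subject cross-modality correlation matrix
#'
#' `C[i, j]` is the Spearman correlation over features between modality-A
#' features of subject `i` and modality-B features of subject `j`
#' (pairwise-complete). The diagonal holds within-subject correlations, the
#' off-diagonal between-subject correlations.
#'
#' @param table_a,table_b Feature tibbles with matching subjects and
#'   features.
#' @param feature_space Descriptor stored on the result (e.g.
#'   `"regions-low"`).
#' @return A `cross_modal` matrix with subject ids as dimnames.
#' @export
cross_modal_matrix <- function(table_a, table_b, feature_space = "regions") {
  ab <- align_subject_tables(table_a, table_b)
  ma <- ab$a
  mb <- ab$b
  n <- nrow(ma)
  if (n < 2L) stop("need at least 2 shared subjects")
  if (!anyNA(ma) && !anyNA(mb)) {
    ra <- t(apply(ma, 1L, rank, ties.method = "average"))
    rb <- t(apply(mb, 1L, rank, ties.method = "average"))
    C <- suppressWarnings(stats::cor(t(ra), t(rb)))
  } else {
    C <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      C[i, j] <- tryCatch(spearman_rho(ma[i, ], mb[j, ]),
                          error = function(e) NA_real_)
    }
  }
  dimnames(C) <- list(rownames(ma), rownames(mb))
  structure(C, feature_space = feature_space,
            class = c("cross_modal", "matrix", "array"))
}

#' @export
print.cross_modal <- function(x, ...) {
  cat("<cross_modal> ", nrow(x), " subjects, feature space: ",
      attr(x, "feature_space") %||% "?", "\n", sep = "")
  invisible(x)
}

#' Differential identifiability
#'
#' Global identifiability of a cross-modality matrix: the median
#' within-subject correlation (diagonal) minus the median between-subject
#' correlation (all off-diagonal cells, both triangles pooled), missing
#' entries excluded.
#'
#' @param C A [cross_modal_matrix()].
#' @return An `identifiability` list: `i_diff`, `md_within`, `md_between`,
#'   `n_subjects`, `feature_space`.
#' @export
differential_identifiability <- function(C) {
  stopifnot(nrow(C) == ncol(C), nrow(C) >= 2L)
  d <- diag(C)
  if (all(is.na(d))) stop("all within-subject correlations missing")
  off <- C[row(C) != col(C)]
  md_w <- stats::median(d, na.rm = TRUE)
  md_b <- stats::median(off, na.rm = TRUE)
  structure(list(i_diff = md_w - md_b, md_within = md_w, md_between = md_b,
                 n_subjects = nrow(C),
                 feature_space = attr(C, "feature_space")),
            class = "identifiability")
}

#' @export
print.identifiability <- function(x, ...) {
  cat(sprintf("<identifiability> I_diff = %.3f (within %.3f - between %.3f), N = %d\n",
              x$i_diff, x$md_within, x$md_between, x$n_subjects))
  invisible(x)
}

#' Individual identifiability index
#'
#' Per subject, the fraction of between-subject correlations that are
#' strictly smaller than the subject's own within-subject correlation.
#' `reference = "modalityA"` compares `C[i, i]` against the row entries
#' `C[i, j]` (identifying subject `i`'s modality-B scan among all subjects'
#' modality-B scans); `reference = "modalityB"` uses the column entries
#' `C[j, i]`. Ties and missing comparators count as non-wins, so 1 means the
#' within-subject correlation exceeds every comparator.
#'
#' @param C A [cross_modal_matrix()].
#' @param reference `"modalityA"` or `"modalityB"`.
#' @return A tibble with columns `subject`, `reference`, `fraction`.
#' @export
individual_identifiability <- function(C, reference = c("modalityA", "modalityB")) {
  reference <- match.arg(reference)
  n <- nrow(C)
  if (n < 2L) stop("need at least 2 subjects")
  frac <- vapply(seq_len(n), function(i) {
    own <- C[i, i]
    comp <- if (reference == "modalityA") C[i, -i] else C[-i, i]
    if (is.na(own)) return(NA_real_)
    sum(!is.na(comp) & comp < own) / length(comp)
  }, numeric(1))
  tibble::tibble(subject = rownames(C) %||% as.character(seq_len(n)),
                 reference = reference, fraction = frac)
}

#' Cell-wise spin thresholding of a cross-modality matrix
#'
#' Tests every within- and between-subject cell of the cross-modality
#' correlation matrix against the spin null (subject i's modality-A regional
#' map permuted, subject j's modality-B map fixed), then adjusts the
#' permutation p-values with Benjamini-Hochberg across all cells.
#'
#' @param table_a,table_b Regional feature tibbles with matching subjects
#'   and regions, aligned to the spin set's region order.
#' @param spins A [generate_spins()] result covering the shared regions.
#' @param q FDR level (default 0.05).
#' @return A tibble with one row per cell: `subject_a`, `subject_b`,
#'   `within`, `rho`, `p`, `p_adj`, `reject`.
#' @export
cross_modal_spin_test <- function(table_a, table_b, spins, q = 0.05) {
  ab <- align_subject_tables(table_a, table_b)
  ma <- ab$a
  mb <- ab$b
  labs <- as.character(attr(spins, "labels"))
  if (!all(labs %in% colnames(ma))) stop("spin set regions missing from tables")
  ma <- ma[, labs, drop = FALSE]
  mb <- mb[, labs, drop = FALSE]
  n <- nrow(ma)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(r) {
    i <- grid$i[r]
    j <- grid$j[r]
    st <- spin_test(ma[i, ], mb[j, ], spins)
    tibble::tibble(subject_a = rownames(ma)[i], subject_b = rownames(mb)[j],
                   within = i == j, rho = st$rho, p = st$p)
  })
  adj <- fdr_bh(res$p, q)
  res$p_adj <- adj$p_adj
  res$reject <- adj$reject
  res
}
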