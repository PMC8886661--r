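#' Generate spherical spin permutations
#'
#' Builds the spatial null model for regional cortical maps: for each
#' permutation a uniform random 3-D rotation is drawn, applied to the
#' left-hemisphere unit-sphere centroids, and its x-mirrored twin applied to
#' the right-hemisphere centroids (preserving hemispheric symmetry); each
#' rotated centroid is then assigned the value of the nearest original
#' centroid in the same hemisphere (duplicates permitted). Rotations are
#' sampled by QR orthogonalisation of Gaussian matrices with sign and
#' determinant correction, so they are uniform over SO(3).
#'
#' @param coords Centroid tibble with columns `label`, `x`, `y`, `z`,
#'   `hemisphere` (unit-norm rows; at least 2 regions per hemisphere).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `spin_set`: integer matrix (`n_perm` rows) whose entry `[k, r]`
#'   is the source region index whose value surrogate region `r` takes in
#'   permutation `k`, with the coordinates and seed as attributes.
#' @export
generate_spins <- function(coords, n_perm, seed = 1L) {
  coords <- tibble::as_tibble(coords)
  stopifnot(all(c("label", "x", "y", "z", "hemisphere") %in% names(coords)))
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(xyz^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("centroids must be unit-norm")
  hemi <- as.character(coords$hemisphere)
  sides <- split(seq_len(nrow(coords)), hemi)
  if (length(sides) != 2L || any(lengths(sides) < 2L)) {
    stop("need at least 2 regions in each of 2 hemispheres")
  }
  left <- sides[["L"]] %||% sides[[1L]]
  right <- sides[["R"]] %||% sides[[2L]]
  mirror <- diag(c(-1, 1, 1))
  set.seed(seed)
  perms <- matrix(NA_integer_, n_perm, nrow(coords))
  for (k in seq_len(n_perm)) {
    R <- random_rotation()
    Rm <- mirror %*% R %*% mirror
    for (side in list(list(idx = left, rot = R),
                      list(idx = right, rot = Rm))) {
      pts <- xyz[side$idx, , drop = FALSE]
      rotated <- pts %*% t(side$rot)
      d <- rotated %*% t(pts) # cosine similarity = negative distance ranking
      nearest <- max.col(d, ties.method = "first")
      perms[k, side$idx] <- side$idx[nearest]
    }
  }
  structure(perms, labels = coords$label, seed = seed, class = "spin_set")
}

# uniform random rotation in SO(3)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' @export
print.spin_set <- function(x, ...) {
  cat("<spin_set> ", nrow(x), " permutations of ", ncol(x),
      " regions (seed ", attr(x, "seed"), ")\n", sep = "")
  invisible(x)
}

#' Spin permutation test for two regional maps
#'
#' Tests the Spearman correlation of two regional maps against the spatial
#' null in which map A is replaced by its spin surrogates (map B is never
#' permuted). Two-sided on `|rho|`, with the add-one permutation p-value
#' `p = (1 + #\{|rho_k| >= |rho_obs|\}) / (n_perm + 1)`, so p is never below
#' `1 / (n_perm + 1)`.
#'
#' @param map_a,map_b Numeric vectors of regional values, aligned to the
#'   region order of the spin set (missing values dropped pairwise).
#' @param spins A [generate_spins()] result.
#' @return A `spin_test` list: `rho`, `p`, `null` (vector of null
#'   correlations), `n_perm`.
#' @export
spin_test <- function(map_a, map_b, spins) {
  stopifnot(inherits(spins, "spin_set"))
  n_reg <- ncol(spins)
  if (length(map_a) != n_reg || length(map_b) != n_reg) {
    stop("maps must match the spin set's region count")
  }
  obs <- tryCatch(spearman_rho(map_a, map_b), error = function(e) NA_real_)
  if (is.na(obs)) {
    return(structure(list(rho = NA_real_, p = NA_real_, null = NULL,
                          n_perm = nrow(spins)), class = "spin_test"))
  }
  null <- vapply(seq_len(nrow(spins)), function(k) {
    tryCatch(spearman_rho(map_a[spins[k, ]], map_b), error = function(e) NA_real_)
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(obs), na.rm = TRUE)) / (nrow(spins) + 1)
  structure(list(rho = obs, p = p, null = null, n_perm = nrow(spins)),
            class = "spin_test")
}

#' @export
print.spin_test <- function(x, ...) {
  cat(sprintf("<spin_test> rho = %.3f, p = %.4g (%d spins)\n",
              x$rho, x$p, x$n_perm))
  invisible(x)
}
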