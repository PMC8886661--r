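#' Specify a multicontrast phantom
#'
#' Collects and validates the parameters of the synthetic multi-subject,
#' multicontrast phantom. Every volume is built from unit-variance spatially
#' autocorrelated Gaussian fields as
#'
#' \deqn{V = a G + w(\sqrt{\kappa} A_s + \sqrt{1-\kappa} B_{sc}) + e E_{sc}}
#'
#' where `G` is a group pattern shared by all subjects and contrasts, `A_s` a
#' subject signature shared across contrasts, `B_sc` a contrast-specific
#' subject signature and `E_sc` residual noise, with `w = subject_signal`,
#' `kappa = contrast_coupling`, `a^2 = (1 - w^2) group_share` and
#' `e^2 = (1 - w^2)(1 - group_share)` so the total variance is 1. The
#' implied cross-contrast Pearson correlations are therefore
#' `rho_between = (1 - w^2) group_share` (shared pattern only) and
#' `rho_within = rho_between + w^2 kappa`; since all fields are Gaussian the
#' expected Spearman correlation is `(6 / pi) asin(rho / 2)`. These closed
#' forms are stored in the generated dataset's `truth` record.
#'
#' @param n_subjects Number of subjects (default 30).
#' @param n_contrasts Number of contrasts per subject (default 6).
#' @param grid_shape Integer length-3 grid dimensions, each >= 4.
#' @param voxel_size_mm Positive length-3 voxel size in mm.
#' @param n_regions Even number of atlas parcels, half per hemisphere.
#' @param smoothness_mm Spatial autocorrelation length: FWHM (mm) of the
#'   Gaussian used to smooth the white-noise fields (0 = white noise).
#' @param subject_signal Weight `w` in `[0, 1]` of the subject-specific
#'   signature relative to the shared pattern plus noise.
#' @param contrast_coupling Correlation `kappa` in `[0, 1]` of a subject's
#'   signatures across contrasts.
#' @param group_share Fraction in `[0, 1]` of the non-subject variance
#'   carried by the shared group pattern (the rest is residual noise).
#' @param homotopy Mirror-symmetry weight in `[0, 1]`: each composed field is
#'   blended with its left-right mirror at this weight (1 = exactly
#'   symmetric).
#' @param fov_truncation_prob Per-subject probability that a contiguous axial
#'   slab (10-25\% of slices, at a random end) is zeroed, emulating reduced
#'   field-of-view scans.
#' @param repeat_noise_sd Standard deviation of the independent field added
#'   to session-1 volumes to form within-session repeat scans.
#' @param n_repeat_subjects Number of subjects (the first ones) with a
#'   session-2 repeat scan (default 10).
#' @param age_effect,sex_effect Effect sizes added to all voxels of the first
#'   (age) and second (sex) atlas regions, as `age_effect * scale(age)` and
#'   `sex_effect * (sex - mean(sex))` (defaults 0).
#' @param seed Integer seed; together with the spec it fully determines the
#'   dataset.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(n_subjects = 30L, n_contrasts = 6L,
                         grid_shape = c(32L, 32L, 24L),
                         voxel_size_mm = c(3, 3, 3),
                         n_regions = 32L, smoothness_mm = 8,
                         subject_signal = 0.6, contrast_coupling = 0.7,
                         group_share = 0.5, homotopy = 0.3,
                         fov_truncation_prob = 0.2, repeat_noise_sd = 0.3,
                         n_repeat_subjects = 10L,
                         age_effect = 0, sex_effect = 0, seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               n_contrasts = as.integer(n_contrasts),
               grid_shape = as.integer(grid_shape),
               voxel_size_mm = as.numeric(voxel_size_mm),
               n_regions = as.integer(n_regions),
               smoothness_mm = smoothness_mm,
               subject_signal = subject_signal,
               contrast_coupling = contrast_coupling,
               group_share = group_share,
               homotopy = homotopy,
               fov_truncation_prob = fov_truncation_prob,
               repeat_noise_sd = repeat_noise_sd,
               n_repeat_subjects = min(as.integer(n_repeat_subjects),
                                       as.integer(n_subjects)),
               age_effect = age_effect, sex_effect = sex_effect,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_subjects >= 1, n_contrasts >= 1,
              length(grid_shape) == 3, length(voxel_size_mm) == 3,
              all(voxel_size_mm > 0),
              n_regions >= 2, n_regions %% 2 == 0,
              prod(grid_shape) >= n_regions,
              smoothness_mm >= 0, repeat_noise_sd >= 0)
    for (p in c(subject_signal, contrast_coupling, group_share, homotopy,
                fov_truncation_prob)) {
      if (p < 0 || p > 1) stop("weights/probabilities must lie in [0, 1]")
    }
    if (any(grid_shape < 4)) stop("degenerate grid: every dimension must be >= 4")
  })
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$n_subjects, " subjects x ", x$n_contrasts,
      " contrasts, grid ", paste(x$grid_shape, collapse = "x"),
      ", ", x$n_regions, " regions, subject_signal = ", x$subject_signal,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# expected Spearman correlation between jointly Gaussian variables with
# Pearson correlation rho
gaussian_spearman <- function(rho) (6 / pi) * asin(rho / 2)

phantom_contrast_names <- function(n) {
  base <- c("T1FLAIR", "T2", "T2star", "T2FLAIR", "DWI", "ADC", "logJacobian")
  if (n <= length(base)) base[seq_len(n)] else paste0("contrast_", seq_len(n))
}

#' Build the phantom's brain-like atlas and spherical centroids
#'
#' Partitions an ellipsoidal "brain" mask into `n_regions` contiguous
#' parcels, mirror-paired across the x midplane (right-hemisphere label =
#' left label + `n_regions / 2`), and places one unit-sphere centroid per
#' region with the two hemispheres at opposite x sign. Parcels are Voronoi
#' cells of k-means centroids fitted to the left-hemisphere voxel
#' coordinates, so parcellation is deterministic given the spec seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `atlas` (a [label_atlas()], lookup columns `label`,
#'   `name`, `hemisphere`), `centroids` (tibble `label`, `x`, `y`, `z`,
#'   `hemisphere`, unit-norm rows) and `mask` (binary `volume_grid`).
#' @export
build_phantom_atlas <- function(spec) {
  d <- spec$grid_shape
  half <- spec$n_regions / 2L
  ctr <- (d + 1) / 2
  radii <- 0.45 * d
  ax <- seq_len(d[1]) ; ay <- seq_len(d[2]) ; az <- seq_len(d[3])
  gx <- (ax - ctr[1]) / radii[1]
  gy <- (ay - ctr[2]) / radii[2]
  gz <- (az - ctr[3]) / radii[3]
  r2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  mask <- r2 <= 1
  # exclude an exact midplane column (odd x dimension) to keep mirror pairing clean
  left <- mask & slice.index(mask, 1) < ctr[1]
  if (sum(left) < half) stop("n_regions exceeds usable mask voxel count")
  coords <- which(left, arr.ind = TRUE)
  set.seed(spec$seed)
  km <- stats::kmeans(coords, centers = half, iter.max = 50L, nstart = 3L)
  labels <- array(0L, d)
  labels[coords] <- km$cluster
  # mirror to the right hemisphere
  mirror_x <- d[1] + 1 - seq_len(d[1])
  labels_r <- labels[mirror_x, , , drop = FALSE]
  labels_r[labels_r != 0L] <- labels_r[labels_r != 0L] + half
  labels <- labels + labels_r
  lookup <- tibble::tibble(
    label = seq_len(spec$n_regions),
    name = paste0(rep(c("L_", "R_"), each = half), "region_",
                  rep(seq_len(half), 2L)),
    hemisphere = rep(c("L", "R"), each = half)
  )
  # unit-sphere centroids: voxel-space centroids scaled by the ellipsoid radii
  cen <- km$centers
  u <- cbind((cen[, 1] - ctr[1]) / radii[1],
             (cen[, 2] - ctr[2]) / radii[2],
             (cen[, 3] - ctr[3]) / radii[3])
  u <- u / sqrt(rowSums(u^2))
  centroids <- tibble::tibble(
    label = lookup$label,
    x = c(u[, 1], -u[, 1]),
    y = c(u[, 2], u[, 2]),
    z = c(u[, 3], u[, 3]),
    hemisphere = lookup$hemisphere
  )
  list(atlas = label_atlas(labels, lookup, voxel_size_mm = spec$voxel_size_mm),
       centroids = centroids,
       mask = volume_grid(mask * 1, voxel_size_mm = spec$voxel_size_mm))
}

# one standardized (mean 0, sd 1 over the whole grid), spatially smoothed,
# optionally mirror-blended Gaussian field
smooth_unit_field <- function(spec, blend = TRUE) {
  d <- spec$grid_shape
  x <- array(stats::rnorm(prod(d)), d)
  if (spec$smoothness_mm > 0) {
    v <- gaussian_smooth(volume_grid(x, spec$voxel_size_mm), spec$smoothness_mm)
    x <- unclass(v)
  }
  x <- (x - mean(x)) / stats::sd(x)
  if (blend && spec$homotopy > 0) {
    m <- x[dim(x)[1]:1, , , drop = FALSE]
    x <- x + spec$homotopy * m
    x <- (x - mean(x)) / stats::sd(x)
  }
  x
}

#' Generate a phantom dataset
#'
#' Draws the full synthetic dataset described by a [phantom_spec()]: volumes
#' for every subject, contrast and session, the mirror-paired atlas and
#' spherical centroids, subject metadata (age uniform on 20-40 years, sex
#' balanced) and a `truth` record holding the closed-form expected
#' within-/between-subject cross-contrast correlations (see
#' [phantom_spec()] for the derivation), the expected differential
#' identifiability and the expected test-retest ICC.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom` list with elements `volumes` (nested list
#'   `[[subject]][[contrast]][[session]]` of `volume_grid`s), `atlas`,
#'   `centroids`, `mask`, `metadata` (tibble `subject`, `age`, `sex`,
#'   `sessions`), `truth` and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  parts <- build_phantom_atlas(spec) # sets the seed, stream continues below
  d <- spec$grid_shape
  mask <- unclass(parts$mask) != 0
  w <- spec$subject_signal
  kap <- spec$contrast_coupling
  a <- sqrt((1 - w^2) * spec$group_share)
  e <- sqrt((1 - w^2) * (1 - spec$group_share))
  ws <- w * sqrt(kap)
  wu <- w * sqrt(1 - kap)
  cnames <- phantom_contrast_names(spec$n_contrasts)
  ids <- sprintf("sub-%02d", seq_len(spec$n_subjects))

  n <- spec$n_subjects
  age <- stats::runif(n, 20, 40)
  sex <- sample(rep(c(0L, 1L), length.out = n))
  metadata <- tibble::tibble(
    subject = ids, age = age, sex = sex,
    sessions = ifelse(seq_len(n) <= spec$n_repeat_subjects, 2L, 1L)
  )

  # per-subject FoV truncation: a zeroed axial slab at a random end
  trunc_plan <- lapply(seq_len(n), function(i) {
    if (stats::runif(1) < spec$fov_truncation_prob) {
      n_sl <- max(1L, round(d[3] * stats::runif(1, 0.10, 0.25)))
      top <- stats::runif(1) < 0.5
      if (top) seq(d[3] - n_sl + 1L, d[3]) else seq_len(n_sl)
    } else integer(0)
  })

  group <- smooth_unit_field(spec)
  idx <- unclass(parts$atlas)
  age_z <- if (n > 1 && stats::sd(age) > 0) as.numeric(scale(age)) else rep(0, n)
  sex_c <- sex - mean(sex)

  volumes <- vector("list", n)
  names(volumes) <- ids
  for (i in seq_len(n)) {
    shared_sig <- smooth_unit_field(spec)
    per_subject <- vector("list", spec$n_contrasts)
    names(per_subject) <- cnames
    for (c in seq_len(spec$n_contrasts)) {
      own <- smooth_unit_field(spec)
      noise <- smooth_unit_field(spec)
      v1 <- a * group + ws * shared_sig + wu * own + e * noise
      if (spec$age_effect != 0) v1[idx == 1L] <- v1[idx == 1L] + spec$age_effect * age_z[i]
      if (spec$sex_effect != 0) v1[idx == 2L] <- v1[idx == 2L] + spec$sex_effect * sex_c[i]
      sessions <- list(finalize_phantom_volume(v1, mask, trunc_plan[[i]], spec))
      if (i <= spec$n_repeat_subjects) {
        v2 <- v1
        if (spec$repeat_noise_sd > 0) {
          v2 <- v2 + spec$repeat_noise_sd * smooth_unit_field(spec)
        }
        sessions[[2L]] <- finalize_phantom_volume(v2, mask, trunc_plan[[i]], spec)
      }
      per_subject[[c]] <- sessions
    }
    volumes[[i]] <- per_subject
  }

  rho_b <- (1 - w^2) * spec$group_share
  rho_w <- rho_b + w^2 * kap
  var_subj <- 1 - rho_b # between-subject variance at a voxel
  truth <- list(
    rho_within_pearson = rho_w,
    rho_between_pearson = rho_b,
    rho_within_spearman = gaussian_spearman(rho_w),
    rho_between_spearman = gaussian_spearman(rho_b),
    expected_i_diff = gaussian_spearman(rho_w) - gaussian_spearman(rho_b),
    expected_icc = var_subj / (var_subj + spec$repeat_noise_sd^2),
    age_effect_region = 1L, sex_effect_region = 2L,
    age_effect = spec$age_effect, sex_effect = spec$sex_effect
  )
  structure(list(volumes = volumes, atlas = parts$atlas,
                 centroids = parts$centroids, mask = parts$mask,
                 metadata = metadata, truth = truth, spec = spec),
            class = "phantom")
}

finalize_phantom_volume <- function(x, mask, trunc_slices, spec) {
  x[!mask] <- 0
  if (length(trunc_slices) > 0L) x[, , trunc_slices] <- 0
  volume_grid(x, voxel_size_mm = spec$voxel_size_mm)
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> ", x$spec$n_subjects, " subjects x ", x$spec$n_contrasts,
      " contrasts (", sum(x$metadata$sessions == 2L), " with repeats), ",
      x$spec$n_regions, " regions\n", sep = "")
  invisible(x)
}

#' Regional feature tables from a phantom
#'
#' Convenience accessor: regional-median feature tables (one per contrast)
#' for one session, after the regional coverage filter.
#'
#' @param phantom A [generate_phantom()] result.
#' @param contrasts Contrast names (default: all).
#' @param session Session number (default 1).
#' @param voxel_frac,subject_frac Coverage thresholds (defaults 0.8, 0.8).
#' @return Named list of feature tibbles (see [feature_table()]).
#' @export
phantom_feature_tables <- function(phantom, contrasts = NULL, session = 1L,
                                   voxel_frac = 0.8, subject_frac = 0.8) {
  contrasts <- contrasts %||% names(phantom$volumes[[1L]])
  have <- phantom$metadata$sessions >= session
  subjects <- phantom$metadata$subject[have]
  vols_first <- lapply(phantom$volumes[subjects],
                       function(s) s[[contrasts[[1L]]]][[session]])
  keep <- region_coverage_filter(vols_first, phantom$atlas,
                                 voxel_frac, subject_frac)
  out <- lapply(contrasts, function(cn) {
    vols <- lapply(phantom$volumes[subjects], function(s) s[[cn]][[session]])
    feature_table(vols, phantom$atlas, keep, feature = cn)
  })
  stats::setNames(out, contrasts)
}

#' Synthetic MSN edge data with planted age/sex effects
#'
#' Generates per-subject region networks directly at the edge level, with a
#' designated set of edges whose strength follows
#' `base + amp (sqrt(r2) z_age + sex_effect c_sex + sqrt(1 - r2) eps)` so the
#' planted population explained variance of the age term is exactly
#' `age_r2`; the remaining edges are pure noise around their base value.
#' Noise is uniform, scaled to unit variance, keeping all edge values inside
#' `(-1, 1)`. Used to validate edge-wise regression recovery.
#'
#' @param n_subjects Number of subjects (default 95).
#' @param n_regions Number of regions (default 32).
#' @param n_designated Number of edges carrying the planted effect.
#' @param age_r2 Planted population R-squared of the age term (default 0.3).
#' @param sex_effect Planted standardized sex effect (default 0).
#' @param seed Integer seed.
#' @return List with `msns` (list of `region_network`s), `metadata` (tibble
#'   `subject`, `age`, `sex`) and `truth` (designated edge tibble and planted
#'   parameters).
#' @export
generate_phantom_edges <- function(n_subjects = 95L, n_regions = 32L,
                                   n_designated = 5L, age_r2 = 0.3,
                                   sex_effect = 0, seed = 1L) {
  stopifnot(age_r2 >= 0, age_r2 <= 1, n_regions >= 3L)
  set.seed(seed)
  n_edges <- n_regions * (n_regions - 1L) / 2L
  stopifnot(n_designated <= n_edges)
  labels <- seq_len(n_regions)
  age <- stats::runif(n_subjects, 20, 40)
  sex <- sample(rep(c(0L, 1L), length.out = n_subjects))
  z_age <- as.numeric(scale(age))
  c_sex <- sex - mean(sex)
  ut <- which(upper.tri(diag(n_regions)), arr.ind = TRUE)
  designated <- sort(sample.int(n_edges, n_designated))
  base <- stats::runif(n_edges, -0.3, 0.3)
  amp <- 0.15
  unit_unif <- function(n) stats::runif(n, -sqrt(3), sqrt(3))
  edges <- matrix(0, n_subjects, n_edges)
  for (j in seq_len(n_edges)) {
    if (j %in% designated) {
      edges[, j] <- base[j] + amp * (sqrt(age_r2) * z_age +
                                       sex_effect * c_sex +
                                       sqrt(max(0, 1 - age_r2)) * unit_unif(n_subjects))
    } else {
      edges[, j] <- base[j] + amp * unit_unif(n_subjects)
    }
  }
  ids <- sprintf("sub-%02d", seq_len(n_subjects))
  msns <- lapply(seq_len(n_subjects), function(i) {
    W <- matrix(NA_real_, n_regions, n_regions,
                dimnames = list(labels, labels))
    W[ut] <- edges[i, ]
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    region_network(W, kind = "msn", id = ids[i])
  })
  list(msns = stats::setNames(msns, ids),
       metadata = tibble::tibble(subject = ids, age = age, sex = sex),
       truth = list(designated = tibble::tibble(region_a = labels[ut[designated, 1L]],
                                                region_b = labels[ut[designated, 2L]]),
                    age_r2 = age_r2, sex_effect = sex_effect))
}

#' Write a phantom dataset to disk
#'
#' Serializes volumes as NIfTI (`sub-<id>_ses-<n>_<contrast>.nii.gz`), the
#' atlas as integer NIfTI plus a lookup TSV (`label`, `name`, `hemisphere`),
#' centroids and metadata as CSV, and the truth record as JSON.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(phantom$volumes)) {
    for (cn in names(phantom$volumes[[id]])) {
      sessions <- phantom$volumes[[id]][[cn]]
      for (s in seq_along(sessions)) {
        write_volume(sessions[[s]],
                     file.path(dir, sprintf("%s_ses-%d_%s.nii.gz", id, s, cn)))
      }
    }
  }
  atl <- phantom$atlas
  write_volume(volume_grid(unclass(atl) + 0, voxel_size(atl)),
               file.path(dir, "atlas.nii.gz"))
  readr::write_tsv(attr(atl, "lookup"), file.path(dir, "atlas_lookup.tsv"))
  readr::write_csv(phantom$centroids, file.path(dir, "centroids.csv"))
  readr::write_csv(phantom$metadata, file.path(dir, "metadata.csv"))
  jsonlite::write_json(phantom$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
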