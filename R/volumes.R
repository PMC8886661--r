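#' Construct a volume grid
#'
#' A `volume_grid` is a 3-D numeric array carrying the voxel size (mm) and a
#' world-space origin, the unit of all voxelwise work. Two grids are treated
#' as co-registered when their dimensions match and their voxel sizes and
#' origins agree within 1e-4.
#'
#' @param data 3-D numeric array.
#' @param voxel_size_mm Positive numeric length-3 vector of voxel edge
#'   lengths in mm.
#' @param origin Numeric length-3 world-space coordinate of voxel (1,1,1).
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(data, voxel_size_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be 3 positive reals")
  }
  structure(data,
            voxel_size_mm = voxel_size_mm,
            origin = as.numeric(origin),
            class = c("volume_grid", "array"))
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x), collapse = " x "),
      " voxels @ ", paste(signif(attr(x, "voxel_size_mm"), 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

voxel_size <- function(v) attr(v, "voxel_size_mm") %||% c(1, 1, 1)

# co-registration check by metadata equality (dims exact, sizes/origin 1e-4)
assert_coregistered <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grids differ in shape")
  va <- voxel_size(a)
  vb <- voxel_size(b)
  oa <- attr(a, "origin") %||% c(0, 0, 0)
  ob <- attr(b, "origin") %||% c(0, 0, 0)
  if (max(abs(va - vb)) > 1e-4 || max(abs(oa - ob)) > 1e-4) {
    stop("grids are not co-registered (voxel size or origin mismatch)")
  }
  invisible(TRUE)
}

#' Read / write a volume grid as NIfTI
#'
#' Thin wrappers over RNifti preserving voxel-size metadata.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return `read_volume()` returns a `volume_grid`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  volume_grid(array(as.numeric(img), dim = dim(img)[1:3]),
              voxel_size_mm = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param volume A `volume_grid`.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(unclass(volume))
  RNifti::pixdim(img) <- voxel_size(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a label atlas
#'
#' Integer-labelled grid (0 = background) plus a lookup table mapping each
#' label to a region name and hemisphere.
#'
#' @param labels 3-D integer array of region labels, 0 for background.
#' @param lookup Data frame with columns `label`, `name`, `hemisphere`
#'   covering every nonzero label in `labels`.
#' @param voxel_size_mm,origin As for [volume_grid()].
#' @return A `label_atlas` object.
#' @export
label_atlas <- function(labels, lookup = NULL,
                        voxel_size_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  present <- sort(unique(labels[labels != 0L]))
  if (is.null(lookup)) {
    lookup <- tibble::tibble(label = present,
                             name = paste0("region_", present),
                             hemisphere = NA_character_)
  }
  lookup <- tibble::as_tibble(lookup)
  if (!all(present %in% lookup$label)) {
    stop("lookup table is missing labels present in the image")
  }
  structure(labels,
            lookup = lookup[order(lookup$label), ],
            voxel_size_mm = as.numeric(voxel_size_mm),
            origin = as.numeric(origin),
            class = c("label_atlas", "array"))
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("<label_atlas> ", paste(dim(x), collapse = " x "), " voxels, ",
      nrow(attr(x, "lookup")), " regions\n", sep = "")
  invisible(x)
}

atlas_labels <- function(atlas) attr(atlas, "lookup")$label

#' Voxelwise participant-coverage filter
#'
#' Keeps the voxels that carry signal (are nonzero) in at least a given
#' fraction of participants; used to discard voxels lost to reduced
#' field-of-view in some scans. The threshold is inclusive.
#'
#' @param volumes List of co-registered `volume_grid`s, one per participant.
#' @param threshold Required fraction of participants with a nonzero value,
#'   in (0, 1].
#' @return A `coverage_report` list with `voxel_keep` (logical 3-D array) and
#'   `voxel_fraction` (per-voxel coverage fractions).
#' @export
voxel_coverage_filter <- function(volumes, threshold = 0.8) {
  if (length(volumes) == 0L) stop("empty volume list")
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  for (v in volumes) assert_coregistered(volumes[[1L]], v)
  counts <- Reduce(`+`, lapply(volumes, function(v) (unclass(v) != 0) * 1L))
  frac <- counts / length(volumes)
  structure(list(voxel_keep = frac >= threshold, voxel_fraction = frac,
                 n_subjects = length(volumes), threshold = threshold),
            class = "coverage_report")
}

#' Regional participant-coverage filter
#'
#' A region is kept when, for at least `subject_frac` of participants, at
#' least `voxel_frac` of its voxels are nonzero. Both thresholds inclusive.
#'
#' @param volumes List of co-registered `volume_grid`s.
#' @param atlas A `label_atlas` on the same grid.
#' @param voxel_frac,subject_frac Fractions in (0, 1] (defaults 0.8, 0.8).
#' @return A `coverage_report` list with a `region` tibble (`label`,
#'   `n_subjects_ok`, `subject_fraction`, `keep`).
#' @export
region_coverage_filter <- function(volumes, atlas,
                                   voxel_frac = 0.8, subject_frac = 0.8) {
  if (length(volumes) == 0L) stop("empty volume list")
  if (voxel_frac <= 0 || voxel_frac > 1 || subject_frac <= 0 || subject_frac > 1) {
    stop("thresholds must lie in (0, 1]")
  }
  assert_coregistered(volumes[[1L]], atlas)
  labs <- atlas_labels(atlas)
  idx <- unclass(atlas)
  region_sizes <- tabulate(idx, nbins = max(labs))[labs]
  ok_counts <- rep(0L, length(labs))
  for (v in volumes) {
    nz <- tapply((unclass(v) != 0)[idx != 0L], idx[idx != 0L], sum)
    nz <- nz[match(labs, as.integer(names(nz)))]
    nz[is.na(nz)] <- 0
    ok_counts <- ok_counts + as.integer(nz / region_sizes >= voxel_frac)
  }
  frac <- ok_counts / length(volumes)
  region <- tibble::tibble(label = labs,
                           n_voxels = region_sizes,
                           n_subjects_ok = ok_counts,
                           subject_fraction = frac,
                           keep = frac >= subject_frac)
  structure(list(region = region, region_keep = region$keep,
                 n_subjects = length(volumes),
                 voxel_frac = voxel_frac, subject_frac = subject_frac),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  if (!is.null(x$voxel_keep)) {
    cat("<coverage_report> voxels kept:", sum(x$voxel_keep), "/",
        length(x$voxel_keep), "\n")
  }
  if (!is.null(x$region)) {
    cat("<coverage_report> regions kept:", sum(x$region$keep), "/",
        nrow(x$region), "\n")
  }
  invisible(x)
}

#' Zero-excluded regional medians
#'
#' Median of the nonzero voxels of each region. Regions dropped by a coverage
#' report, or with no nonzero voxels, yield `NA`.
#'
#' @param volume A `volume_grid`.
#' @param atlas A co-registered `label_atlas`.
#' @param keep Optional `coverage_report` from [region_coverage_filter()].
#' @return A tibble with columns `label` and `value`.
#' @export
regional_medians <- function(volume, atlas, keep = NULL) {
  assert_coregistered(volume, atlas)
  labs <- atlas_labels(atlas)
  idx <- unclass(atlas)
  vals <- unclass(volume)
  sel <- idx != 0L & vals != 0
  med <- tapply(vals[sel], idx[sel], stats::median)
  out <- med[match(labs, as.integer(names(med)))]
  out <- as.numeric(out)
  if (!is.null(keep)) {
    kept <- keep$region$label[keep$region$keep]
    out[!labs %in% kept] <- NA_real_
  }
  tibble::tibble(label = labs, value = out)
}

#' Isotropic Gaussian smoothing
#'
#' Separable convolution with a Gaussian kernel specified by its full width
#' at half maximum in mm; `sigma_mm = fwhm / (2 sqrt(2 ln 2))`, converted to
#' voxels per axis using the grid's voxel size. Boundaries use nearest-edge
#' replication, so constant volumes pass through unchanged.
#'
#' @param volume A `volume_grid`.
#' @param fwhm_mm Positive kernel width in mm.
#' @return A smoothed `volume_grid` on the same grid.
#' @export
gaussian_smooth <- function(volume, fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0) {
    stop("fwhm_mm must be a positive scalar")
  }
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vs <- voxel_size(volume)
  x <- unclass(volume)
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / vs[axis]
    x <- convolve_axis_gaussian(x, axis, sigma_vox)
  }
  volume_grid(x, voxel_size_mm = vs, origin = attr(volume, "origin"))
}

# 1-D Gaussian convolution along one axis with replicated edges
convolve_axis_gaussian <- function(x, axis, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(x)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = n)
  # edge-replicated index into the axis for each kernel offset
  acc <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    acc <- acc + k[j] * m[idx, , drop = FALSE]
  }
  out <- array(acc, dim = d[perm])
  aperm(out, order(perm))
}

#' Binary mask dilation
#'
#' Morphological dilation of a binary mask with 26-connectivity (the full
#' 3 x 3 x 3 neighbourhood), iterated.
#'
#' @param mask A `volume_grid` or 3-D array with values in \{0, 1\}.
#' @param iterations Number of dilation passes (default 1).
#' @return A binary `volume_grid`.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  x <- unclass(as.array(mask))
  if (!all(x %in% c(0, 1))) stop("mask must be binary")
  d <- dim(x)
  for (it in seq_len(iterations)) {
    acc <- array(FALSE, d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      acc <- acc | shift_array(x, c(dx, dy, dz)) != 0
    }
    x <- acc * 1
  }
  volume_grid(x, voxel_size_mm = voxel_size(mask),
              origin = attr(mask, "origin") %||% c(0, 0, 0))
}

# shift array contents by an integer offset, zero-filling vacated cells
shift_array <- function(x, offset) {
  d <- dim(x)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- offset[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) {
      dst[[a]] <- (1 + o):d[a]
      src[[a]] <- 1:(d[a] - o)
    } else {
      dst[[a]] <- 1:(d[a] + o)
      src[[a]] <- (1 - o):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Assemble a subjects-by-regions feature table
#'
#' Applies [regional_medians()] to one volume per subject and binds the
#' results into a wide tibble, one row per subject and one column per region
#' label, the unit of all correspondence, covariance and reliability work.
#'
#' @param volumes Named list of `volume_grid`s (names = subject ids).
#' @param atlas A co-registered `label_atlas`.
#' @param keep Optional `coverage_report` from [region_coverage_filter()].
#' @param feature Feature name stored in the `feature` attribute.
#' @return A tibble with a `subject` column followed by one numeric column
#'   per region (named by label).
#' @export
feature_table <- function(volumes, atlas, keep = NULL, feature = "feature") {
  stopifnot(length(volumes) > 0L)
  ids <- names(volumes) %||% as.character(seq_along(volumes))
  rows <- purrr::map(volumes, function(v) {
    m <- regional_medians(v, atlas, keep)
    stats::setNames(as.list(m$value), as.character(m$label))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(tibble::tibble(subject = ids), out)
  attr(out, "feature") <- feature
  out
}

# strip the subject column, returning a numeric matrix with rownames
feature_matrix <- function(table) {
  stopifnot("subject" %in% names(table))
  m <- as.matrix(dplyr::select(table, -"subject"))
  rownames(m) <- table$subject
  storage.mode(m) <- "double"
  m
}
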