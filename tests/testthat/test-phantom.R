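test_that("phantom generation is deterministic given spec and seed", {
  spec <- phantom_spec(n_subjects = 3, n_contrasts = 2,
                       grid_shape = c(12, 12, 8), n_regions = 4,
                       n_repeat_subjects = 2, seed = 99)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$volumes, b$volumes)
  expect_identical(unclass(a$atlas), unclass(b$atlas))
  expect_identical(a$truth, b$truth)
})

test_that("phantom spec validation rejects degenerate input", {
  expect_error(phantom_spec(grid_shape = c(3, 12, 12)), "degenerate grid")
  expect_error(phantom_spec(n_regions = 7), "n_regions")
  expect_error(phantom_spec(subject_signal = 1.2), "\\[0, 1\\]")
})

test_that("homotopy 1 without truncation gives exactly mirror-symmetric volumes", {
  ph <- generate_phantom(phantom_spec(
    n_subjects = 2, n_contrasts = 2, grid_shape = c(14, 12, 8),
    n_regions = 4, homotopy = 1, fov_truncation_prob = 0,
    n_repeat_subjects = 2, seed = 5))
  for (id in names(ph$volumes)) {
    for (cn in names(ph$volumes[[id]])) {
      for (v in ph$volumes[[id]][[cn]]) {
        x <- array(as.numeric(v), dim(v))
        expect_identical(x, x[dim(x)[1]:1, , , drop = FALSE])
      }
    }
  }
})

test_that("zero repeat noise makes session 2 identical to session 1", {
  ph <- generate_phantom(phantom_spec(
    n_subjects = 3, n_contrasts = 2, grid_shape = c(12, 12, 8), n_regions = 4,
    repeat_noise_sd = 0, n_repeat_subjects = 3, seed = 6))
  expect_identical(ph$volumes[[1]][[1]][[1]], ph$volumes[[1]][[1]][[2]])
  expect_identical(ph$volumes[[3]][[2]][[1]], ph$volumes[[3]][[2]][[2]])
})

test_that("no subject signature means equal expected within/between correlations", {
  spec <- phantom_spec(n_subjects = 4, grid_shape = c(12, 12, 8), n_regions = 4,
                       subject_signal = 0, repeat_noise_sd = 0)
  ph <- generate_phantom(spec)
  expect_equal(ph$truth$rho_within_pearson, ph$truth$rho_between_pearson)
  expect_equal(ph$truth$expected_i_diff, 0)
  expect_equal(ph$truth$expected_icc, 1) # no repeat noise
})

test_that("the atlas partitions the mask into mirror-paired parcels", {
  spec <- phantom_spec(n_subjects = 2, grid_shape = c(16, 14, 10), n_regions = 8)
  parts <- build_phantom_atlas(spec)
  labels <- unclass(parts$atlas)
  mask <- unclass(parts$mask) != 0
  # every labelled voxel is in the mask; each voxel has exactly one label
  expect_true(all(labels[!mask] == 0))
  expect_setequal(unique(labels[labels != 0]), 1:8)
  # right hemisphere is the x-mirror of the left, offset by half the labels
  mirrored <- labels[dim(labels)[1]:1, , , drop = FALSE]
  left <- labels %in% 1:4 & labels != 0
  expect_true(all(mirrored[left] == labels[left] + 4))
  # centroids: unit norm, hemispheres at opposite x
  cen <- parts$centroids
  expect_equal(sqrt(cen$x^2 + cen$y^2 + cen$z^2), rep(1, 8),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(cen$x[5:8], -cen$x[1:4])
  expect_equal(cen$y[5:8], cen$y[1:4])
})

test_that("a 2-region atlas is a mirror pair with centroids at opposite x", {
  parts <- build_phantom_atlas(phantom_spec(grid_shape = c(12, 10, 8),
                                            n_regions = 2))
  labels <- unclass(parts$atlas)
  expect_setequal(unique(labels[labels != 0]), 1:2)
  mirrored <- labels[dim(labels)[1]:1, , , drop = FALSE]
  expect_true(all(mirrored[labels == 1] == 2))
  expect_equal(parts$centroids$x[2], -parts$centroids$x[1])
})

test_that("parcel volumes are balanced within a factor of 3 at 32 regions", {
  parts <- build_phantom_atlas(phantom_spec(n_regions = 32))
  sizes <- table(unclass(parts$atlas)[unclass(parts$atlas) != 0])
  expect_length(sizes, 32)
  expect_lt(max(sizes) / min(sizes), 3)
})

test_that("FoV truncation zeroes an axial slab for some subjects", {
  ph <- generate_phantom(phantom_spec(
    n_subjects = 12, n_contrasts = 1, grid_shape = c(14, 14, 12), n_regions = 4,
    fov_truncation_prob = 0.9, seed = 8))
  # the ellipsoid mask leaves the two outermost axial slices empty on its
  # own; truncated subjects lose extra slices at one end
  n_empty <- vapply(ph$volumes, function(s) {
    sum(apply(unclass(s[[1]][[1]]) == 0, 3, all))
  }, numeric(1))
  expect_gt(mean(n_empty > 2), 0.4)
  expect_true(all(n_empty >= 2))
})

test_that("phantom datasets round-trip to disk in standard formats", {
  ph <- generate_phantom(phantom_spec(
    n_subjects = 2, n_contrasts = 2, grid_shape = c(12, 10, 8), n_regions = 4,
    n_repeat_subjects = 1, seed = 30))
  dir <- tempfile("phantom")
  write_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "sub-01_ses-1_T1FLAIR.nii.gz")))
  expect_true(file.exists(file.path(dir, "sub-01_ses-2_T2.nii.gz")))
  expect_false(file.exists(file.path(dir, "sub-02_ses-2_T2.nii.gz")))
  atl <- read_volume(file.path(dir, "atlas.nii.gz"))
  expect_equal(array(as.integer(unclass(atl)), dim(atl)),
               array(unclass(ph$atlas), dim(ph$atlas)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$rho_within_pearson, ph$truth$rho_within_pearson,
               tolerance = 1e-12)
  meta <- readr::read_csv(file.path(dir, "metadata.csv"), show_col_types = FALSE)
  expect_equal(nrow(meta), 2)
})

test_that("edge-level phantom plants the requested effect structure", {
  ed <- generate_phantom_edges(n_subjects = 20, n_regions = 6,
                               n_designated = 3, age_r2 = 0.5, seed = 2)
  expect_length(ed$msns, 20)
  expect_equal(nrow(ed$truth$designated), 3)
  W <- unclass(ed$msns[[1]])
  expect_true(all(abs(W[upper.tri(W)]) < 1))
  expect_identical(W, t(W))
  # determinism
  ed2 <- generate_phantom_edges(n_subjects = 20, n_regions = 6,
                                n_designated = 3, age_r2 = 0.5, seed = 2)
  expect_identical(unclass(ed$msns[[5]]), unclass(ed2$msns[[5]]))
})
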