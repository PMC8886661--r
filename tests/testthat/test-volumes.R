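vol <- function(v, dims = c(length(v), 1, 1), vs = c(1, 1, 1)) {
  volume_grid(array(v, dims), voxel_size_mm = vs)
}

test_that("voxel coverage threshold is inclusive at the boundary", {
  vols <- lapply(1:10, function(i) vol(c(as.numeric(i <= 8), as.numeric(i <= 7))))
  rep <- voxel_coverage_filter(vols, 0.8)
  expect_true(rep$voxel_keep[1, 1, 1])   # 8/10 >= 0.8 kept
  expect_false(rep$voxel_keep[2, 1, 1])  # 7/10 dropped
  expect_equal(rep$voxel_fraction[, 1, 1], c(0.8, 0.7))
  expect_error(voxel_coverage_filter(list(), 0.8), "empty")
})

test_that("kept-voxel counts match a per-voxel brute-force count on a phantom", {
  ph <- tiny_phantom()
  vols <- lapply(ph$volumes, function(s) s[[1]][[1]])
  rep <- voxel_coverage_filter(vols, 0.8)
  arr <- simplify2array(lapply(vols, unclass))
  brute <- apply(arr != 0, 1:3, sum) / length(vols) >= 0.8
  expect_identical(sum(rep$voxel_keep), sum(brute))
  expect_identical(as.vector(rep$voxel_keep), as.vector(brute))
})

test_that("region coverage filter matches hand enumeration on a constructed toy", {
  # 3 regions x 4 voxels each; per-subject nonzero counts chosen by hand
  labels <- array(rep(1:3, each = 4), c(12, 1, 1))
  atl <- label_atlas(labels)
  mk <- function(n1, n2, n3) vol(c(rep(1, n1), rep(0, 4 - n1),
                                   rep(1, n2), rep(0, 4 - n2),
                                   rep(1, n3), rep(0, 4 - n3)), c(12, 1, 1))
  # region 1: >=80% voxels nonzero (4/4) in 4/5 subjects -> kept (0.8 inclusive)
  # region 2: full coverage in all subjects -> kept
  # region 3: at most 2/4 voxels nonzero everywhere -> dropped
  vols <- list(mk(4, 4, 2), mk(4, 4, 2), mk(4, 4, 1), mk(4, 4, 0), mk(2, 4, 2))
  rep <- region_coverage_filter(vols, atl, 0.8, 0.8)
  expect_identical(rep$region$keep, c(TRUE, TRUE, FALSE))
  expect_equal(rep$region$subject_fraction, c(0.8, 1, 0))
})

test_that("coverage filters are monotone in their thresholds", {
  ph <- tiny_phantom()
  vols <- lapply(ph$volumes, function(s) s[[2]][[1]])
  k1 <- voxel_coverage_filter(vols, 0.5)$voxel_keep
  k2 <- voxel_coverage_filter(vols, 0.8)$voxel_keep
  expect_true(all(k1[k2])) # raising the threshold never adds voxels
  r1 <- region_coverage_filter(vols, ph$atlas, 0.5, 0.5)$region$keep
  r2 <- region_coverage_filter(vols, ph$atlas, 0.8, 0.8)$region$keep
  expect_true(all(r1[r2]))
})

test_that("regional medians exclude zeros and match a sort-based oracle", {
  atl <- label_atlas(array(c(1, 1, 1, 1, 2, 2), c(6, 1, 1)))
  v <- vol(c(1, 2, 3, 0, 0, 0))
  m <- regional_medians(v, atl)
  expect_equal(m$value, c(2, NA)) # zero excluded; all-zero region missing
  sort_median <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  set.seed(5)
  ph <- tiny_phantom()
  v <- ph$volumes[[3]][[1]][[1]]
  med <- regional_medians(v, ph$atlas)
  idx <- unclass(ph$atlas)
  for (l in sample(med$label, 4)) {
    vox <- unclass(v)[idx == l]
    vox <- vox[vox != 0]
    expect_equal(med$value[med$label == l], sort_median(vox))
  }
})

test_that("regional medians ignore voxel order and excluded zero values", {
  atl <- label_atlas(array(1L, c(5, 1, 1)))
  expect_equal(regional_medians(vol(c(3, 1, 2, 0, 5)), atl)$value,
               regional_medians(vol(c(5, 3, 0, 1, 2)), atl)$value)
})

test_that("gaussian smoothing preserves constants and the interior mean", {
  v <- vol(rep(2.5, 7 * 7 * 7), c(7, 7, 7))
  expect_equal(unclass(gaussian_smooth(v, 4)), unclass(v), tolerance = 1e-12)
  # interior-supported field: kernel never reaches the edge, mean is exact
  x <- array(0, c(24, 24, 24))
  set.seed(2)
  x[9:16, 9:16, 9:16] <- rnorm(512)
  sm <- gaussian_smooth(volume_grid(x), 2)
  expect_equal(mean(sm), mean(x), tolerance = 1e-6)
  expect_error(gaussian_smooth(v, 0), "positive")
})

test_that("an impulse smoothed at 6 mm has the requested FWHM", {
  d <- c(33, 33, 33)
  x <- array(0, d); x[17, 17, 17] <- 1
  sm <- unclass(gaussian_smooth(volume_grid(x, c(1, 1, 1)), 6))
  prof <- sm[, 17, 17]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation at the two crossings
  lo <- min(above); hi <- max(above)
  f_lo <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  f_hi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  expect_lt(abs((f_hi - f_lo) - 6), 0.5)
  # sigma_mm = fwhm / 2.3548: second-moment check
  sigma <- sqrt(sum((seq_len(33) - 17)^2 * prof) / sum(prof))
  expect_equal(sigma, 6 / (2 * sqrt(2 * log(2))), tolerance = 0.05)
})

test_that("dilation of a single voxel with 26-connectivity yields a 3x3x3 cube", {
  x <- array(0, c(5, 5, 5)); x[3, 3, 3] <- 1
  d <- dilate_mask(volume_grid(x), 1)
  expect_equal(sum(d), 27)
  expect_equal(sum(dilate_mask(volume_grid(array(0, c(4, 4, 4))), 1)), 0)
  expect_error(dilate_mask(vol(c(0, 2, 1)), 1), "binary")
})

test_that("dilation equals a brute-force neighbourhood union", {
  set.seed(13)
  x <- array(rbinom(6 * 5 * 4, 1, 0.2), c(6, 5, 4))
  got <- array(as.numeric(dilate_mask(volume_grid(x), 1)), dim(x))
  brute <- array(0, dim(x))
  for (i in 1:6) for (j in 1:5) for (k in 1:4) {
    nb <- x[max(1, i - 1):min(6, i + 1),
            max(1, j - 1):min(5, j + 1),
            max(1, k - 1):min(4, k + 1)]
    brute[i, j, k] <- as.numeric(any(nb == 1))
  }
  expect_equal(got, brute)
})

test_that("volumes round-trip through NIfTI with voxel size intact", {
  ph <- tiny_phantom()
  v <- ph$volumes[[1]][[1]][[1]]
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(unclass(v2), unclass(v), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(attr(v2, "voxel_size_mm"), attr(v, "voxel_size_mm"))
})

test_that("co-registration is enforced by metadata", {
  a <- vol(1:4)
  b <- vol(1:4, vs = c(2, 1, 1))
  expect_error(voxel_coverage_filter(list(a, b)), "co-registered")
  expect_error(regional_medians(b, label_atlas(array(1L, c(4, 1, 1)))),
               "co-registered")
})
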