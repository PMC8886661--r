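fake_table <- function(m, ids = sprintf("s%02d", seq_len(nrow(m)))) {
  out <- tibble::as_tibble(m, .name_repair = ~ paste0("r", seq_len(ncol(m))))
  dplyr::bind_cols(tibble::tibble(subject = ids), out)
}

test_that("structural covariance equals hand-computed rank correlations on a toy", {
  # 4 subjects x 3 regions, no ties; values are permutations so ranks = values
  m <- cbind(c(1, 2, 3, 4), c(2, 1, 4, 3), c(4, 3, 2, 1))
  net <- structural_covariance(fake_table(m))
  hand <- function(x, y) 1 - 6 * sum((x - y)^2) / (4 * 15)
  expect_equal(net["r1", "r2"], hand(m[, 1], m[, 2]), tolerance = 1e-12)
  expect_equal(net["r1", "r3"], hand(m[, 1], m[, 3]), tolerance = 1e-12)
  expect_equal(net["r2", "r3"], hand(m[, 2], m[, 3]), tolerance = 1e-12)
  expect_identical(unclass(net), t(unclass(net)))
  # duplicated region column correlates perfectly
  net2 <- structural_covariance(fake_table(cbind(m, m[, 1])))
  expect_equal(net2["r1", "r4"], 1)
})

test_that("msn matches the rank formula on a 7-feature toy and flags degeneracy", {
  set.seed(41)
  f <- matrix(rnorm(5 * 7), 5, 7, dimnames = list(paste0("R", 1:5), NULL))
  net <- msn(f, id = "s1")
  # independent check through normalised midranks
  norm <- apply(f, 2, function(x) (x - median(x)) / median(abs(x - median(x))))
  expect_equal(net["R1", "R2"], oracle_spearman(norm[1, ], norm[2, ]),
               tolerance = 1e-12)
  expect_equal(net["R3", "R5"], oracle_spearman(norm[3, ], norm[5, ]),
               tolerance = 1e-12)
  # identical region profiles -> 1
  f_dup <- rbind(f, dup = f["R1", ])
  expect_equal(msn(f_dup)["R1", "dup"], 1)
  # reversed orderings -> -1: columns are permutations of 1:4 so the
  # MAD-normalisation applies the same affine map to every feature
  p <- c(1, 2, 3, 4, 1, 2, 3)
  g <- vapply(p, function(v) {
    rest <- sort(setdiff(1:4, c(v, 5 - v)))
    c(a = v, b = rest[1], c = rest[2], d = 5 - v)
  }, numeric(4))
  net2 <- msn(g)
  expect_equal(net2["a", "d"], -1)
  # zero-MAD feature dropped with warning; < 3 survivors is an error
  f_bad <- cbind(f, 7)
  expect_warning(net3 <- msn(f_bad), "zero MAD")
  expect_equal(unclass(net3), unclass(net), ignore_attr = TRUE)
  expect_error(suppressWarnings(msn(cbind(f[, 1:2], 1, 2))), "fewer than 3")
})

test_that("msn is invariant to affine rescaling of any feature map", {
  set.seed(42)
  f <- matrix(rnorm(6 * 4), 6, 4)
  f2 <- f
  f2[, 2] <- 100 * f2[, 2] - 3
  expect_equal(unclass(msn(f)), unclass(msn(f2)), tolerance = 1e-12)
})

test_that("thresholding keeps the right number and identity of edges", {
  set.seed(43)
  W <- matrix(runif(64, -1, 1), 8, 8)
  W <- (W + t(W)) / 2
  net <- region_network(W)
  # proportion 1 keeps everything
  full <- threshold_network(net, 1)
  expect_equal(tidy(full)$weight, tidy(net)$weight)
  # sort oracle, both modes
  for (mode in c("signed_top", "absolute_top")) {
    thr <- threshold_network(net, 0.25, mode)
    e <- tidy(net)$weight
    strength <- if (mode == "signed_top") e else abs(e)
    kept <- tidy(thr)$weight
    n_keep <- ceiling(0.25 * length(e))
    expect_equal(sum(is.finite(kept)), n_keep)
    expect_setequal(kept[is.finite(kept)], e[order(-strength)][1:n_keep])
  }
})

test_that("a 32-region network thresholded at 10% keeps exactly 50 edges", {
  set.seed(44)
  W <- matrix(rnorm(32 * 32), 32, 32)
  W <- W + t(W)
  thr <- threshold_network(region_network(W), 0.10, "absolute_top")
  expect_equal(sum(is.finite(tidy(thr)$weight)), 50) # ceil(0.10 * 496)
})

test_that("absolute-top thresholds nest as the proportion grows", {
  set.seed(45)
  W <- matrix(rnorm(100), 10, 10)
  W <- W + t(W)
  net <- region_network(W)
  kept <- function(p) {
    e <- tidy(threshold_network(net, p, "absolute_top"))
    which(is.finite(e$weight))
  }
  expect_true(all(kept(0.1) %in% kept(0.3)))
  expect_true(all(kept(0.3) %in% kept(0.8)))
})

test_that("network comparison matches a flatten-then-correlate oracle", {
  set.seed(46)
  A <- matrix(rnorm(36), 6, 6); A <- A + t(A)
  B <- matrix(rnorm(36), 6, 6); B <- B + t(B)
  na <- region_network(A); nb <- region_network(B)
  expect_equal(compare_networks(na, na)$rho, 1)
  got <- compare_networks(na, nb)$rho
  expect_equal(got, oracle_spearman(A[upper.tri(A)], B[upper.tri(B)]),
               tolerance = 1e-12)
  # rank reversal
  nr <- region_network(-A)
  expect_equal(compare_networks(na, nr)$rho, -1)
  expect_error(compare_networks(na, region_network(A[1:5, 1:5])), "region sets")
})

test_that("block-wise comparison partitions the edges", {
  set.seed(47)
  A <- matrix(rnorm(64), 8, 8); A <- A + t(A)
  B <- matrix(rnorm(64), 8, 8); B <- B + t(B)
  blocks <- tibble::tibble(label = as.character(1:8),
                           community = rep(c("x", "y"), each = 4))
  cmp <- compare_networks(region_network(A), region_network(B), blocks)
  expect_equal(sum(cmp$n_edges[cmp$block_a != "all"]), 28)
  expect_setequal(paste(cmp$block_a, cmp$block_b),
                  c("all all", "x x", "x y", "y y"))
})

test_that("group averaging is edgewise with missing dropped per edge", {
  W1 <- matrix(c(NA, 0.2, 0.2, NA), 2, 2)
  W2 <- matrix(c(NA, 0.4, 0.4, NA), 2, 2)
  W3 <- matrix(c(NA, NA, NA, NA), 2, 2)
  nets <- lapply(list(W1, W2, W3), region_network)
  avg <- group_average_msn(nets)
  expect_equal(avg[1, 2], 0.3) # mean of 0.2, 0.4; missing third dropped
  single <- group_average_msn(nets[1])
  expect_equal(unclass(single), unclass(nets[[1]]), ignore_attr = TRUE)
  expect_error(group_average_msn(list()), "empty")
})

test_that("covariance networks of symmetric phantoms favour homotopic pairs", {
  ph <- generate_phantom(phantom_spec(
    n_subjects = 16, n_contrasts = 1, grid_shape = c(20, 20, 14),
    n_regions = 8, homotopy = 1, fov_truncation_prob = 0, seed = 50))
  tab <- phantom_feature_tables(ph)[[1]]
  net <- structural_covariance(tab)
  pairs <- homotopic_pairs(ph$atlas)
  hom <- mapply(function(l, r) net[as.character(l), as.character(r)],
                pairs$left, pairs$right)
  edges <- tidy(net)
  is_hom <- paste(edges$region_a, edges$region_b) %in%
    paste(pmin(pairs$left, pairs$right), pmax(pairs$left, pairs$right))
  expect_gt(median(hom, na.rm = TRUE),
            median(edges$weight[!is_hom], na.rm = TRUE))
  # perfectly mirrored data makes homotopic values identical
  expect_true(all(hom > 0.99, na.rm = TRUE))
})

test_that("networks round-trip through CSV", {
  set.seed(48)
  W <- matrix(rnorm(25), 5, 5); W <- W + t(W)
  net <- region_network(W, kind = "msn")
  f <- tempfile(fileext = ".csv")
  write_network(net, f)
  back <- read_network(f, kind = "msn")
  expect_equal(unclass(back), unclass(net), ignore_attr = TRUE)
  f2 <- tempfile(fileext = ".tsv")
  write_edge_list(net, f2)
  el <- readr::read_tsv(f2, show_col_types = FALSE)
  expect_equal(nrow(el), 10)
})
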