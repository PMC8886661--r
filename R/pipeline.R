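#' Pipeline configuration
#'
#' Validated option set shared by the suite runners.
#'
#' @param voxel_coverage,region_voxel_frac,region_subject_frac Coverage
#'   thresholds in (0, 1] (defaults 0.8).
#' @param smooth_fwhm_mm Gaussian kernel widths (mm) for the smoothed
#'   voxelwise analyses (default `c(2, 4, 6)`).
#' @param n_perm Spin permutations for regional null models (default 1000).
#' @param q FDR level (default 0.05).
#' @param seed Integer seed.
#' @param n_regions_low Region count of the coarse companion atlas used for
#'   the `regions-low` feature space (default 8).
#' @param threshold_proportion,threshold_mode Network threshold settings for
#'   reported edge lists (defaults 0.1, `"absolute_top"`).
#' @param k_folds Cross-validation folds for edge-wise regression (default 5).
#' @return A `pipeline_config` list with a stable `hash`.
#' @export
pipeline_config <- function(voxel_coverage = 0.8,
                            region_voxel_frac = 0.8,
                            region_subject_frac = 0.8,
                            smooth_fwhm_mm = c(2, 4, 6),
                            n_perm = 1000L, q = 0.05, seed = 1L,
                            n_regions_low = 8L,
                            threshold_proportion = 0.1,
                            threshold_mode = "absolute_top",
                            k_folds = 5L) {
  cfg <- list(voxel_coverage = voxel_coverage,
              region_voxel_frac = region_voxel_frac,
              region_subject_frac = region_subject_frac,
              smooth_fwhm_mm = smooth_fwhm_mm,
              n_perm = as.integer(n_perm), q = q, seed = as.integer(seed),
              n_regions_low = as.integer(n_regions_low),
              threshold_proportion = threshold_proportion,
              threshold_mode = threshold_mode,
              k_folds = as.integer(k_folds))
  for (th in c(cfg$voxel_coverage, cfg$region_voxel_frac,
               cfg$region_subject_frac, cfg$q, cfg$threshold_proportion)) {
    if (th <= 0 || th > 1) stop("thresholds must lie in (0, 1]")
  }
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "pipeline_config")
}

provenance <- function(config) {
  list(config_hash = config$hash, seed = config$seed,
       package_version = as.character(utils::packageVersion("multiscan")))
}

# subjects x voxels feature tibble for the voxels kept by `keep`
voxel_feature_table <- function(volumes, keep, feature = "voxels") {
  m <- t(vapply(volumes, function(v) unclass(v)[keep],
                numeric(sum(keep))))
  m[m == 0] <- NA_real_ # zero voxels are missing by convention
  out <- tibble::as_tibble(m, .name_repair = ~ paste0("v", seq_len(sum(keep))))
  out <- dplyr::bind_cols(
    tibble::tibble(subject = names(volumes) %||% as.character(seq_len(nrow(m)))),
    out
  )
  attr(out, "feature") <- feature
  out
}

session_volumes <- function(phantom, contrast, session = 1L) {
  have <- phantom$metadata$sessions >= session
  subjects <- phantom$metadata$subject[have]
  lapply(stats::setNames(subjects, subjects),
         function(id) phantom$volumes[[id]][[contrast]][[session]])
}

# identifiability summary row for one pair of aligned feature tables
identifiability_row <- function(table_a, table_b, space, q) {
  cmap <- correspondence_map(table_a, table_b, q = q)
  C <- cross_modal_matrix(table_a, table_b, feature_space = space)
  ident <- differential_identifiability(C)
  ind_a <- individual_identifiability(C, "modalityA")
  ind_b <- individual_identifiability(C, "modalityB")
  tibble::tibble(
    feature_space = space,
    n_features = sum(is.finite(cmap$rho)),
    md_rho = stats::median(cmap$rho, na.rm = TRUE),
    pct_significant = 100 * mean(cmap$reject[is.finite(cmap$rho)]),
    md_within = ident$md_within,
    md_between = ident$md_between,
    i_diff = ident$i_diff,
    ind_md_ref_a = stats::median(ind_a$fraction, na.rm = TRUE),
    ind_md_ref_b = stats::median(ind_b$fraction, na.rm = TRUE)
  )
}

#' Cross-modality correspondence and identifiability suite
#'
#' Runs the correspondence analyses between two contrasts of a phantom (or
#' any dataset with the same structure) across feature spaces: all brain
#' voxels (dilated mask), grey-matter voxels (atlas union), regional medians
#' at the native atlas resolution and at a coarse companion atlas, plus
#' optionally smoothed grey-matter voxel analyses. Also compares the two
#' modalities' structural covariance networks at the regional level.
#'
#' @param phantom A [generate_phantom()] dataset.
#' @param config A [pipeline_config()].
#' @param modality_a,modality_b Contrast names (defaults: first two).
#' @param session_a,session_b Session used for each modality (default 1; set
#'   `session_b = 2` with `modality_b = modality_a` for test-retest
#'   identifiability).
#' @param feature_spaces Subset of `c("voxels-brain", "voxels-GM",
#'   "regions-high", "regions-low")`.
#' @param smoothed Also run smoothed voxels-GM analyses at
#'   `config$smooth_fwhm_mm` (default FALSE).
#' @return A `correspondence_suite` list: `summary` (one tibble row per
#'   feature space: median correspondence, \% significant after FDR, median
#'   within/between correlations, differential identifiability, median
#'   individual identifiability under both references), `covariance_rho`
#'   (tibble), and `provenance`.
#' @export
run_correspondence_suite <- function(phantom, config = pipeline_config(),
                                     modality_a = NULL, modality_b = NULL,
                                     session_a = 1L, session_b = 1L,
                                     feature_spaces = c("voxels-brain",
                                                        "voxels-GM",
                                                        "regions-high",
                                                        "regions-low"),
                                     smoothed = FALSE) {
  cn <- names(phantom$volumes[[1L]])
  modality_a <- modality_a %||% cn[[1L]]
  modality_b <- modality_b %||% cn[[min(2L, length(cn))]]
  if (!all(c(modality_a, modality_b) %in% cn)) stop("missing modality")
  vols_a <- session_volumes(phantom, modality_a, session_a)
  vols_b <- session_volumes(phantom, modality_b, session_b)
  shared <- intersect(names(vols_a), names(vols_b))
  vols_a <- vols_a[shared]
  vols_b <- vols_b[shared]

  rows <- list()
  cov_rows <- list()

  if (any(c("voxels-brain", "voxels-GM") %in% feature_spaces) || smoothed) {
    cov_a <- voxel_coverage_filter(vols_a, config$voxel_coverage)
    cov_b <- voxel_coverage_filter(vols_b, config$voxel_coverage)
    keep_vox <- cov_a$voxel_keep & cov_b$voxel_keep
  }
  if ("voxels-brain" %in% feature_spaces) {
    brain <- unclass(dilate_mask(phantom$mask, 1L)) != 0
    k <- keep_vox & brain
    rows$vb <- identifiability_row(voxel_feature_table(vols_a, k),
                                   voxel_feature_table(vols_b, k),
                                   "voxels-brain", config$q)
  }
  if ("voxels-GM" %in% feature_spaces || smoothed) {
    gm <- unclass(phantom$atlas) != 0L
    k_gm <- keep_vox & gm
  }
  if ("voxels-GM" %in% feature_spaces) {
    rows$vg <- identifiability_row(voxel_feature_table(vols_a, k_gm),
                                   voxel_feature_table(vols_b, k_gm),
                                   "voxels-GM", config$q)
  }
  if (smoothed) {
    for (f in config$smooth_fwhm_mm) {
      sa <- lapply(vols_a, gaussian_smooth, fwhm_mm = f)
      sb <- lapply(vols_b, gaussian_smooth, fwhm_mm = f)
      rows[[paste0("sm", f)]] <- identifiability_row(
        voxel_feature_table(sa, k_gm), voxel_feature_table(sb, k_gm),
        sprintf("voxels-GM-smoothed-%gmm", f), config$q)
    }
  }
  region_spaces <- list()
  if ("regions-high" %in% feature_spaces) {
    region_spaces[["regions-high"]] <- phantom$atlas
  }
  if ("regions-low" %in% feature_spaces) {
    spec_low <- phantom$spec
    spec_low$n_regions <- config$n_regions_low
    region_spaces[["regions-low"]] <- build_phantom_atlas(spec_low)$atlas
  }
  for (space in names(region_spaces)) {
    atl <- region_spaces[[space]]
    keep <- region_coverage_filter(vols_a, atl, config$region_voxel_frac,
                                   config$region_subject_frac)
    ta <- feature_table(vols_a, atl, keep, feature = modality_a)
    tb <- feature_table(vols_b, atl, keep, feature = modality_b)
    rows[[space]] <- identifiability_row(ta, tb, space, config$q)
    cmp <- compare_networks(structural_covariance(ta),
                            structural_covariance(tb))
    cov_rows[[space]] <- tibble::tibble(feature_space = space,
                                        rho = cmp$rho,
                                        n_edges = cmp$n_edges)
  }
  structure(list(summary = dplyr::bind_rows(rows),
                 covariance_rho = dplyr::bind_rows(cov_rows),
                 modalities = c(modality_a, modality_b),
                 provenance = provenance(config)),
            class = "correspondence_suite")
}

# vectorized two-way (or one-way) consistency ICC over columns, two sessions
icc_columns <- function(s1, s2, model = "twoway") {
  n <- nrow(s1)
  grand <- (colSums(s1) + colSums(s2)) / (2 * n)
  rm_ <- (s1 + s2) / 2
  ss_rows <- 2 * colSums(sweep(rm_, 2L, grand)^2)
  cm1 <- colMeans(s1) - grand
  cm2 <- colMeans(s2) - grand
  ss_cols <- n * (cm1^2 + cm2^2)
  ss_tot <- colSums(sweep(s1, 2L, grand)^2) + colSums(sweep(s2, 2L, grand)^2)
  ms_rows <- ss_rows / (n - 1)
  if (model == "twoway") {
    ms_err <- (ss_tot - ss_rows - ss_cols) / (n - 1)
  } else {
    ms_err <- (ss_tot - ss_rows) / n
  }
  icc <- (ms_rows - ms_err) / (ms_rows + ms_err)
  icc[ss_tot == 0] <- NA_real_
  icc[!is.finite(icc)] <- NA_real_
  icc
}

#' Test-retest reliability suite
#'
#' ICC(3,1) between session-1 and session-2 scans of the repeat subjects,
#' per voxel, per region, and per MSN edge, summarised as median and
#' quartiles per contrast and feature space.
#'
#' @param phantom A [generate_phantom()] dataset with >= 2 repeat subjects.
#' @param config A [pipeline_config()].
#' @param contrasts Contrast names (default: all).
#' @param model `"twoway"` (ICC(3,1), default) or `"oneway"`.
#' @return A `reliability_suite` list: `summary` tibble (`contrast`,
#'   `feature_space`, `n_units`, `md_icc`, `q1_icc`, `q3_icc`), `icc`
#'   (per-unit tibble), and `provenance`.
#' @export
run_reliability_suite <- function(phantom, config = pipeline_config(),
                                  contrasts = NULL, model = "twoway") {
  contrasts <- contrasts %||% names(phantom$volumes[[1L]])
  rep_ids <- phantom$metadata$subject[phantom$metadata$sessions >= 2L]
  if (length(rep_ids) < 2L) stop("need at least 2 repeat subjects")
  units <- list()
  for (cn in contrasts) {
    v1 <- lapply(rep_ids, function(id) phantom$volumes[[id]][[cn]][[1L]])
    v2 <- lapply(rep_ids, function(id) phantom$volumes[[id]][[cn]][[2L]])
    keep <- voxel_coverage_filter(c(v1, v2), config$voxel_coverage)$voxel_keep
    s1 <- t(vapply(v1, function(v) unclass(v)[keep], numeric(sum(keep))))
    s2 <- t(vapply(v2, function(v) unclass(v)[keep], numeric(sum(keep))))
    units[[paste(cn, "voxels")]] <- tibble::tibble(
      contrast = cn, feature_space = "voxels",
      unit = paste0("v", seq_len(sum(keep))),
      icc = icc_columns(s1, s2, model))
    rkeep <- region_coverage_filter(c(v1, v2), phantom$atlas,
                                    config$region_voxel_frac,
                                    config$region_subject_frac)
    names(v1) <- names(v2) <- rep_ids
    t1 <- feature_matrix(feature_table(v1, phantom$atlas, rkeep))
    t2 <- feature_matrix(feature_table(v2, phantom$atlas, rkeep))
    ok <- colSums(!is.finite(t1)) == 0 & colSums(!is.finite(t2)) == 0
    units[[paste(cn, "regions")]] <- tibble::tibble(
      contrast = cn, feature_space = "regions",
      unit = colnames(t1)[ok],
      icc = icc_columns(t1[, ok, drop = FALSE], t2[, ok, drop = FALSE], model))
  }
  if (length(contrasts) >= 3L) {
    msn_edges <- function(session) {
      tabs <- phantom_feature_tables(phantom, contrasts, session = session,
                                     config$region_voxel_frac,
                                     config$region_subject_frac)
      mats <- lapply(tabs, feature_matrix)
      sapply(rep_ids, function(id) {
        f <- sapply(mats, function(m) m[id, ])
        network_edges(msn(f, id = id))$weight
      })
    }
    e1 <- t(msn_edges(1L))
    e2 <- t(msn_edges(2L))
    ok <- colSums(!is.finite(e1)) == 0 & colSums(!is.finite(e2)) == 0
    units[["msn"]] <- tibble::tibble(
      contrast = "MSN", feature_space = "edges",
      unit = paste0("e", which(ok)),
      icc = icc_columns(e1[, ok, drop = FALSE], e2[, ok, drop = FALSE], model))
  }
  icc_tbl <- dplyr::bind_rows(units)
  summary <- icc_tbl |>
    dplyr::group_by(.data$contrast, .data$feature_space) |>
    dplyr::summarise(n_units = sum(is.finite(.data$icc)),
                     md_icc = stats::median(.data$icc, na.rm = TRUE),
                     q1_icc = stats::quantile(.data$icc, 0.25, na.rm = TRUE),
                     q3_icc = stats::quantile(.data$icc, 0.75, na.rm = TRUE),
                     .groups = "drop")
  structure(list(summary = summary, icc = icc_tbl,
                 n_repeat = length(rep_ids), provenance = provenance(config)),
            class = "reliability_suite")
}

#' Morphometric similarity suite
#'
#' Builds one MSN per subject from the phantom's regional feature tables
#' (contrasts as features, MAD-normalised within subject), the group-average
#' MSN and its thresholded edge list, per-subject comparisons to the group
#' average, and edge-wise age/sex regression scores under age-stratified
#' cross-validation.
#'
#' @param phantom A [generate_phantom()] dataset with >= 3 contrasts.
#' @param config A [pipeline_config()].
#' @param blocks Optional community mapping for [compare_networks()].
#' @return An `msn_suite` list: `msns`, `group_msn`, `thresholded_edges`
#'   (tibble), `subject_vs_group` (tibble of per-subject rho), `prediction`
#'   (an [edgewise_explained_variance()] tibble), and `provenance`.
#' @export
run_msn_suite <- function(phantom, config = pipeline_config(), blocks = NULL) {
  contrasts <- names(phantom$volumes[[1L]])
  if (length(contrasts) < 3L) stop("need at least 3 feature maps per subject")
  tabs <- phantom_feature_tables(phantom, contrasts, session = 1L,
                                 config$region_voxel_frac,
                                 config$region_subject_frac)
  mats <- lapply(tabs, feature_matrix)
  ids <- rownames(mats[[1L]])
  # drop regions missing in any subject so all subjects share a region set
  ok_region <- Reduce(`&`, lapply(mats, function(m) colSums(!is.finite(m)) == 0))
  msns <- lapply(stats::setNames(ids, ids), function(id) {
    f <- sapply(mats, function(m) m[id, ok_region])
    msn(f, id = id)
  })
  group <- group_average_msn(msns)
  thr <- threshold_network(group, config$threshold_proportion,
                           config$threshold_mode)
  thr_edges <- dplyr::filter(network_edges(thr), is.finite(.data$weight))
  svg <- purrr::map_dfr(ids, function(id) {
    cmp <- compare_networks(msns[[id]], group, blocks)
    dplyr::bind_cols(tibble::tibble(subject = id), cmp)
  })
  meta <- phantom$metadata[match(ids, phantom$metadata$subject), ]
  folds <- stratified_folds(meta$age, k = config$k_folds, seed = config$seed)
  pred <- edgewise_explained_variance(msns, meta, folds)
  structure(list(msns = msns, group_msn = group,
                 thresholded_edges = thr_edges, subject_vs_group = svg,
                 prediction = pred, provenance = provenance(config)),
            class = "msn_suite")
}
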