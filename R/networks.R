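#' Construct a region network
#'
#' Symmetric region-by-region matrix of correlations: structural covariance
#' (across subjects) or morphometric similarity (within subject). The
#' diagonal is undefined and stored as `NA`.
#'
#' @param W Square symmetric numeric matrix with region labels as dimnames.
#' @param kind `"covariance"` or `"msn"`.
#' @param id Optional subject id (MSN) or subject-set descriptor.
#' @return A `region_network` object.
#' @export
region_network <- function(W, kind = c("covariance", "msn"), id = NULL) {
  kind <- match.arg(kind)
  W <- as.matrix(W)
  stopifnot(nrow(W) == ncol(W))
  if (is.null(dimnames(W))) {
    dimnames(W) <- list(seq_len(nrow(W)), seq_len(nrow(W)))
  }
  diag(W) <- NA_real_
  structure(W, kind = kind, id = id,
            class = c("region_network", "matrix", "array"))
}

#' @export
print.region_network <- function(x, ...) {
  cat("<region_network:", attr(x, "kind"), "> ", nrow(x), " x ", ncol(x),
      " regions", if (!is.null(attr(x, "id"))) paste0(" [", attr(x, "id"), "]"),
      "\n", sep = "")
  invisible(x)
}

network_labels <- function(net) rownames(net)

# upper-triangle edge view: tibble region_a, region_b, weight (row-major order)
network_edges <- function(net) {
  labs <- network_labels(net)
  ut <- which(upper.tri(net), arr.ind = TRUE)
  ord <- order(ut[, 1L], ut[, 2L])
  ut <- ut[ord, , drop = FALSE]
  tibble::tibble(region_a = labs[ut[, 1L]], region_b = labs[ut[, 2L]],
                 weight = net[ut])
}

# pairwise-complete Spearman correlation matrix between columns of m
spearman_matrix <- function(m) {
  if (!anyNA(m)) {
    r <- apply(m, 2L, rank, ties.method = "average")
    W <- suppressWarnings(stats::cor(r))
  } else {
    p <- ncol(m)
    W <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(p)) {
      W[i, i] <- 1
      for (j in seq_len(p)[-seq_len(i)]) {
        ok <- is.finite(m[, i]) & is.finite(m[, j])
        W[i, j] <- W[j, i] <- if (sum(ok) >= 3L) {
          suppressWarnings(stats::cor(rank(m[ok, i]), rank(m[ok, j])))
        } else NA_real_
      }
    }
  }
  dimnames(W) <- list(colnames(m), colnames(m))
  W
}

#' Structural covariance network
#'
#' Correlates regional values across subjects for every pair of regions
#' (Spearman, pairwise-complete). Constant regional vectors yield missing
#' entries.
#'
#' @param table Feature tibble from [feature_table()] (subjects in rows,
#'   region columns, plus a `subject` column).
#' @return A `region_network` of kind `"covariance"`.
#' @export
structural_covariance <- function(table) {
  m <- feature_matrix(table)
  if (nrow(m) < 4L) stop("need at least 4 subjects")
  if (ncol(m) < 2L) stop("need at least 2 regions")
  region_network(spearman_matrix(m), kind = "covariance",
                 id = paste0(nrow(m), " subjects"))
}

#' Morphometric similarity network for one subject
#'
#' Stacks one regional feature vector per contrast/map, MAD-normalises each
#' feature across regions ([mad_normalize()]), then correlates every pair of
#' regions across the normalised features (Spearman). Features whose MAD is
#' zero are dropped with a warning; at least 3 usable features are required.
#'
#' @param features Regions-by-features numeric matrix or data frame for one
#'   subject, with region labels as rownames (or a `label` column).
#' @param id Optional subject id.
#' @return A `region_network` of kind `"msn"`.
#' @export
msn <- function(features, id = NULL) {
  f <- features
  if (is.data.frame(f)) {
    if ("label" %in% names(f)) {
      labs <- as.character(f$label)
      f <- as.matrix(f[setdiff(names(f), "label")])
      rownames(f) <- labs
    } else {
      f <- as.matrix(f)
    }
  }
  storage.mode(f) <- "double"
  if (is.null(rownames(f))) rownames(f) <- seq_len(nrow(f))
  norm <- matrix(NA_real_, nrow(f), ncol(f), dimnames = dimnames(f))
  keep <- logical(ncol(f))
  for (j in seq_len(ncol(f))) {
    z <- withCallingHandlers(
      mad_normalize(f[, j]),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (!all(is.na(z))) {
      norm[, j] <- as.numeric(z)
      keep[j] <- TRUE
    }
  }
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " feature(s) with zero MAD")
  }
  if (sum(keep) < 3L) stop("fewer than 3 usable features after MAD filtering")
  W <- spearman_matrix(t(norm[, keep, drop = FALSE]))
  region_network(W, kind = "msn", id = id)
}

#' Proportional network threshold
#'
#' Retains the `ceiling(proportion * n_edges)` strongest upper-triangle
#' edges, by signed value (`signed_top`, "strongest" = most positive) or
#' absolute value (`absolute_top`); all other entries become `NA`. Ties are
#' broken by stable row-major upper-triangle order.
#'
#' @param net A `region_network`.
#' @param proportion Fraction of edges to keep, in (0, 1].
#' @param mode `"signed_top"` or `"absolute_top"`.
#' @return A sparse `region_network` (non-kept edges `NA`).
#' @export
threshold_network <- function(net, proportion,
                              mode = c("signed_top", "absolute_top")) {
  mode <- match.arg(mode)
  if (nrow(net) < 2L) stop("empty network")
  if (proportion <= 0 || proportion > 1) stop("proportion must lie in (0, 1]")
  ut <- which(upper.tri(net), arr.ind = TRUE)
  ord <- order(ut[, 1L], ut[, 2L]) # row-major stable edge order
  ut <- ut[ord, , drop = FALSE]
  w <- net[ut]
  strength <- if (mode == "signed_top") w else abs(w)
  n_keep <- ceiling(proportion * length(w))
  strength[is.na(strength)] <- -Inf
  keep_idx <- order(-strength, seq_along(strength))[seq_len(n_keep)]
  W <- matrix(NA_real_, nrow(net), ncol(net), dimnames = dimnames(net))
  sel <- ut[keep_idx, , drop = FALSE]
  W[sel] <- w[keep_idx]
  W[sel[, c(2L, 1L), drop = FALSE]] <- w[keep_idx]
  region_network(W, kind = attr(net, "kind"), id = attr(net, "id"))
}

#' Compare two region networks
#'
#' Spearman correlation of the vectorised upper triangles (missing edges
#' dropped pairwise), overall and optionally within/between community
#' blocks.
#'
#' @param net_a,net_b `region_network`s on the same region set.
#' @param blocks Optional community mapping: data frame with columns `label`
#'   and `community`.
#' @return A tibble with columns `block_a`, `block_b` (both `"all"` for the
#'   overall row), `n_edges`, `rho`.
#' @export
compare_networks <- function(net_a, net_b, blocks = NULL) {
  if (!identical(network_labels(net_a), network_labels(net_b))) {
    stop("region sets differ")
  }
  ea <- network_edges(net_a)
  eb <- network_edges(net_b)
  overall <- tibble::tibble(
    block_a = "all", block_b = "all",
    n_edges = sum(is.finite(ea$weight) & is.finite(eb$weight)),
    rho = spearman_rho(ea$weight, eb$weight)
  )
  if (is.null(blocks)) return(overall)
  blocks <- tibble::as_tibble(blocks)
  comm <- blocks$community[match(network_labels(net_a), as.character(blocks$label))]
  if (anyNA(comm)) stop("blocks mapping must cover every region")
  ca <- comm[match(ea$region_a, network_labels(net_a))]
  cb <- comm[match(ea$region_b, network_labels(net_a))]
  pair <- tibble::tibble(
    block_a = pmin(ca, cb), block_b = pmax(ca, cb),
    wa = ea$weight, wb = eb$weight
  )
  per_block <- pair |>
    dplyr::group_by(.data$block_a, .data$block_b) |>
    dplyr::summarise(
      n_edges = sum(is.finite(.data$wa) & is.finite(.data$wb)),
      rho = tryCatch(spearman_rho(.data$wa, .data$wb), error = function(e) NA_real_),
      .groups = "drop"
    )
  dplyr::bind_rows(overall, per_block)
}

#' Edgewise group-average network
#'
#' Mean of each edge over a set of networks, missing values dropped per
#' edge.
#'
#' @param nets Non-empty list of `region_network`s on the same region set.
#' @return A `region_network`.
#' @export
group_average_msn <- function(nets) {
  if (length(nets) == 0L) stop("empty network list")
  labs <- network_labels(nets[[1L]])
  for (n in nets) {
    if (!identical(network_labels(n), labs)) stop("region sets differ")
  }
  arr <- simplify2array(lapply(nets, unclass))
  W <- apply(arr, c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  region_network(W, kind = attr(nets[[1L]], "kind"),
                 id = paste0("mean of ", length(nets)))
}

#' Homotopic region pairs of a mirror-paired atlas
#'
#' For atlases whose lookup pairs `L_x` with `R_x` names (as built by
#' [build_phantom_atlas()]), returns the left/right label pairs.
#'
#' @param atlas A `label_atlas` with `hemisphere` and mirror-paired names.
#' @return Tibble with columns `left`, `right` (labels).
#' @export
homotopic_pairs <- function(atlas) {
  lk <- attr(atlas, "lookup")
  left <- lk[lk$hemisphere == "L", ]
  right <- lk[lk$hemisphere == "R", ]
  stem <- function(n) sub("^[LR]_", "", n)
  m <- match(stem(left$name), stem(right$name))
  tibble::tibble(left = left$label, right = right$label[m])
}
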