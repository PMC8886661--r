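#' Tidiers for multiscan result objects
#'
#' Broom-style `tidy()` and `glance()` methods: `tidy()` returns one row per
#' element (region, edge, subject or cell), `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name multiscan-tidiers
NULL

#' @rdname multiscan-tidiers
#' @method tidy dice_result
#' @export
tidy.dice_result <- function(x, ...) {
  tibble::as_tibble(x)[-1L, ]
}

#' @rdname multiscan-tidiers
#' @method glance dice_result
#' @export
glance.dice_result <- function(x, ...) {
  g <- tibble::as_tibble(x)[1L, ]
  tibble::tibble(global_dice = g$dice, n_source = g$n_source,
                 n_target = g$n_target, n_overlap = g$n_overlap,
                 n_regions = nrow(x) - 1L)
}

#' @rdname multiscan-tidiers
#' @method tidy cross_modal
#' @export
tidy.cross_modal <- function(x, ...) {
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  tidyr::expand_grid(subject_a = ids, subject_b = ids) |>
    dplyr::mutate(rho = as.vector(t(unclass(x))),
                  within = .data$subject_a == .data$subject_b)
}

#' @rdname multiscan-tidiers
#' @method glance identifiability
#' @export
glance.identifiability <- function(x, ...) {
  tibble::tibble(i_diff = x$i_diff, md_within = x$md_within,
                 md_between = x$md_between, n_subjects = x$n_subjects,
                 feature_space = x$feature_space %||% NA_character_)
}

#' @rdname multiscan-tidiers
#' @method tidy region_network
#' @export
tidy.region_network <- function(x, ...) {
  network_edges(x)
}

#' @rdname multiscan-tidiers
#' @method glance region_network
#' @export
glance.region_network <- function(x, ...) {
  e <- network_edges(x)$weight
  tibble::tibble(kind = attr(x, "kind"), n_regions = nrow(x),
                 n_edges = sum(is.finite(e)),
                 md_weight = stats::median(e, na.rm = TRUE))
}

#' @rdname multiscan-tidiers
#' @method tidy spin_test
#' @export
tidy.spin_test <- function(x, ...) {
  tibble::tibble(null_rho = x$null)
}

#' @rdname multiscan-tidiers
#' @method glance spin_test
#' @export
glance.spin_test <- function(x, ...) {
  tibble::tibble(rho = x$rho, p = x$p, n_perm = x$n_perm)
}

#' Plot methods for multiscan results
#'
#' `autoplot()` methods returning ggplot objects: a heatmap for region
#' networks and cross-modality matrices, a null-distribution histogram for
#' spin tests, and a fold-score distribution for edge-wise regression.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name multiscan-autoplot
NULL

#' @rdname multiscan-autoplot
#' @method autoplot region_network
#' @export
autoplot.region_network <- function(object, ...) {
  labs <- network_labels(object)
  df <- tidyr::expand_grid(region_a = factor(labs, labs),
                           region_b = factor(labs, labs)) |>
    dplyr::mutate(weight = as.vector(t(unclass(object))))
  ggplot2::ggplot(df, ggplot2::aes(.data$region_b, .data$region_a,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0(attr(object, "kind"), " network")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @rdname multiscan-autoplot
#' @method autoplot cross_modal
#' @export
autoplot.cross_modal <- function(object, ...) {
  df <- tidy.cross_modal(object)
  ids <- rownames(object)
  df$subject_a <- factor(df$subject_a, ids)
  df$subject_b <- factor(df$subject_b, rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(.data$subject_a, .data$subject_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey90") +
    ggplot2::labs(x = "modality B subject", y = "modality A subject",
                  title = "cross-modality correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @rdname multiscan-autoplot
#' @method autoplot spin_test
#' @export
autoplot.spin_test <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(null = object$null),
                  ggplot2::aes(.data$null)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$rho, colour = "red") +
    ggplot2::labs(x = "null Spearman rho", y = "count",
                  title = sprintf("spin test: rho = %.3f, p = %.4g",
                                  object$rho, object$p)) +
    ggplot2::theme_minimal()
}

#' @rdname multiscan-autoplot
#' @method autoplot edge_regression
#' @export
autoplot.edge_regression <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$median_score)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::labs(x = "median held-out explained variance",
                  y = "edges", title = "edge-wise age/sex regression") +
    ggplot2::theme_minimal()
}
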