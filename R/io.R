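#' Read and write feature tables
#'
#' A feature table is stored as CSV (rows = subjects, columns = region
#' labels, first column `subject`) with the feature name in a JSON sidecar
#' next to it.
#'
#' @param table A [feature_table()] tibble.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `read_feature_table()` returns the tibble with its `feature`
#'   attribute restored; `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  jsonlite::write_json(list(feature = attr(table, "feature") %||% "feature"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(subject = "c", .default = "d"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(out, "feature") <- jsonlite::read_json(sidecar)$feature
  }
  out
}

#' Read and write region networks
#'
#' Square CSV with a region-label header (and a leading `region` column), or
#' an edge-list TSV (`region_a`, `region_b`, `weight`).
#'
#' @param net A `region_network`.
#' @param path Output path.
#' @param kind Network kind to restore on read.
#' @return `read_network()` returns a `region_network`; the writers return
#'   `path` invisibly.
#' @export
write_network <- function(net, path) {
  df <- tibble::as_tibble(unclass(net), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(region = network_labels(net)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_network
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(network_edges(net), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, kind = "covariance") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  W <- as.matrix(df[, -1L])
  rownames(W) <- df$region
  region_network(W, kind = kind)
}
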