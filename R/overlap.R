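#' Dice overlap of two label images
#'
#' Scores the agreement of two co-registered label atlases with the Dice
#' coefficient D = 2|A n B| / (|A| + |B|). Globally, A and B are all labelled
#' (nonzero) voxels of source and target and a voxel counts as overlapping
#' only when its labels are equal, so the global count is the sum of the
#' per-region intersection counts. Per region, A and B are restricted to one
#' label. Regions present in only one image score 0 with a warning.
#'
#' @param source,target `label_atlas` objects on the same grid.
#' @return A `dice_result`: a tibble with columns `label`, `name`, `n_source`,
#'   `n_target`, `n_overlap`, `dice`, with the pooled global row labelled
#'   `"GLOBAL"` first.
#' @examples
#' a <- label_atlas(array(c(1L, 1L, 2L, 0L), c(4, 1, 1)))
#' dice(a, a)
#' @export
dice <- function(source, target) {
  if (!identical(dim(source), dim(target))) stop("grid mismatch")
  s <- as.integer(unclass(source))
  t <- as.integer(unclass(target))
  labs_s <- sort(unique(s[s != 0L]))
  labs_t <- sort(unique(t[t != 0L]))
  labs <- sort(union(labs_s, labs_t))
  if (length(intersect(labs_s, labs_t)) == 0L && length(labs) > 0L) {
    stop("label vocabularies are disjoint")
  }
  only_one <- setdiff(labs, intersect(labs_s, labs_t))
  if (length(only_one) > 0L) {
    warning("labels present in only one image score Dice 0: ",
            paste(only_one, collapse = ", "))
  }
  nb <- max(labs, 1L)
  n_s <- tabulate(s, nbins = nb)[labs]
  n_t <- tabulate(t, nbins = nb)[labs]
  both <- s != 0L & s == t
  n_o <- tabulate(s[both], nbins = nb)[labs]
  per <- tibble::tibble(
    label = as.character(labs),
    n_source = n_s, n_target = n_t, n_overlap = n_o,
    dice = ifelse(n_s + n_t > 0, 2 * n_o / (n_s + n_t), NA_real_)
  )
  glob <- tibble::tibble(
    label = "GLOBAL",
    n_source = sum(n_s), n_target = sum(n_t), n_overlap = sum(n_o),
    dice = if (sum(n_s) + sum(n_t) > 0) {
      2 * sum(n_o) / (sum(n_s) + sum(n_t))
    } else NA_real_
  )
  lk <- attr(source, "lookup")
  out <- dplyr::bind_rows(glob, per)
  out$name <- c("GLOBAL", lk$name[match(labs, lk$label)])
  out <- dplyr::relocate(out, "name", .after = "label")
  class(out) <- c("dice_result", class(out))
  out
}

#' Global Dice coefficient
#'
#' @param result A `dice_result` from [dice()].
#' @return The pooled global Dice value.
#' @export
global_dice <- function(result) {
  result$dice[result$label == "GLOBAL"]
}
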