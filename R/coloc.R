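# Inter-channel spatial relationship metrics between two puncta sets:
# directional minimum centroid distances and the effective-radius overlap
# ratio. Distances are in pixels, as in the underlying feature definitions;
# conversion to nm via the pixel pitch is left to the caller.

puncta_centroids <- function(set) {
  stopifnot(inherits(set, "puncta_set"))
  as.matrix(set$props[, c("centroid_row", "centroid_col")])
}

# pairwise Euclidean distance matrix between two (n x 2) centroid matrices
centroid_dist <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

#' Directional minimum centroid distances between two puncta sets
#'
#' For each source punctum centroid, the Euclidean distance to its nearest
#' target punctum centroid; summarized by the mean and a fixed-width
#' histogram (bin edges 0, `bin_width`, 2 `bin_width`, ...; left-closed,
#' right-open). The metric is directional: swapping source and target gives
#' a different value in general, and no symmetrization is applied.
#'
#' @param source,target `puncta_set`s (typically H3K27ac and CTCF).
#' @param bin_width histogram bin width in px (default 10).
#' @return object of class `coloc_distances`: list with `mean_min_distance`,
#'   `min_distances` (one per source punctum), `histogram` (named counts)
#'   and `n_source`, `n_target`. With an empty source or target the result
#'   is missing (`NA`), not zero.
#' @export
min_distances <- function(source, target, bin_width = 10) {
  a <- puncta_centroids(source); b <- puncta_centroids(target)
  if (nrow(a) == 0 || nrow(b) == 0)
    return(structure(list(mean_min_distance = NA_real_,
                          min_distances = numeric(0), histogram = integer(0),
                          n_source = nrow(a), n_target = nrow(b)),
                     class = "coloc_distances"))
  d <- centroid_dist(a, b)
  mins <- unname(apply(d, 1, min))
  nb <- floor(max(mins) / bin_width) + 1
  edges <- bin_width * (0:nb)
  counts <- tabulate(findInterval(mins, edges, rightmost.closed = FALSE), nbins = nb)
  names(counts) <- sprintf("[%g,%g)", edges[-length(edges)], edges[-1])
  structure(list(mean_min_distance = mean(mins), min_distances = mins,
                 histogram = counts, n_source = nrow(a), n_target = nrow(b)),
            class = "coloc_distances")
}

#' Effective-radius overlap ratio between two puncta sets
#'
#' Each punctum carries an effective radius r = (L_major + L_minor)/4 (the
#' average of the half-lengths of its moment-equivalent ellipse axes). A
#' source punctum i overlaps a target punctum j when their centroid distance
#' satisfies d_ij <= r_i + r_j. The overlap ratio is the proportion of
#' source puncta with at least one such overlapping target punctum.
#'
#' @param source,target `puncta_set`s.
#' @return proportion in [0, 1]; `NA` for an empty source; 0 (with a
#'   warning) for an empty target.
#' @export
overlap_ratio <- function(source, target) {
  a <- puncta_centroids(source); b <- puncta_centroids(target)
  if (nrow(a) == 0) return(NA_real_)
  if (nrow(b) == 0) {
    warning("overlap_ratio: empty target puncta set; ratio is 0")
    return(0)
  }
  d <- centroid_dist(a, b)
  rsum <- outer(source$props$r_eff, target$props$r_eff, "+")
  mean(apply(d <= rsum, 1, any))
}
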