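# Nuclear puncta segmentation (four-class multi-Otsu thresholding followed by
# marker-based watershed on the inverted Euclidean distance map) and the
# per-nucleus puncta feature set.

#' Multi-level Otsu thresholds
#'
#' Exhaustive maximization of the between-class variance of the intensity
#' histogram over `n_classes - 1` thresholds (the multilevel generalization
#' of Otsu's method). Returns thresholds on the intensity scale; class k
#' collects values in (t_{k-1}, t_k].
#'
#' @param x numeric vector of intensities.
#' @param n_classes number of classes (default 4).
#' @param n_bins histogram bins used for the search.
#' @return numeric vector of `n_classes - 1` increasing thresholds.
#' @export
multiotsu_thresholds <- function(x, n_classes = 4L, n_bins = 128L) {
  stopifnot(n_classes >= 2)
  x <- x[is.finite(x)]
  if (length(unique(x)) < n_classes)
    stop("multiotsu_thresholds: fewer distinct intensity levels than classes (untextured input)")
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1L), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  P <- c(0, cumsum(p)); S <- c(0, cumsum(p * mids))
  # class (i, j]: weight P[j+1]-P[i+1], sum S[j+1]-S[i+1]
  cls_score <- function(i, j) {
    w <- P[j + 1] - P[i + 1]
    s <- S[j + 1] - S[i + 1]
    ifelse(w > 0, s^2 / w, 0)
  }
  if (n_classes == 4L) {
    best <- -Inf; bt <- c(1L, 2L, 3L)
    for (t1 in 1:(n_bins - 3)) {
      s1 <- cls_score(0L, t1)
      for (t2 in (t1 + 1):(n_bins - 2)) {
        s2 <- s1 + cls_score(t1, t2)
        t3 <- (t2 + 1):(n_bins - 1)
        sc <- s2 + cls_score(t2, t3) + cls_score(t3, n_bins)
        m <- which.max(sc)
        if (sc[m] > best) { best <- sc[m]; bt <- c(t1, t2, t3[m]) }
      }
    }
    return(breaks[bt + 1])
  }
  # generic recursive search for other class counts (small n_bins advised)
  combs <- utils::combn(n_bins - 1L, n_classes - 1L)
  scores <- apply(combs, 2, function(tt) {
    bounds <- c(0L, tt, n_bins)
    sum(cls_score(bounds[-length(bounds)], bounds[-1]))
  })
  breaks[combs[, which.max(scores)] + 1]
}

#' Segment nuclear puncta within a nucleus mask
#'
#' The channel intensities inside the nucleus mask are split into four
#' classes by multi-Otsu thresholding; the brightest class is the punctum
#' foreground. The Euclidean distance transform of the foreground provides a
#' topography whose local maxima (merged within `tolerance` of height and an
#' `ext`-pixel neighborhood, preventing oversplits of round spots while
#' still splitting dumbbells) seed a watershed on the inverted distance map.
#' Objects larger than `max_area` px^2 are removed (strictly greater;
#' exactly `max_area` is kept).
#'
#' @param channel numeric matrix, one marker channel.
#' @param mask binary nucleus mask of the same shape.
#' @param max_area area cutoff in px^2 (default 300).
#' @param top_classes number of top Otsu classes forming the foreground
#'   (default 1, the brightest only).
#' @param tolerance,ext watershed maxima parameters (h-maxima depth and
#'   neighborhood radius in px).
#' @return an object of class `puncta_set`: list with `labels` (integer
#'   matrix), `props` (one [region_props()] row per punctum), `channel`
#'   (name, if the input carries one) and `n`.
#' @export
segment_puncta <- function(channel, mask, max_area = 300, top_classes = 1L,
                           tolerance = 1, ext = 3L) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("segment_puncta: empty nucleus mask")
  stopifnot(all(dim(channel) == dim(mask)))
  vals <- channel[mask]
  thr <- multiotsu_thresholds(vals, n_classes = 4L)
  cut <- thr[length(thr) - top_classes + 1L]
  fg <- channel > cut & mask
  labels <- matrix(0L, nrow(channel), ncol(channel))
  if (any(fg)) {
    d <- EBImage::distmap(fg)
    w <- EBImage::watershed(d, tolerance = tolerance, ext = ext)
    labels <- matrix(as.integer(w), nrow(channel), ncol(channel))
    sizes <- tabulate(labels[labels > 0])
    drop <- which(sizes > max_area)
    if (length(drop)) labels[labels %in% drop] <- 0L
    labels <- relabel_consecutive(labels)
  }
  props <- region_props(labels, channel)
  structure(list(labels = labels, props = props,
                 channel = attr(channel, "channel_name"),
                 n = nrow(props)),
            class = "puncta_set")
}

relabel_consecutive <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(labels)
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  pos <- labels > 0
  labels[pos] <- map[labels[pos]]
  labels
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("puncta_set: %d puncta%s\n", x$n,
              if (!is.null(x$channel)) paste0(" (", x$channel, ")") else ""))
  invisible(x)
}

#' Aggregate per-nucleus puncta features
#'
#' Arithmetic means over all puncta of area, intensity and elongation
#' (irregularity = mean major/minor axis ratio). With no puncta the count is
#' retained and the means are recorded as missing. Single-pixel puncta with
#' a zero minor axis are excluded from the irregularity mean (their count is
#' reported in `n_degenerate`) but contribute to all other features.
#'
#' @param set a `puncta_set`.
#' @return object of class `puncta_features`: list with `n`, `mean_area`,
#'   `mean_intensity`, `irregularity`, `n_degenerate`.
#' @export
puncta_aggregates <- function(set) {
  stopifnot(inherits(set, "puncta_set"))
  p <- set$props
  if (nrow(p) == 0)
    return(structure(list(n = 0L, mean_area = NA_real_,
                          mean_intensity = NA_real_, irregularity = NA_real_,
                          n_degenerate = 0L),
                     class = "puncta_features"))
  ok <- p$l_minor > 0
  irr <- if (any(ok)) mean(elongation(p$l_major[ok], p$l_minor[ok])) else NA_real_
  structure(list(n = nrow(p),
                 mean_area = mean(p$area),
                 mean_intensity = mean(p$mean_intensity),
                 irregularity = irr,
                 n_degenerate = sum(!ok)),
            class = "puncta_features")
}

#' Detection rate and centroid accuracy against ground truth
#'
#' Greedy one-to-one matching of true punctum positions to segmented
#' centroids within `match_radius` px; a true punctum is detected when a
#' (still unclaimed) centroid lies within the radius. The RMSE is over the
#' matched pairs.
#'
#' @param truth data.frame with `row`, `col` true positions (as in a
#'   `ground_truth` channel table).
#' @param set a `puncta_set`.
#' @param match_radius maximum match distance in px.
#' @return list with `detection_rate`, `rmse`, `n_true`, `n_detected`,
#'   `n_matched`.
#' @export
puncta_recovery <- function(truth, set, match_radius = 3) {
  stopifnot(inherits(set, "puncta_set"))
  nt <- nrow(truth)
  if (nt == 0) return(list(detection_rate = NA_real_, rmse = NA_real_,
                           n_true = 0L, n_detected = set$n, n_matched = 0L))
  if (set$n == 0) return(list(detection_rate = 0, rmse = NA_real_,
                              n_true = nt, n_detected = 0L, n_matched = 0L))
  d <- sqrt(outer(truth$row, set$props$centroid_row, "-")^2 +
              outer(truth$col, set$props$centroid_col, "-")^2)
  used <- logical(set$n)
  errs <- numeric(0)
  ord <- order(apply(d, 1, min))
  matched <- 0L
  for (i in ord) {
    cand <- which(!used & d[i, ] <= match_radius)
    if (length(cand) == 0) next
    j <- cand[which.min(d[i, cand])]
    used[j] <- TRUE
    matched <- matched + 1L
    errs <- c(errs, d[i, j])
  }
  list(detection_rate = matched / nt,
       rmse = if (matched > 0) sqrt(mean(errs^2)) else NA_real_,
       n_true = nt, n_detected = set$n, n_matched = matched)
}

#' Puncta density per concentric nuclear zone
#'
#' Density in zone j is `n_j * 250 / A_j`: the number of puncta whose
#' centroids fall in zone j per 250-px^2 unit of zone area. Puncta whose
#' centroids fall outside all zones (outside the fitted ellipse) are counted
#' in none and reported via `n_outside`.
#'
#' @param set a `puncta_set`.
#' @param partition a `zone_partition` for the same nucleus.
#' @return list with `density` (numeric, one value per zone), `counts`
#'   (`n_j`), and `n_outside`.
#' @export
zone_densities <- function(set, partition) {
  stopifnot(inherits(set, "puncta_set"), inherits(partition, "zone_partition"))
  if (any(partition$areas == 0))
    stop("zone_densities: invalid partition (zone with zero area)")
  z <- partition$zones
  p <- set$props
  nz <- partition$n_zones
  if (nrow(p) == 0)
    return(list(density = rep(0, nz), counts = rep(0L, nz), n_outside = 0L))
  r <- pmin(pmax(round(p$centroid_row), 1L), nrow(z))
  cc <- pmin(pmax(round(p$centroid_col), 1L), ncol(z))
  zl <- z[cbind(r, cc)]
  counts <- tabulate(zl[zl > 0], nbins = nz)
  list(density = counts * 250 / partition$areas,
       counts = counts, n_outside = sum(zl == 0))
}
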