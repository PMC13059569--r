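# Extraction of single-nucleus crops from multi-cell fields (classical
# segmentation), quality-control rejection rules, and zero padding onto the
# fixed classifier canvas.

#' Classical nucleus segmentation of a multi-cell DNA-channel field
#'
#' Otsu threshold on a lightly smoothed copy of the DNA channel, hole
#' filling, Euclidean distance transform, and watershed on the inverted
#' distance map to split touching nuclei. Returns an instance label mask
#' (0 = background). A field with no foreground yields an all-zero mask.
#'
#' @param dna_channel numeric matrix (DNA/Hoechst channel of the field).
#' @param smooth_sigma Gaussian pre-smoothing sd in px.
#' @param tolerance,ext watershed maxima parameters; the defaults merge the
#'   shallow distance-map maxima inside one nucleus while still separating
#'   nuclei touching along a short boundary.
#' @param min_area instances smaller than this many px^2 are discarded as
#'   debris before QC.
#' @return integer matrix of instance labels.
#' @export
segment_field_classical <- function(dna_channel, smooth_sigma = 2,
                                    tolerance = 10, ext = 7L,
                                    min_area = 500) {
  stopifnot(is.matrix(dna_channel))
  sm <- if (smooth_sigma > 0) gaussian_blur(dna_channel, smooth_sigma) else dna_channel
  if (length(unique(as.vector(sm))) < 2)
    return(matrix(0L, nrow(dna_channel), ncol(dna_channel)))
  thr <- multiotsu_thresholds(as.vector(sm), n_classes = 2L)
  fg <- sm > thr
  # contrast guard: on a foreground-free field Otsu merely splits the noise;
  # require clear bimodal separation before accepting any foreground
  if (!any(fg) ||
      mean(sm[fg]) - mean(sm[!fg]) < 3 * stats::sd(sm[!fg]))
    return(matrix(0L, nrow(dna_channel), ncol(dna_channel)))
  fg <- matrix(EBImage::fillHull(fg) > 0, nrow(fg), ncol(fg))
  d <- EBImage::distmap(fg)
  w <- EBImage::watershed(d, tolerance = tolerance, ext = ext)
  labels <- matrix(as.integer(w), nrow(fg), ncol(fg))
  sizes <- tabulate(labels[labels > 0])
  drop <- which(sizes < min_area)
  if (length(drop)) labels[labels %in% drop] <- 0L
  relabel_consecutive(labels)
}

#' Per-instance segment records for QC
#'
#' Builds one record per instance of a label mask: bounding box (1-based,
#' inclusive), side lengths, pixel area, roundness and box aspect ratio
#' (long side / short side). The batch aspect z-score and the accept/reject
#' decision are added by [qc_filter()].
#'
#' @param instance_mask integer label matrix.
#' @return data.frame with one row per instance.
#' @export
segment_records <- function(instance_mask) {
  ids <- sort(unique(instance_mask[instance_mask > 0]))
  rec <- data.frame(instance = integer(), row0 = integer(), col0 = integer(),
                    row1 = integer(), col1 = integer(), side_rows = integer(),
                    side_cols = integer(), area = integer(),
                    roundness = numeric(), aspect_ratio = numeric())
  for (id in ids) {
    idx <- which(instance_mask == id, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    sides <- c(r1 - r0 + 1L, c1 - c0 + 1L)
    rec <- rbind(rec, data.frame(
      instance = id, row0 = r0, col0 = c0, row1 = r1, col1 = c1,
      side_rows = sides[1], side_cols = sides[2],
      area = nrow(idx),
      roundness = roundness(instance_mask == id),
      aspect_ratio = max(sides) / min(sides)))
  }
  rec
}

#' Quality-control thresholds for segmented nuclei
#'
#' @param aspect_z_max reject when the batch z-score of the box aspect ratio
#'   exceeds this (default 1.5).
#' @param side_range acceptable bounding-box side lengths in px
#'   (default 200..600).
#' @param area_px area threshold in px^2 (default 30000).
#' @param area_rule_direction `"less"` (default) rejects nuclei with area
#'   *below* `area_px` (small-outlier rejection, consistent with the other
#'   thresholds); `"greater"` rejects area above it.
#' @param roundness_min reject when roundness falls below this (default 0.7).
#' @return list of thresholds for [qc_filter()].
#' @export
qc_thresholds <- function(aspect_z_max = 1.5, side_range = c(200, 600),
                          area_px = 30000, area_rule_direction = c("less", "greater"),
                          roundness_min = 0.7) {
  list(aspect_z_max = aspect_z_max, side_range = side_range,
       area_px = area_px,
       area_rule_direction = match.arg(area_rule_direction),
       roundness_min = roundness_min)
}

#' Apply the QC rejection rules to a batch of segment records
#'
#' A record is rejected when its box aspect-ratio z-score (sample sd over
#' the batch; 0 by convention for batches of fewer than 2 records) exceeds
#' `aspect_z_max`, any bounding-box side falls outside `side_range`, the
#' pixel area fails the area rule, or roundness falls below `roundness_min`.
#' Every rejection lists its reasons.
#'
#' @param records data.frame from [segment_records()].
#' @param thresholds list from [qc_thresholds()].
#' @return the records with added columns `aspect_z`, `accepted` and
#'   `reject_reasons` (semicolon-separated; empty when accepted).
#' @export
qc_filter <- function(records, thresholds = qc_thresholds()) {
  n <- nrow(records)
  if (n == 0) {
    records$aspect_z <- numeric(0); records$accepted <- logical(0)
    records$reject_reasons <- character(0)
    return(records)
  }
  th <- thresholds
  z <- if (n >= 2 && stats::sd(records$aspect_ratio) > 0)
    (records$aspect_ratio - mean(records$aspect_ratio)) / stats::sd(records$aspect_ratio)
  else rep(0, n)
  records$aspect_z <- z
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    rs <- character(0)
    if (z[i] > th$aspect_z_max) rs <- c(rs, "aspect_z")
    sides <- c(records$side_rows[i], records$side_cols[i])
    if (any(sides < th$side_range[1] | sides > th$side_range[2]))
      rs <- c(rs, "side_length")
    bad_area <- if (th$area_rule_direction == "less")
      records$area[i] < th$area_px else records$area[i] > th$area_px
    if (bad_area) rs <- c(rs, "area")
    if (records$roundness[i] < th$roundness_min) rs <- c(rs, "roundness")
    reasons[[i]] <- rs
  }
  records$accepted <- lengths(reasons) == 0
  records$reject_reasons <- vapply(reasons, paste, "", collapse = ";")
  records
}

#' Extract per-nucleus crops from a field
#'
#' @param field list with `channels` (named matrices) and `instance_mask`,
#'   e.g. from [generate_multicell_field()].
#' @param records segment records (only rows with `accepted == TRUE` are
#'   used when the column is present).
#' @param pitch_nm pixel pitch carried into each crop.
#' @return list of `nucleus_image` crops; each carries attribute `offset`
#'   (top-left field coordinate of the crop) and `instance`.
#' @export
extract_crops <- function(field, records, pitch_nm = field$pitch_nm %||% 50) {
  if ("accepted" %in% names(records)) records <- records[records$accepted, ]
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    rr <- r$row0:r$row1; cc <- r$col0:r$col1
    chans <- lapply(field$channels, function(m) m[rr, cc, drop = FALSE])
    img <- structure(list(channels = chans,
                          mask = field$instance_mask[rr, cc] == r$instance,
                          pitch_nm = pitch_nm),
                     class = "nucleus_image")
    attr(img, "offset") <- c(row = r$row0, col = r$col0)
    attr(img, "instance") <- r$instance
    out[[i]] <- img
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero-pad a nucleus crop onto the fixed classifier canvas
#'
#' The crop is centered on a `canvas` x `canvas` zero canvas; the mask is
#' padded identically and the centering offsets are recorded in attribute
#' `pad_offset`, so features can be mapped back to crop coordinates.
#'
#' @param crop a `nucleus_image` (or a single matrix).
#' @param canvas canvas side length, px (default 600).
#' @return padded object of the same type.
#' @export
pad_to_canvas <- function(crop, canvas = 600L) {
  pad1 <- function(m) {
    d <- dim(m)
    if (any(d > canvas))
      stop("pad_to_canvas: crop (", d[1], "x", d[2], ") larger than canvas ", canvas)
    off <- floor((canvas - d) / 2)
    out <- matrix(if (is.logical(m)) FALSE else 0, canvas, canvas)
    out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- m
    attr(out, "pad_offset") <- off
    out
  }
  if (is.matrix(crop)) return(pad1(crop))
  stopifnot(inherits(crop, "nucleus_image"))
  chans <- lapply(crop$channels, pad1)
  mask <- pad1(crop$mask)
  out <- structure(list(channels = lapply(chans, function(m) { attr(m, "pad_offset") <- NULL; m }),
                        mask = matrix(as.logical(mask), canvas, canvas),
                        pitch_nm = crop$pitch_nm),
                   class = "nucleus_image")
  attr(out, "pad_offset") <- attr(mask, "pad_offset")
  attr(out, "offset") <- attr(crop, "offset")
  attr(out, "instance") <- attr(crop, "instance")
  out
}
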