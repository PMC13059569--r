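# Score-CAM heatmap generation and quantification.
#
# Score-CAM is gradient-free class activation mapping: each spatial
# activation map of a target layer is upsampled, min-max normalized, used to
# mask the input, and the masked input's class score weights that map in a
# softmax-weighted sum; a final ReLU keeps the per-pixel score S(p)
# nonnegative. Two nuclear metrics summarize a heatmap: the mean score over
# nonzero mask pixels (nuclear intensity) and the ratio of the outermost
# concentric zone's mean score to it (nuclear periphery enrichment).

#' Score-CAM heatmap for one input image
#'
#' @param model trained `nucleo_model`.
#' @param image H x W matrix (pseudo-RGB applied internally) or H x W x 3
#'   array, on the raw intensity scale used in training.
#' @param mask optional binary nucleus mask linked to the heatmap (required
#'   by the nuclear metrics).
#' @param target_class class whose score weights the maps (1 = perturbed,
#'   the positive logit; 0 uses the negated logit).
#' @param layer target layer: `"last_conv"` (default), `"conv1"` or
#'   `"block1"`..`"block4"`.
#' @param batch_size masked-input forward-pass batch size.
#' @return object of class `cam_heatmap`: list with `S` (nonnegative score
#'   matrix), `mask`, `ellipse` (an `ellipse_fit` of the mask, if given).
#' @export
score_cam <- function(model, image, mask = NULL, target_class = 1L,
                      layer = "last_conv", batch_size = 16L) {
  x3 <- if (is.matrix(image)) to_pseudo_rgb(image) else image
  stopifnot(length(dim(x3)) == 3, dim(x3)[3] == 3)
  H <- dim(x3)[1]; W <- dim(x3)[2]
  x4 <- array(x3 / model$input_scale, dim = c(H, W, 3L, 1L))
  fwd <- nn_forward(model, x4, capture = layer)
  act <- fwd$captured
  if (is.null(act)) stop("score_cam: unknown target layer '", layer, "'")
  K <- dim(act)[3]
  maps <- vector("list", K); keep <- logical(K)
  for (k in seq_len(K)) {
    up <- bilinear_resize(act[, , k, 1], H, W)
    rng <- range(up)
    if (rng[2] - rng[1] <= 0) next
    maps[[k]] <- (up - rng[1]) / (rng[2] - rng[1])
    keep[k] <- TRUE
  }
  if (!any(keep)) {
    warning("score_cam: all activation maps constant; heatmap is zero")
    return(new_cam_heatmap(matrix(0, H, W), mask))
  }
  if (any(!keep))
    warning("score_cam: ", sum(!keep), " constant activation map(s) skipped")
  kept <- which(keep)
  scores <- numeric(length(kept))
  for (b0 in seq(1, length(kept), by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1, length(kept))
    xb <- array(0, dim = c(H, W, 3L, length(bi)))
    for (m in seq_along(bi))
      xb[, , , m] <- (x3 * array(maps[[kept[bi[m]]]], dim = dim(x3))) / model$input_scale
    lg <- nn_forward(model, xb)$logits
    scores[bi] <- if (target_class == 1L) lg else -lg
  }
  wts <- exp(scores - max(scores)); wts <- wts / sum(wts)
  S <- matrix(0, H, W)
  for (m in seq_along(kept)) S <- S + wts[m] * maps[[kept[m]]]
  S[S < 0] <- 0
  new_cam_heatmap(S, mask)
}

new_cam_heatmap <- function(S, mask) {
  ell <- if (!is.null(mask) && any(mask != 0)) fit_ellipse(mask) else NULL
  structure(list(S = S, mask = mask, ellipse = ell), class = "cam_heatmap")
}

#' Construct a heatmap object from a precomputed score matrix
#' @param S nonnegative score matrix.
#' @param mask binary nucleus mask of the same shape.
#' @return a `cam_heatmap`.
#' @export
cam_heatmap <- function(S, mask = NULL) {
  stopifnot(is.matrix(S), all(S >= 0))
  if (!is.null(mask)) stopifnot(all(dim(mask) == dim(S)))
  new_cam_heatmap(S, mask)
}

#' Nuclear intensity of a Score-CAM heatmap
#'
#' Mean score over M, the mask pixels with strictly positive score. With no
#' such pixel the metric is missing (`NA`), never 0.
#'
#' @param heatmap a `cam_heatmap` with a mask.
#' @return mean score, or `NA`.
#' @export
nuclear_intensity <- function(heatmap) {
  stopifnot(inherits(heatmap, "cam_heatmap"), !is.null(heatmap$mask))
  m <- heatmap$mask != 0 & heatmap$S > 0
  if (!any(m)) return(NA_real_)
  mean(heatmap$S[m])
}

#' Nuclear periphery enrichment of a Score-CAM heatmap
#'
#' Mean score over ALL pixels of the outermost zone (zeros included in that
#' mean) divided by the nuclear intensity (whose mean excludes zero-score
#' pixels) -- the two means deliberately treat zeros differently, matching
#' the definitions of the two quantities.
#'
#' @param heatmap a `cam_heatmap` with a mask.
#' @param partition a `zone_partition` of the same nucleus.
#' @return enrichment ratio >= 0, or `NA` when the denominator is undefined.
#' @export
periphery_enrichment <- function(heatmap, partition) {
  stopifnot(inherits(partition, "zone_partition"))
  den <- nuclear_intensity(heatmap)
  if (is.na(den) || den == 0) return(NA_real_)
  r5 <- partition$zones == partition$n_zones
  if (!any(r5)) return(NA_real_)
  mean(heatmap$S[r5]) / den
}

#' Align heatmaps to a canonical ellipse frame and average them
#'
#' Each heatmap is rotated by minus its nucleus orientation and
#' anisotropically scaled so the fitted semi-axes (a, b) map onto the
#' canonical `(a0, b0)` (major axis horizontal, nucleus centered); the
#' aligned maps are resampled bilinearly onto a common canvas and averaged
#' pixel-wise.
#'
#' @param heatmaps nonempty list of `cam_heatmap`s with valid ellipse fits.
#' @param canonical canonical semi-axes `(a0, b0)` in px (default 150, 100).
#' @param canvas_size side of the square output canvas (default fits the
#'   canonical ellipse with a margin).
#' @return matrix: the pixel-wise mean aligned heatmap.
#' @export
align_and_average <- function(heatmaps, canonical = c(150, 100),
                              canvas_size = NULL) {
  if (length(heatmaps) == 0) stop("align_and_average: empty heatmap list")
  a0 <- canonical[1]; b0 <- canonical[2]
  if (is.null(canvas_size)) canvas_size <- 2L * ceiling(a0) + 21L
  cen <- (canvas_size + 1) / 2
  acc <- matrix(0, canvas_size, canvas_size)
  rows <- matrix(seq_len(canvas_size), canvas_size, canvas_size)
  cols <- matrix(seq_len(canvas_size), canvas_size, canvas_size, byrow = TRUE)
  vc <- rows - cen; uc <- cols - cen
  for (hm in heatmaps) {
    ell <- hm$ellipse
    if (is.null(ell)) stop("align_and_average: heatmap without an ellipse fit")
    u <- uc * ell$a / a0; v <- vc * ell$b / b0
    ct <- cos(ell$theta); st <- sin(ell$theta)
    sr <- ell$center[1] + u * st + v * ct
    sc <- ell$center[2] + u * ct - v * st
    acc <- acc + bilinear_sample(hm$S, sr, sc)
  }
  acc / length(heatmaps)
}

# ---- resampling helpers ----------------------------------------------------

# sample matrix m at fractional (rows, cols); outside -> 0
bilinear_sample <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- numeric(length(ri))
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    out
  }
  dim_ <- dim(rows)
  r0v <- as.vector(r0); c0v <- as.vector(c0)
  frv <- as.vector(fr); fcv <- as.vector(fc)
  out <- val(r0v, c0v) * (1 - frv) * (1 - fcv) +
    val(r0v + 1, c0v) * frv * (1 - fcv) +
    val(r0v, c0v + 1) * (1 - frv) * fcv +
    val(r0v + 1, c0v + 1) * frv * fcv
  if (!is.null(dim_)) dim(out) <- dim_
  out
}

# resize a matrix to (H, W) by bilinear interpolation of pixel centers
bilinear_resize <- function(m, H, W) {
  sr <- (seq_len(H) - 0.5) * nrow(m) / H + 0.5
  sc <- (seq_len(W) - 0.5) * ncol(m) / W + 0.5
  sr <- pmin(pmax(sr, 1), nrow(m)); sc <- pmin(pmax(sc, 1), ncol(m))
  bilinear_sample(m, matrix(sr, H, W), matrix(sc, H, W, byrow = TRUE))
}

# ---- feature battery -------------------------------------------------------

#' Version tag of the frozen CAM feature battery
#' @export
cam_battery_version <- "1.0"

#' Standard image-feature battery over a Score-CAM heatmap
#'
#' A frozen, versioned battery of region features in five categories --
#' Size (area, axis lengths, equivalent diameter), Shape (roundness,
#' eccentricity, elongation, extent), Intensity (mean, sd, percentiles,
#' MAD), Edge (Sobel-gradient edge count and statistics) and Texture
#' (histogram entropy plus a Haralick subset) -- computed inside the
#' nucleus mask. Category fractions of significant features are reproducible
#' across runs for a given battery version.
#'
#' @param heatmap a `cam_heatmap` with a nonempty mask.
#' @return data.frame with `feature`, `category`, `value`; attribute
#'   `battery_version`.
#' @export
cam_feature_battery <- function(heatmap) {
  stopifnot(inherits(heatmap, "cam_heatmap"), !is.null(heatmap$mask))
  mask <- heatmap$mask != 0
  if (!any(mask)) stop("cam_feature_battery: empty mask")
  S <- heatmap$S
  ell <- heatmap$ellipse %||% fit_ellipse(mask)
  area <- sum(mask)
  idx <- which(mask, arr.ind = TRUE)
  bbox_area <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  vals <- S[mask]
  gm <- sobel_magnitude(S)
  gmask <- gm[mask]
  edge_thr <- 0.5 * max(gmask)
  edge_count <- if (max(gmask) > 0) sum(gmask > edge_thr) else 0L
  ent <- hist_entropy(vals)
  har <- haralick_subset(S, mask)
  feats <- c(
    size_area = area,
    size_major_axis = 2 * ell$a,
    size_minor_axis = 2 * ell$b,
    size_equiv_diameter = 2 * sqrt(area / pi),
    shape_roundness = roundness(mask),
    shape_eccentricity = sqrt(max(0, 1 - (ell$b / ell$a)^2)),
    shape_elongation = ell$a / ell$b,
    shape_extent = area / bbox_area,
    intensity_mean = mean(vals),
    intensity_sd = stats::sd(vals),
    intensity_p10 = stats::quantile(vals, 0.1, names = FALSE),
    intensity_median = stats::median(vals),
    intensity_p90 = stats::quantile(vals, 0.9, names = FALSE),
    intensity_mad = stats::mad(vals),
    edge_count = edge_count,
    edge_density = edge_count / area,
    edge_gradient_mean = mean(gmask),
    edge_gradient_sd = stats::sd(gmask),
    texture_entropy = ent,
    texture_haralick_asm = har["asm"],
    texture_haralick_contrast = har["con"],
    texture_haralick_idm = har["idm"],
    texture_haralick_entropy = har["ent"]
  )
  category <- sub("_.*", "", names(feats))
  category <- c(size = "Size", shape = "Shape", intensity = "Intensity",
                edge = "Edge", texture = "Texture")[category]
  out <- data.frame(feature = names(feats), category = unname(category),
                    value = unname(feats), row.names = NULL)
  attr(out, "battery_version") <- cam_battery_version
  out
}

#' Category mapping of the CAM feature battery
#' @param battery a data.frame from [cam_feature_battery()].
#' @return named character vector feature -> category for
#'   [category_significance()].
#' @export
cam_battery_categories <- function(battery) {
  stats::setNames(battery$category, battery$feature)
}

sobel_magnitude <- function(m) {
  shift <- function(x, dr, dc) {
    nr <- nrow(x); nc <- ncol(x)
    ri <- pmin(pmax(seq_len(nr) + dr, 1), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1), nc)
    x[ri, ci, drop = FALSE]
  }
  sx <- (shift(m, -1, 1) + 2 * shift(m, 0, 1) + shift(m, 1, 1)) -
    (shift(m, -1, -1) + 2 * shift(m, 0, -1) + shift(m, 1, -1))
  sy <- (shift(m, 1, -1) + 2 * shift(m, 1, 0) + shift(m, 1, 1)) -
    (shift(m, -1, -1) + 2 * shift(m, -1, 0) + shift(m, -1, 1))
  sqrt(sx^2 + sy^2)
}

hist_entropy <- function(vals, bins = 64L) {
  if (diff(range(vals)) == 0) return(0)
  h <- tabulate(cut(vals, breaks = bins, labels = FALSE), nbins = bins)
  p <- h[h > 0] / sum(h)
  -sum(p * log2(p))
}

haralick_subset <- function(S, mask) {
  out <- c(asm = NA_real_, con = NA_real_, idm = NA_real_, ent = NA_real_)
  ref <- S
  mx <- max(ref[mask])
  if (mx > 0) ref <- ref / mx
  h <- tryCatch(
    EBImage::computeFeatures.haralick(matrix(as.integer(mask), nrow(S), ncol(S)),
                                      ref),
    error = function(e) NULL)
  if (!is.null(h) && nrow(h) >= 1) {
    out["asm"] <- h[1, "h.asm.s1"]; out["con"] <- h[1, "h.con.s1"]
    out["idm"] <- h[1, "h.idm.s1"]; out["ent"] <- h[1, "h.ent.s1"]
  }
  out
}
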