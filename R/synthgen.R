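# Synthetic single-nucleus image simulator with known ground truth.
#
# Emulates single-nucleus crops from multi-channel super-resolution imaging:
# an elliptical DNA-stained nucleus plus bright punctate foci in two marker
# channels (H3K27ac, CTCF), with controllable puncta count, size, intensity,
# radial placement across five concentric zones, inter-channel
# colocalization, background and noise. Every generated quantity is recorded
# as ground truth so downstream stages can be validated without real data.

#' Configuration for the synthetic nucleus generator
#'
#' @param canvas_size canvas side length in px (images are square).
#' @param pixel_pitch_nm physical pixel pitch, nm/px.
#' @param ellipse_a,ellipse_b ranges (min, max) in px for the nucleus
#'   semi-major / semi-minor axes; sampled uniformly per nucleus.
#' @param channels names of the marker channels.
#' @param puncta_count_mean expected puncta count per marker channel
#'   (recycled across channels).
#' @param puncta_count_dispersion negative-binomial size parameter for the
#'   count distribution; `Inf` (default) gives Poisson counts.
#' @param puncta_radius range (min, max) px of punctum radius; the rendered
#'   focus is an isotropic 2D Gaussian with sigma = radius/2 (a
#'   PSF-convolved spot, not a hard disc).
#' @param puncta_peak range (min, max) of punctum peak intensity, image units.
#' @param zone_weights five nonnegative probabilities (summing to 1) of
#'   placing a punctum in concentric zones 1 (innermost) .. 5 (periphery);
#'   placement is uniform by area within the chosen zone.
#' @param min_separation minimum centre-to-centre distance (px) between
#'   puncta of the same channel; enforced by rejection sampling (0 = off).
#' @param coloc_fraction fraction in [0, 1] of channel-2 puncta placed at
#'   channel-1 punctum positions (colocalized), the rest independent.
#' @param coloc_jitter Gaussian jitter (px sd) applied to colocalized
#'   positions.
#' @param background_level constant background, image units.
#' @param noise_sigma additive Gaussian noise sd, image units.
#' @param dna_fill DNA-channel fill intensity of the nucleus interior.
#' @param edge_smooth_sigma Gaussian sigma (px) smoothing the DNA edge.
#' @param extra_foci optional list(`channel`, `count`, `radius`, `peak`,
#'   `quadrant` in 1..4) adding a second punctum population confined to one
#'   quadrant of the ellipse frame; used for localization studies.
#' @return a validated object of class `synth_config`.
#' @export
synth_config <- function(canvas_size = 600L,
                         pixel_pitch_nm = 50,
                         ellipse_a = c(180, 230),
                         ellipse_b = c(120, 170),
                         channels = c("H3K27ac", "CTCF"),
                         puncta_count_mean = 50,
                         puncta_count_dispersion = Inf,
                         puncta_radius = c(2, 5),
                         puncta_peak = c(500, 1500),
                         zone_weights = rep(0.2, 5),
                         min_separation = 0,
                         coloc_fraction = 0,
                         coloc_jitter = 0,
                         background_level = 100,
                         noise_sigma = 10,
                         dna_fill = 800,
                         edge_smooth_sigma = 2,
                         extra_foci = NULL) {
  cfg <- list(canvas_size = as.integer(canvas_size),
              pixel_pitch_nm = pixel_pitch_nm,
              ellipse_a = sort(ellipse_a), ellipse_b = sort(ellipse_b),
              channels = channels,
              puncta_count_mean = rep_len(puncta_count_mean, length(channels)),
              puncta_count_dispersion = puncta_count_dispersion,
              puncta_radius = sort(puncta_radius),
              puncta_peak = sort(puncta_peak),
              zone_weights = zone_weights,
              min_separation = min_separation,
              coloc_fraction = coloc_fraction,
              coloc_jitter = coloc_jitter,
              background_level = background_level,
              noise_sigma = noise_sigma,
              dna_fill = dna_fill,
              edge_smooth_sigma = edge_smooth_sigma,
              extra_foci = extra_foci)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (length(cfg$zone_weights) != 5 || any(cfg$zone_weights < 0) ||
      abs(sum(cfg$zone_weights) - 1) > 1e-9)
    stop("synth_config: zone_weights must be 5 nonnegative values summing to 1")
  if (cfg$coloc_fraction < 0 || cfg$coloc_fraction > 1)
    stop("synth_config: coloc_fraction must lie in [0, 1]")
  if (any(c(cfg$puncta_radius, cfg$puncta_peak, cfg$ellipse_a, cfg$ellipse_b,
            cfg$background_level, cfg$noise_sigma, cfg$coloc_jitter) < 0))
    stop("synth_config: ranges and levels must be nonnegative")
  if (cfg$puncta_radius[2] > cfg$ellipse_b[1])
    stop("synth_config: puncta radius larger than the ellipse minor semi-axis")
  if (2 * cfg$ellipse_a[2] >= cfg$canvas_size)
    stop("synth_config: canvas does not accommodate the largest ellipse")
  if (!is.null(cfg$extra_foci)) {
    ef <- cfg$extra_foci
    stopifnot(is.list(ef), ef$channel %in% cfg$channels,
              ef$count >= 0, ef$quadrant %in% 1:4)
  }
  invisible(cfg)
}

# evaluate expr under a private RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one synthetic single-nucleus image with ground truth
#'
#' The DNA channel is a filled, edge-smoothed ellipse; each marker channel is
#' background plus a sum of isotropic 2D Gaussian foci at positions sampled
#' radially according to `zone_weights` (uniform by area within the chosen
#' zone), plus Gaussian noise. Identical `(config, seed)` reproduce the
#' output bit-exactly.
#'
#' @param config a `synth_config`.
#' @param seed integer seed.
#' @return list with `image` (class `nucleus_image`: named channel matrices
#'   incl. `DNA`, binary `mask`, `pitch_nm`) and `truth` (class
#'   `ground_truth`: the `ellipse_fit`-style true ellipse, per-channel
#'   data.frames of centroids/radii/peaks, `class_label`).
#' @export
generate_nucleus <- function(config, seed) {
  validate_synth_config(config)
  with_seed(seed, generate_nucleus_impl(config))
}

generate_nucleus_impl <- function(config, add_background = TRUE) {
  n <- config$canvas_size
  a <- runif(1, config$ellipse_a[1], config$ellipse_a[2])
  b <- runif(1, config$ellipse_b[1], config$ellipse_b[2])
  if (b > a) { tmp <- a; a <- b; b <- tmp }
  theta <- runif(1, 0, pi)
  ell <- structure(list(center = c(row = (n + 1) / 2, col = (n + 1) / 2),
                        a = a, b = b, theta = theta),
                   class = "ellipse_fit")
  rho <- elliptical_radius(ell, c(n, n))
  mask <- rho <= 1

  dna <- matrix(0, n, n)
  dna[mask] <- config$dna_fill
  if (config$edge_smooth_sigma > 0)
    dna <- gaussian_blur(dna, sigma = config$edge_smooth_sigma)

  nch <- length(config$channels)
  truth_ch <- vector("list", nch); names(truth_ch) <- config$channels
  chans <- vector("list", nch); names(chans) <- config$channels

  for (ci in seq_len(nch)) {
    mu <- config$puncta_count_mean[ci]
    cnt <- if (is.finite(config$puncta_count_dispersion))
      rnbinom(1, size = config$puncta_count_dispersion, mu = mu)
    else rpois(1, mu)
    if (ci == 2 && config$coloc_fraction > 0 && nrow(truth_ch[[1]]) > 0) {
      k <- round(config$coloc_fraction * cnt)
      k <- min(k, cnt)
      src <- truth_ch[[1]]
      idx <- ((seq_len(k) - 1) %% nrow(src)) + 1
      pos_c <- cbind(src$row[idx], src$col[idx])
      if (config$coloc_jitter > 0)
        pos_c <- pos_c + matrix(rnorm(2 * k, 0, config$coloc_jitter), ncol = 2)
      pos_i <- sample_zone_positions(cnt - k, ell, config$zone_weights,
                                     config$min_separation, pos_c)
      pos <- rbind(pos_c, pos_i)
    } else {
      pos <- sample_zone_positions(cnt, ell, config$zone_weights,
                                   config$min_separation)
    }
    radii <- runif(nrow(pos), config$puncta_radius[1], config$puncta_radius[2])
    peaks <- runif(nrow(pos), config$puncta_peak[1], config$puncta_peak[2])
    df <- data.frame(row = pos[, 1], col = pos[, 2],
                     radius = radii, peak = peaks,
                     extra = logical(nrow(pos)))
    if (!is.null(config$extra_foci) &&
        config$extra_foci$channel == config$channels[ci] &&
        config$extra_foci$count > 0) {
      ef <- config$extra_foci
      epos <- sample_quadrant_positions(ef$count, ell, ef$quadrant)
      eradii <- runif(ef$count, min(ef$radius), max(ef$radius))
      epeaks <- runif(ef$count, min(ef$peak), max(ef$peak))
      df <- rbind(df, data.frame(row = epos[, 1], col = epos[, 2],
                                 radius = eradii, peak = epeaks, extra = TRUE))
    }
    img <- render_puncta(n, df)
    chans[[ci]] <- img
    truth_ch[[ci]] <- df
  }

  if (add_background) {
    for (ci in seq_len(nch))
      chans[[ci]] <- pmax(chans[[ci]] + config$background_level +
                            matrix(rnorm(n * n, 0, config$noise_sigma), n, n), 0)
    dna <- pmax(dna + matrix(rnorm(n * n, 0, config$noise_sigma), n, n), 0)
  }

  image <- structure(list(channels = c(chans, list(DNA = dna)),
                          mask = mask, pitch_nm = config$pixel_pitch_nm),
                     class = "nucleus_image")
  truth <- structure(list(ellipse = ell, channels = truth_ch,
                          class_label = NA_integer_),
                     class = "ground_truth")
  list(image = image, truth = truth)
}

# sample positions uniformly by area within zones chosen by zone_weights;
# optional minimum separation enforced by rejection sampling
sample_zone_positions <- function(cnt, ell, weights, min_sep = 0,
                                  existing = matrix(numeric(0), 0, 2)) {
  if (cnt == 0) return(matrix(numeric(0), 0, 2))
  draw1 <- function() {
    zone <- sample.int(5, 1, prob = weights)
    rho <- sqrt(runif(1, ((zone - 1) / 5)^2, (zone / 5)^2))
    phi <- runif(1, 0, 2 * pi)
    ellipse_frame_to_canvas(ell, rho, phi)
  }
  if (min_sep <= 0) {
    zone <- sample.int(5, cnt, replace = TRUE, prob = weights)
    lo <- (zone - 1) / 5; hi <- zone / 5
    rho <- sqrt(runif(cnt, lo^2, hi^2))
    phi <- runif(cnt, 0, 2 * pi)
    return(ellipse_frame_to_canvas(ell, rho, phi))
  }
  acc <- existing
  placed <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(placed) < cnt) {
    tries <- tries + 1
    if (tries > 200 * cnt)
      stop("sample_zone_positions: cannot satisfy min_separation ", min_sep)
    cand <- draw1()
    if (nrow(acc) == 0 ||
        min(sqrt((acc[, 1] - cand[1])^2 + (acc[, 2] - cand[2])^2)) >= min_sep) {
      acc <- rbind(acc, cand)
      placed <- rbind(placed, cand)
    }
  }
  placed
}

# positions uniform within one quadrant of the ellipse frame
sample_quadrant_positions <- function(cnt, ell, quadrant) {
  if (cnt == 0) return(matrix(numeric(0), 0, 2))
  rho <- sqrt(runif(cnt, 0, 0.9^2))
  base <- switch(quadrant, 0, pi / 2, pi, 3 * pi / 2)
  phi <- runif(cnt, base, base + pi / 2)
  ellipse_frame_to_canvas(ell, rho, phi)
}

ellipse_frame_to_canvas <- function(ell, rho, phi) {
  u <- ell$a * rho * cos(phi); v <- ell$b * rho * sin(phi)
  ct <- cos(ell$theta); st <- sin(ell$theta)
  dx <- u * ct - v * st; dy <- u * st + v * ct
  cbind(ell$center[1] + dy, ell$center[2] + dx)
}

# additively render isotropic Gaussian foci (sigma = radius/2) on a canvas
render_puncta <- function(n, df) {
  img <- matrix(0, n, n)
  for (i in seq_len(nrow(df))) {
    s <- df$radius[i] / 2
    half <- ceiling(3 * s)
    r0 <- max(1, floor(df$row[i] - half)); r1 <- min(n, ceiling(df$row[i] + half))
    c0 <- max(1, floor(df$col[i] - half)); c1 <- min(n, ceiling(df$col[i] + half))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    gy <- exp(-((rr - df$row[i])^2) / (2 * s^2))
    gx <- exp(-((cc - df$col[i])^2) / (2 * s^2))
    img[rr, cc] <- img[rr, cc] + df$peak[i] * outer(gy, gx)
  }
  img
}

#' Generate a labeled two-class synthetic dataset
#'
#' @param cfg_class0,cfg_class1 `synth_config`s for the two conditions.
#' @param n_per_class images per class (>= 1).
#' @param seed master seed; per-image seeds are derived deterministically.
#' @return list of `n = 2 * n_per_class` elements, each a
#'   `generate_nucleus()` result with `truth$class_label` set to 0 or 1.
#' @export
generate_dataset <- function(cfg_class0, cfg_class1, n_per_class, seed) {
  stopifnot(n_per_class >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, 2 * n_per_class))
  labels <- rep(c(0L, 1L), each = n_per_class)
  out <- vector("list", 2 * n_per_class)
  for (i in seq_along(out)) {
    cfg <- if (labels[i] == 0L) cfg_class0 else cfg_class1
    x <- generate_nucleus(cfg, seeds[i])
    x$truth$class_label <- labels[i]
    out[[i]] <- x
  }
  out
}

#' Generate a multi-nucleus field image with an instance ground-truth mask
#'
#' Nuclei are rejection-sampled onto the field so that their bounding discs
#' respect `min_gap`; each nucleus is rendered noise-free and pasted, then
#' background and noise are added once over the whole field.
#'
#' @param n_nuclei number of nuclei to place.
#' @param field_size field side length, px.
#' @param min_gap minimum gap between nucleus bounding discs, px.
#' @param config `synth_config` for individual nuclei.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling budget.
#' @return list with `channels` (named field matrices incl. DNA),
#'   `instance_mask` (integer matrix with labels 1..n_nuclei), and `truths`
#'   (per-nucleus ground truth, with centroids in field coordinates).
#' @export
generate_multicell_field <- function(n_nuclei, field_size, min_gap, config,
                                     seed, max_attempts = 1000L * n_nuclei) {
  validate_synth_config(config)
  with_seed(seed, {
    n <- config$canvas_size
    rad <- config$ellipse_a[2]
    # centers must keep both the bounding disc (+gap) and the full nucleus
    # canvas inside the field
    margin <- max(rad + min_gap / 2 + 1, (n + 1) / 2)
    lo <- margin; hi <- field_size - margin
    if (hi <= lo)
      stop("generate_multicell_field: field too small for the requested nuclei/gap")
    centers <- matrix(numeric(0), 0, 2)
    attempts <- 0
    while (nrow(centers) < n_nuclei) {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("generate_multicell_field: placement failed after ", max_attempts,
             " attempts (reduce n_nuclei or min_gap)")
      cand <- runif(2, lo, hi)
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= 2 * rad + min_gap))
        centers <- rbind(centers, cand)
    }
    chn <- c(config$channels, "DNA")
    field <- lapply(chn, function(x) matrix(0, field_size, field_size))
    names(field) <- chn
    imask <- matrix(0L, field_size, field_size)
    truths <- vector("list", n_nuclei)
    for (i in seq_len(n_nuclei)) {
      x <- generate_nucleus_impl(config, add_background = FALSE)
      off <- round(centers[i, ] - (n + 1) / 2)   # top-left offset (row, col)
      rr <- seq_len(n) + off[1]; cc <- seq_len(n) + off[2]
      for (ch in chn)
        field[[ch]][rr, cc] <- field[[ch]][rr, cc] + x$image$channels[[ch]]
      sub <- imask[rr, cc]
      sub[x$image$mask] <- i
      imask[rr, cc] <- sub
      tr <- x$truth
      tr$ellipse$center <- tr$ellipse$center + off
      for (ch in config$channels) {
        tr$channels[[ch]]$row <- tr$channels[[ch]]$row + off[1]
        tr$channels[[ch]]$col <- tr$channels[[ch]]$col + off[2]
      }
      truths[[i]] <- tr
    }
    for (ch in chn)
      field[[ch]] <- pmax(field[[ch]] + config$background_level +
                            matrix(rnorm(field_size^2, 0, config$noise_sigma),
                                   field_size, field_size), 0)
    list(channels = field, instance_mask = imask, truths = truths,
         pitch_nm = config$pixel_pitch_nm)
  })
}
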