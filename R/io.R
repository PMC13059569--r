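# Format readers/writers and the end-to-end pipeline driver.

#' Write a multi-channel image as a multi-page 16-bit TIFF
#'
#' One page per channel, in list order; values are clamped to [0, 65535]
#' and rounded, so integer-valued images round-trip bit-exactly through
#' [read_image()].
#'
#' @param image a `nucleus_image`, a named list of matrices, or a matrix.
#' @param path output file path.
#' @return the channel names written, invisibly.
#' @export
write_image <- function(image, path) {
  chans <- if (inherits(image, "nucleus_image")) image$channels
  else if (is.matrix(image)) list(image) else image
  pages <- lapply(chans, function(m) pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(names(chans))
}

#' Read a multi-channel TIFF (or a PNG mask)
#'
#' Multi-page TIFFs are returned as a named list of integer-valued matrices
#' (16-bit values as written by [write_image()]). PNG masks with values
#' {0, 255} (or {0, 1}) are normalized to {0, 1}.
#'
#' @param path input file.
#' @param channels optional channel names to assign to the TIFF pages; the
#'   page count must match, and every requested channel must be present.
#' @return named list of matrices (TIFF) or a single matrix (PNG).
#' @export
read_image <- function(path, channels = NULL) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("read_image: the 'png' package is required for PNG masks")
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    return((m > 0.5) * 1)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  if (!is.null(channels)) {
    if (length(pages) < length(channels))
      stop("read_image: channel '", channels[length(pages) + 1],
           "' not present (file has ", length(pages), " page(s))")
    pages <- pages[seq_along(channels)]
    names(pages) <- channels
  }
  pages
}

#' Write ground truth as a JSON sidecar
#' @param truth a `ground_truth`.
#' @param path output .json path.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(ellipse = list(center = as.numeric(truth$ellipse$center),
                             a = truth$ellipse$a, b = truth$ellipse$b,
                             theta = truth$ellipse$theta),
              class_label = truth$class_label,
              channels = truth$channels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

# cheap rolling hash of a configuration for CSV provenance headers
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write a feature table CSV with a provenance header
#'
#' The first line is a comment naming the units in play (px, px^2, image
#' units) and a hash of the configuration that produced the table; read it
#' back with [read_feature_csv()].
#'
#' @param df data.frame to write.
#' @param path output .csv path.
#' @param config configuration object to hash into the header.
#' @export
write_feature_csv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: px, px^2, image units; config_hash: %s",
                     if (is.null(config)) "none" else config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Pipeline run configuration
#'
#' Bundles every stage's parameters with defaults matching the reference
#' analysis (QC thresholds, puncta area cutoff 300 px^2, five zones, 11 px
#' blur kernel, 600 px canvas).
#'
#' @param synth a [synth_config()] for synthetic input (ignored when a
#'   `field` is passed to [run_pipeline()]).
#' @param n_nuclei,field_size,min_gap synthetic field layout.
#' @param qc a [qc_thresholds()] list.
#' @param canvas classifier canvas side (px).
#' @param puncta_max_area puncta area cutoff (px^2).
#' @param n_zones concentric zones.
#' @param blur_kernel odd kernel size for the low-resolution branch, or
#'   `NULL` to skip it.
#' @param seed master seed.
#' @param out_dir optional output directory for CSV/TIFF artifacts.
#' @return object of class `run_config`.
#' @export
run_config <- function(synth = synth_config(), n_nuclei = 12L,
                       field_size = 2306L, min_gap = 30, qc = qc_thresholds(),
                       canvas = 600L, puncta_max_area = 300, n_zones = 5L,
                       blur_kernel = NULL, seed = 1L, out_dir = NULL) {
  structure(list(synth = synth, n_nuclei = n_nuclei, field_size = field_size,
                 min_gap = min_gap, qc = qc, canvas = canvas,
                 puncta_max_area = puncta_max_area, n_zones = n_zones,
                 blur_kernel = blur_kernel, seed = seed, out_dir = out_dir),
            class = "run_config")
}

# per-nucleus feature rows (one per marker channel) for a padded crop
nucleus_feature_rows <- function(crop, cell_id, config) {
  markers <- setdiff(names(crop$channels), "DNA")
  ell <- fit_ellipse(crop$mask)
  part <- partition_zones(ell, dim(crop$mask), config$n_zones)
  sets <- list()
  for (ch in markers) {
    sets[[ch]] <- tryCatch(
      segment_puncta(crop$channels[[ch]], crop$mask,
                     max_area = config$puncta_max_area),
      error = function(e) NULL)
  }
  rows <- list()
  for (ch in markers) {
    s <- sets[[ch]]
    other <- setdiff(markers, ch)[1]
    so <- if (!is.na(other)) sets[[other]] else NULL
    agg <- if (!is.null(s)) puncta_aggregates(s) else NULL
    dens <- if (!is.null(s)) zone_densities(s, part) else NULL
    cl <- if (!is.null(s) && !is.null(so)) {
      md <- min_distances(s, so)
      list(mean_min_distance = md$mean_min_distance,
           overlap = suppressWarnings(overlap_ratio(s, so)))
    } else list(mean_min_distance = NA_real_, overlap = NA_real_)
    row <- data.frame(cell = cell_id, channel = ch,
                      roundness = roundness(crop$mask),
                      n_puncta = if (is.null(agg)) NA_integer_ else agg$n,
                      mean_area = if (is.null(agg)) NA_real_ else agg$mean_area,
                      mean_intensity = if (is.null(agg)) NA_real_ else agg$mean_intensity,
                      irregularity = if (is.null(agg)) NA_real_ else agg$irregularity,
                      mean_min_distance = cl$mean_min_distance,
                      overlap_ratio = cl$overlap)
    dd <- if (is.null(dens)) rep(NA_real_, config$n_zones) else dens$density
    for (j in seq_len(config$n_zones)) row[[paste0("density_part", j)]] <- dd[j]
    rows[[ch]] <- row
  }
  do.call(rbind, rows)
}

#' Run the full image-analysis pipeline on a (synthetic or supplied) field
#'
#' Segment the DNA channel, build and QC-filter segment records, extract
#' and pad accepted crops, segment puncta in each marker channel, compute
#' per-nucleus aggregates, zone densities and inter-channel colocalization,
#' and assemble a tidy feature table (one row per cell-channel). With
#' `blur_kernel` set, a parallel low-resolution feature table is produced
#' from Gaussian-blurred channels. Re-running with the same configuration
#' and seed reproduces all outputs bit-exactly.
#'
#' @param config a [run_config()].
#' @param field optional precomputed field (as from
#'   [generate_multicell_field()]); when `NULL` a synthetic field is
#'   generated from the config.
#' @param use_truth_mask use the field's ground-truth instance mask instead
#'   of the classical segmenter (synthetic fields only).
#' @return list with `features` (data.frame), `features_lowres` (or NULL),
#'   `records` (QC report), `crops`.
#' @export
run_pipeline <- function(config, field = NULL, use_truth_mask = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(field))
    field <- generate_multicell_field(config$n_nuclei, config$field_size,
                                      config$min_gap, config$synth, config$seed)
  imask <- if (use_truth_mask && !is.null(field$instance_mask))
    field$instance_mask
  else segment_field_classical(field$channels$DNA)
  field$instance_mask <- imask
  records <- qc_filter(segment_records(imask), config$qc)
  crops <- lapply(extract_crops(field, records),
                  pad_to_canvas, canvas = config$canvas)
  feature_table <- function(crops) {
    rows <- lapply(seq_along(crops), function(i)
      nucleus_feature_rows(crops[[i]], cell_id = i, config))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  features <- if (length(crops)) feature_table(crops) else NULL
  features_lowres <- NULL
  if (!is.null(config$blur_kernel) && length(crops)) {
    lr <- lapply(crops, function(cr) {
      cr$channels <- lapply(cr$channels, simulate_lowres, kernel = config$blur_kernel)
      cr
    })
    features_lowres <- feature_table(lr)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_csv(records, file.path(config$out_dir, "qc_report.csv"), config)
    if (!is.null(features))
      write_feature_csv(features, file.path(config$out_dir, "features.csv"), config)
    if (!is.null(features_lowres))
      write_feature_csv(features_lowres,
                        file.path(config$out_dir, "features_lowres.csv"), config)
  }
  list(features = features, features_lowres = features_lowres,
       records = records, crops = crops)
}
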