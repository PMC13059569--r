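# Shared fixtures, all built in code.

# rasterize a filled ellipse with known parameters on an n x n canvas
rasterize_ellipse <- function(a, b, theta = 0, n = 2 * ceiling(a) + 21) {
  ell <- structure(list(center = c(row = (n + 1) / 2, col = (n + 1) / 2),
                        a = a, b = b, theta = theta),
                   class = "ellipse_fit")
  nucleoprofiler:::elliptical_radius(ell, c(n, n)) <= 1
}

# a puncta_set built directly from centroid/axis tables (bypassing
# segmentation) for metric-level tests
puncta_set_from_table <- function(rows, cols, l_major = 4, l_minor = 4) {
  n <- length(rows)
  props <- data.frame(label = seq_len(n), area = rep(10L, n),
                      centroid_row = rows, centroid_col = cols,
                      mean_intensity = rep(1, n),
                      l_major = rep_len(l_major, n),
                      l_minor = rep_len(l_minor, n))
  props$r_eff <- (props$l_major + props$l_minor) / 4
  structure(list(labels = matrix(0L, 1, 1), props = props,
                 channel = NULL, n = n),
            class = "puncta_set")
}

# small synthetic nucleus configuration used across tests
small_synth_config <- function(...) {
  args <- list(canvas_size = 200L, ellipse_a = c(70, 80), ellipse_b = c(50, 60),
               puncta_count_mean = 20, puncta_radius = c(2, 4),
               puncta_peak = c(800, 1200), background_level = 100,
               noise_sigma = 10)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

# brute-force O(N^2) oracles for the colocalization metrics
brute_min_distances <- function(src, tgt) {
  sapply(seq_len(nrow(src)), function(i)
    min(sqrt((src[i, 1] - tgt[, 1])^2 + (src[i, 2] - tgt[, 2])^2)))
}
brute_overlap_ratio <- function(src, tgt, r_src, r_tgt) {
  hits <- sapply(seq_len(nrow(src)), function(i) {
    d <- sqrt((src[i, 1] - tgt[, 1])^2 + (src[i, 2] - tgt[, 2])^2)
    any(d <= r_src[i] + r_tgt)
  })
  mean(hits)
}
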