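test_that("generator is a pure function of (config, seed)", {
  cfg <- small_synth_config()
  x1 <- generate_nucleus(cfg, 42)
  x2 <- generate_nucleus(cfg, 42)
  expect_identical(x1, x2)
  x3 <- generate_nucleus(cfg, 43)
  expect_false(identical(x1$image$channels[[1]], x3$image$channels[[1]]))
})

test_that("zero puncta give background-only marker channels", {
  cfg <- small_synth_config(puncta_count_mean = 0)
  x <- generate_nucleus(cfg, 7)
  expect_identical(nrow(x$truth$channels$H3K27ac), 0L)
  expect_identical(nrow(x$truth$channels$CTCF), 0L)
  ch <- x$image$channels$H3K27ac
  expect_lt(abs(mean(ch) - cfg$background_level), 1)
  expect_lt(sd(ch), 2 * cfg$noise_sigma)
})

test_that("full colocalization with zero jitter copies channel-1 centroids", {
  cfg <- small_synth_config(coloc_fraction = 1, coloc_jitter = 0,
                            puncta_count_mean = 15,
                            puncta_count_dispersion = Inf)
  # force equal counts by repeated draws until they match (bounded)
  for (s in 1:50) {
    x <- generate_nucleus(cfg, s)
    n1 <- nrow(x$truth$channels$H3K27ac); n2 <- nrow(x$truth$channels$CTCF)
    if (n1 == n2 && n1 > 0) break
  }
  expect_identical(n1, n2)
  expect_equal(x$truth$channels$CTCF[, c("row", "col")],
               x$truth$channels$H3K27ac[seq_len(n2), c("row", "col")],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("all ground-truth centroids lie inside the true ellipse", {
  cfg <- small_synth_config(puncta_count_mean = 40)
  x <- generate_nucleus(cfg, 3)
  ell <- x$truth$ellipse
  for (ch in names(x$truth$channels)) {
    tr <- x$truth$channels[[ch]]
    ct <- cos(ell$theta); st <- sin(ell$theta)
    dx <- tr$col - ell$center[2]; dy <- tr$row - ell$center[1]
    u <- dx * ct + dy * st; v <- -dx * st + dy * ct
    expect_true(all((u / ell$a)^2 + (v / ell$b)^2 <= 1 + 1e-9))
  }
})

test_that("radial placement follows the zone weights (chi-squared law)", {
  w <- c(0.05, 0.15, 0.2, 0.25, 0.35)
  cfg <- small_synth_config(zone_weights = w, puncta_count_mean = 120)
  counts <- numeric(5)
  for (s in 1:90) {
    x <- generate_nucleus(cfg, 500 + s)
    ell <- x$truth$ellipse
    tr <- x$truth$channels$H3K27ac
    ct <- cos(ell$theta); st <- sin(ell$theta)
    dx <- tr$col - ell$center[2]; dy <- tr$row - ell$center[1]
    u <- dx * ct + dy * st; v <- -dx * st + dy * ct
    rho <- sqrt((u / ell$a)^2 + (v / ell$b)^2)
    z <- pmin(pmax(ceiling(rho * 5), 1), 5)
    counts <- counts + tabulate(z, 5)
  }
  expect_gt(sum(counts), 1e4)
  pval <- suppressWarnings(chisq.test(counts, p = w)$p.value)
  expect_gt(pval, 0.01)
})

test_that("colocalized fraction matches rho within binomial error", {
  rho <- 0.6
  cfg <- small_synth_config(coloc_fraction = rho, coloc_jitter = 0,
                            puncta_count_mean = 50)
  hits <- 0; tot <- 0
  for (s in 1:30) {
    x <- generate_nucleus(cfg, 900 + s)
    t1 <- x$truth$channels$H3K27ac; t2 <- x$truth$channels$CTCF
    if (nrow(t1) == 0 || nrow(t2) == 0) next
    d <- sqrt(outer(t2$row, t1$row, "-")^2 + outer(t2$col, t1$col, "-")^2)
    hits <- hits + sum(apply(d, 1, min) < 1e-9)
    tot <- tot + nrow(t2)
  }
  phat <- hits / tot
  expect_lt(abs(phat - rho), 3 * sqrt(rho * (1 - rho) / tot) + 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(small_synth_config(zone_weights = c(1, 1, 1, 1, 1)), "zone_weights")
  expect_error(small_synth_config(coloc_fraction = 1.2), "coloc_fraction")
  expect_error(small_synth_config(puncta_radius = c(2, 80)), "minor semi-axis")
  expect_error(synth_config(canvas_size = 100L, ellipse_a = c(60, 70)),
               "accommodate")
})

test_that("dataset generation yields labeled images with derived seeds", {
  cfg0 <- small_synth_config()
  cfg1 <- small_synth_config(puncta_count_mean = 40)
  ds <- generate_dataset(cfg0, cfg1, 5, seed = 21)
  expect_length(ds, 10)
  labs <- vapply(ds, function(d) d$truth$class_label, 1L)
  expect_identical(sum(labs == 0L), 5L)
  expect_identical(sum(labs == 1L), 5L)
  ds2 <- generate_dataset(cfg0, cfg1, 5, seed = 21)
  expect_identical(ds, ds2)
})

test_that("multicell fields have disjoint instances and honor min_gap limits", {
  cfg <- small_synth_config()
  fld <- generate_multicell_field(6, 1200, 30, cfg, seed = 5)
  expect_identical(sort(unique(as.vector(fld$instance_mask[fld$instance_mask > 0]))),
                   1:6)
  # single nucleus: instance mask is the ellipse mask up to translation
  f1 <- generate_multicell_field(1, 600, 10, cfg, seed = 9)
  expect_identical(sum(f1$instance_mask == 1),
                   as.integer(sum(nucleoprofiler:::elliptical_radius(
                     f1$truths[[1]]$ellipse, dim(f1$instance_mask)) <= 1)))
  expect_error(generate_multicell_field(4, 300, 10, cfg, seed = 1),
               "too small|failed")
})
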