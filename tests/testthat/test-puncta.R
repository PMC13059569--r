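test_that("multi-Otsu splits a known four-level mixture at the gaps", {
  set.seed(1)
  x <- c(rnorm(4000, 100, 5), rnorm(1500, 300, 8),
         rnorm(800, 600, 10), rnorm(400, 1000, 12))
  thr <- multiotsu_thresholds(x, 4)
  expect_length(thr, 3)
  expect_true(thr[1] > 110 && thr[1] < 290)
  expect_true(thr[2] > 310 && thr[2] < 590)
  expect_true(thr[3] > 615 && thr[3] < 985)
  expect_error(multiotsu_thresholds(rep(1, 100), 4), "untextured|distinct")
})

test_that("two well-separated Gaussian spots are segmented at their centers", {
  cfg <- synth_config(canvas_size = 200L, ellipse_a = c(70, 80),
                      ellipse_b = c(50, 60), puncta_count_mean = 2,
                      puncta_radius = c(4, 4), puncta_peak = c(1000, 1000),
                      background_level = 10, noise_sigma = 2,
                      min_separation = 30)
  for (s in 1:20) {
    x <- generate_nucleus(cfg, 600 + s)
    if (nrow(x$truth$channels$H3K27ac) == 2) break
  }
  tr <- x$truth$channels$H3K27ac
  expect_identical(nrow(tr), 2L)
  ps <- segment_puncta(x$image$channels$H3K27ac, x$image$mask)
  expect_identical(ps$n, 2L)
  rec <- puncta_recovery(tr, ps, match_radius = 1.5)
  expect_identical(rec$n_matched, 2L)
})

test_that("oversized objects are removed by the strict area cutoff", {
  # one uniform bright 19x19 square (361 px > 300) on a dim textured bed
  img <- matrix(10, 100, 100)
  set.seed(2); img <- img + matrix(runif(1e4, 0, 2), 100, 100)
  img[40:58, 40:58] <- 1000
  mask <- matrix(TRUE, 100, 100)
  ps <- segment_puncta(img, mask, max_area = 300)
  expect_identical(ps$n, 0L)
  # the identical square is kept when its area equals the cutoff exactly
  ps2 <- segment_puncta(img, mask, max_area = 361)
  expect_identical(ps2$n, 1L)
})

test_that("watershed splits a dumbbell of two overlapping discs", {
  img <- matrix(10, 80, 80)
  for (ctr in list(c(40, 32), c(40, 42))) {
    idx <- which((row(img) - ctr[1])^2 + (col(img) - ctr[2])^2 <= 36)
    img[idx] <- 1000
  }
  set.seed(3)
  img <- img + matrix(runif(6400, 0, 3), 80, 80)
  ps <- segment_puncta(img, matrix(TRUE, 80, 80))
  expect_identical(ps$n, 2L)
  expect_equal(sort(ps$props$centroid_col), c(32, 42), tolerance = 0.1 * 42)
})

test_that("isolated convex spots are never oversplit (component oracle)", {
  img <- matrix(10, 150, 150)
  centers <- list(c(25, 25), c(25, 95), c(75, 50), c(120, 120), c(120, 30))
  for (ctr in centers) {
    idx <- which((row(img) - ctr[1])^2 + (col(img) - ctr[2])^2 <= 25)
    img[idx] <- 1000
  }
  set.seed(4)
  img <- img + matrix(runif(150^2, 0, 3), 150, 150)
  ps <- segment_puncta(img, matrix(TRUE, 150, 150))
  cc <- max(EBImage::bwlabel(img > 500))
  expect_identical(ps$n, as.integer(cc))
  expect_identical(ps$n, 5L)
})

test_that("degenerate inputs are rejected", {
  expect_error(segment_puncta(matrix(5, 50, 50), matrix(TRUE, 50, 50)),
               "untextured|distinct")
  expect_error(segment_puncta(matrix(rnorm(2500), 50, 50), matrix(FALSE, 50, 50)),
               "empty")
})

test_that("segmentation is invariant to positive intensity scaling", {
  cfg <- small_synth_config(puncta_count_mean = 15, min_separation = 10)
  x <- generate_nucleus(cfg, 77)
  ch <- x$image$channels$H3K27ac
  p1 <- segment_puncta(ch, x$image$mask)
  p2 <- segment_puncta(ch * 3.7, x$image$mask)
  expect_identical(p1$labels, p2$labels)
  expect_equal(p2$props$mean_intensity, 3.7 * p1$props$mean_intensity,
               tolerance = 1e-9)
  # raising max_area never decreases the count
  p3 <- segment_puncta(ch, x$image$mask, max_area = 1000)
  expect_gte(p3$n, p1$n)
})

test_that("aggregate features follow the stated formulas", {
  s <- puncta_set_from_table(c(10, 20, 30), c(10, 20, 30))
  s$props$area <- c(10L, 20L, 30L)
  s$props$mean_intensity <- c(100, 200, 600)
  s$props$l_major <- c(4, 10, 6); s$props$l_minor <- c(4, 6, 6)
  agg <- puncta_aggregates(s)
  expect_identical(agg$n, 3L)
  expect_equal(agg$mean_area, 20)
  expect_equal(agg$mean_intensity, 300)
  expect_equal(agg$irregularity, mean(c(1, 10 / 6, 1)), tolerance = 1e-12)

  empty <- puncta_set_from_table(numeric(0), numeric(0))
  agg0 <- puncta_aggregates(empty)
  expect_identical(agg0$n, 0L)
  expect_true(is.na(agg0$mean_area) && is.na(agg0$irregularity))
})

test_that("a single rasterized circular punctum has irregularity ~1", {
  img <- matrix(10, 60, 60)
  idx <- which((row(img) - 30)^2 + (col(img) - 30)^2 <= 36)
  img[idx] <- 1000
  set.seed(5)
  img <- img + matrix(runif(3600, 0, 3), 60, 60)
  agg <- puncta_aggregates(segment_puncta(img, matrix(TRUE, 60, 60)))
  expect_equal(agg$irregularity, 1, tolerance = 0.1)
})

test_that("zone densities follow n_j * 250 / A_j and conserve counts", {
  m <- rasterize_ellipse(60, 40, 0, n = 141)
  part <- partition_zones(fit_ellipse(m), dim(m))
  # place 4 puncta at the center (zone 1) and one outside the ellipse
  s <- puncta_set_from_table(c(71, 71, 72, 72, 3), c(71, 72, 71, 72, 3))
  zd <- zone_densities(s, part)
  expect_identical(zd$counts[1], 4L)
  expect_identical(sum(zd$counts) + zd$n_outside, 5L)
  expect_equal(zd$density[1], 4 * 250 / part$areas[1], tolerance = 1e-12)
  expect_true(all(zd$density[2:5] == 0))

  empty <- puncta_set_from_table(numeric(0), numeric(0))
  zd0 <- zone_densities(empty, part)
  expect_true(all(zd0$density == 0))
})

test_that("puncta placed only in zone 1 give zero outer-zone densities", {
  cfg <- small_synth_config(zone_weights = c(1, 0, 0, 0, 0),
                            puncta_count_mean = 10)
  x <- generate_nucleus(cfg, 12)
  ps <- segment_puncta(x$image$channels$H3K27ac, x$image$mask)
  part <- partition_zones(x$truth$ellipse, dim(x$image$mask))
  zd <- zone_densities(ps, part)
  expect_gt(zd$density[1], 0)
  expect_true(all(zd$density[3:5] == 0))
})
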