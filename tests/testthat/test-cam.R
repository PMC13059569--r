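test_that("nuclear intensity averages only strictly positive mask pixels", {
  mask <- matrix(FALSE, 20, 20); mask[5:14, 5:14] <- TRUE   # 100 px
  S <- matrix(0, 20, 20); S[mask] <- 2.5
  expect_equal(nuclear_intensity(cam_heatmap(S, mask)), 2.5)
  # half the mask zero: zeros are excluded from M by definition
  S2 <- matrix(0, 20, 20); S2[5:14, 5:9] <- 1.0
  expect_equal(nuclear_intensity(cam_heatmap(S2, mask)), 1.0)
  # all-zero heatmap: missing, not zero
  expect_true(is.na(nuclear_intensity(cam_heatmap(matrix(0, 20, 20), mask))))
})

test_that("periphery enrichment reproduces the closed-form fixtures", {
  m <- rasterize_ellipse(40, 25, 0.3, n = 101)
  part <- partition_zones(fit_ellipse(m), dim(m))
  interior <- part$zones > 0
  # uniform heatmap over the partitioned ellipse: enrichment exactly 1
  S <- matrix(0, 101, 101); S[interior] <- 3.14
  expect_equal(periphery_enrichment(cam_heatmap(S, interior), part), 1.0)
  # zero on the periphery, constant elsewhere: enrichment 0
  S0 <- matrix(0, 101, 101); S0[interior] <- 2; S0[part$zones == 5] <- 0
  expect_equal(periphery_enrichment(cam_heatmap(S0, interior), part), 0)
})

test_that("the 100-px/20-px two-level fixture gives 5/3 exactly", {
  # synthetic partition: mask of 100 px with |R5| = 20
  mask <- matrix(FALSE, 10, 12); mask[1:10, 1:10] <- TRUE
  zones <- matrix(0L, 10, 12)
  zones[1:10, 1:8] <- 1L; zones[1:10, 9:10] <- 5L
  part <- structure(list(zones = zones, areas = c(80L, 0L, 0L, 0L, 20L),
                         n_zones = 5L, ellipse = NULL),
                    class = "zone_partition")
  S <- matrix(0, 10, 12); S[zones == 5L] <- 1.0; S[zones == 1L] <- 0.5
  # numerator 1.0; denominator (20*1 + 80*0.5)/100 = 0.6
  expect_equal(periphery_enrichment(cam_heatmap(S, mask), part), 1 / 0.6,
               tolerance = 1e-9)
})

test_that("metrics scale correctly under heatmap rescaling", {
  m <- rasterize_ellipse(30, 20, 1.1, n = 81)
  part <- partition_zones(fit_ellipse(m), dim(m))
  set.seed(15)
  S <- matrix(0, 81, 81); S[m] <- runif(sum(m))
  h1 <- cam_heatmap(S, m); h2 <- cam_heatmap(4.2 * S, m)
  expect_equal(nuclear_intensity(h2), 4.2 * nuclear_intensity(h1),
               tolerance = 1e-12)
  expect_equal(periphery_enrichment(h2, part), periphery_enrichment(h1, part),
               tolerance = 1e-12)
})

test_that("alignment is the identity for an already-canonical heatmap", {
  m <- rasterize_ellipse(150, 100, 0, n = 321)
  ell <- fit_ellipse(m)
  # smooth radial map
  S <- exp(-(nucleoprofiler:::elliptical_radius(ell, dim(m)))^2)
  hm <- structure(list(S = S, mask = m, ellipse = ell), class = "cam_heatmap")
  avg <- align_and_average(list(hm), canonical = c(ell$a, ell$b),
                           canvas_size = 321L)
  inside <- nucleoprofiler:::elliptical_radius(
    structure(list(center = c(row = 161, col = 161), a = ell$a, b = ell$b,
                   theta = 0), class = "ellipse_fit"), c(321L, 321L)) <= 0.95
  expect_lt(max(abs(avg[inside] - S[inside])), 1e-3)
  # averaging N copies returns the same map
  avg3 <- align_and_average(list(hm, hm, hm), canonical = c(ell$a, ell$b),
                            canvas_size = 321L)
  expect_equal(avg3, avg, tolerance = 1e-12)
  expect_error(align_and_average(list()), "empty")
})

test_that("a rotated copy aligns back onto the unrotated map", {
  n <- 241
  mk <- function(theta) {
    ell <- structure(list(center = c(row = (n + 1) / 2, col = (n + 1) / 2),
                          a = 80, b = 50, theta = theta), class = "ellipse_fit")
    rho <- nucleoprofiler:::elliptical_radius(ell, c(n, n))
    # smooth asymmetric pattern tied to the ellipse frame
    S <- exp(-rho^2) * (1 + 0.5 * pmin(rho, 1))
    structure(list(S = S, mask = rho <= 1, ellipse = ell),
              class = "cam_heatmap")
  }
  h0 <- mk(0); h90 <- mk(pi / 2)
  a0 <- align_and_average(list(h0), canonical = c(80, 50), canvas_size = n)
  a90 <- align_and_average(list(h90), canonical = c(80, 50), canvas_size = n)
  ell0 <- structure(list(center = c(row = (n + 1) / 2, col = (n + 1) / 2),
                         a = 80, b = 50, theta = 0), class = "ellipse_fit")
  inside <- nucleoprofiler:::elliptical_radius(ell0, c(n, n)) <= 0.9
  expect_lt(max(abs(a0[inside] - a90[inside])), 0.02)
  # alignment approximately preserves the mean level on smooth maps
  expect_lt(abs(mean(a90[inside]) - mean(a0[inside])) / mean(a0[inside]), 0.02)
})

test_that("score_cam with a single-map layer returns that normalized map", {
  spec <- model_spec("9conv_1f", input_size = 32L, width = 1L)  # conv1: K = 1
  m <- build_model(spec, 5)
  m$input_scale <- 1
  set.seed(16)
  img <- matrix(runif(32 * 32, 0, 100), 32, 32)
  hm <- score_cam(m, img, layer = "conv1")
  x4 <- array(to_pseudo_rgb(img), dim = c(32, 32, 3, 1))
  act <- nucleoprofiler:::nn_forward(m, x4, capture = "conv1")$captured[, , 1, 1]
  up <- nucleoprofiler:::bilinear_resize(act, 32, 32)
  ref <- (up - min(up)) / (max(up) - min(up))
  expect_equal(hm$S, pmax(ref, 0), tolerance = 1e-12)
  expect_true(all(hm$S >= 0))
})

test_that("feature battery covers five categories with sane degenerate values", {
  mask <- rasterize_ellipse(20, 14, 0.2, n = 61)
  cst <- matrix(0, 61, 61); cst[mask] <- 1
  fb <- cam_feature_battery(cam_heatmap(cst, mask))
  expect_setequal(unique(fb$category),
                  c("Size", "Shape", "Intensity", "Edge", "Texture"))
  expect_true(all(table(fb$category) >= 4))
  g <- function(n) fb$value[fb$feature == n]
  expect_equal(g("intensity_sd"), 0)
  expect_equal(g("texture_entropy"), 0)
  # checkerboard: edges and entropy appear
  chk <- matrix(0, 61, 61)
  chk[mask] <- (row(chk)[mask] + col(chk)[mask]) %% 2
  fb2 <- cam_feature_battery(cam_heatmap(chk, mask))
  g2 <- function(n) fb2$value[fb2$feature == n]
  expect_gt(g2("edge_count"), 0)
  expect_gt(g2("texture_entropy"), 0)
  # determinism
  fb3 <- cam_feature_battery(cam_heatmap(chk, mask))
  expect_identical(fb2, fb3)
  expect_identical(attr(fb2, "battery_version"), cam_battery_version)
  # mapping helper feeds category_significance
  cats <- cam_battery_categories(fb2)
  expect_identical(unname(cats["intensity_mean"]), "Intensity")
})
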