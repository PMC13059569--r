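test_that("classical segmentation recovers well-separated synthetic nuclei", {
  cfg <- small_synth_config()
  fld <- generate_multicell_field(6, 1200, 40, cfg, seed = 31)
  lab <- segment_field_classical(fld$channels$DNA)
  expect_identical(max(lab), 6L)
  # match each found instance to ground truth by IoU
  for (id in 1:6) {
    found <- lab == id
    ious <- vapply(1:6, function(g) {
      gt <- fld$instance_mask == g
      sum(found & gt) / sum(found | gt)
    }, 1)
    expect_gte(max(ious), 0.9)
  }
})

test_that("a blank field yields zero instances without error", {
  set.seed(9)
  blank <- matrix(100 + rnorm(300 * 300, 0, 1), 300, 300)
  lab <- segment_field_classical(blank, min_area = 500)
  expect_identical(max(lab), 0L)
})

test_that("two touching nuclei are split into two instances", {
  img <- matrix(10, 200, 300)
  for (ctr in list(c(100, 100), c(100, 186))) {
    idx <- which((row(img) - ctr[1])^2 + (col(img) - ctr[2])^2 <= 45^2)
    img[idx] <- 800
  }
  set.seed(10)
  img <- img + matrix(rnorm(200 * 300, 0, 5), 200, 300)
  lab <- segment_field_classical(img)
  expect_identical(max(lab), 2L)
})

test_that("each QC threshold rejects exactly its violating fixture", {
  # base passing record template
  base <- data.frame(instance = 1L, row0 = 1L, col0 = 1L, row1 = 300L,
                     col1 = 300L, side_rows = 300L, side_cols = 300L,
                     area = 65000L, roundness = 0.9, aspect_ratio = 1.0)
  mk <- function(...) { r <- base; mods <- list(...); r[names(mods)] <- mods; r }
  recs <- rbind(mk(),                                  # passes
                mk(instance = 2L, roundness = 0.65),   # roundness < 0.7
                mk(instance = 3L, side_cols = 650L, aspect_ratio = 650 / 300),
                mk(instance = 4L, side_rows = 150L, aspect_ratio = 2.0),
                mk(instance = 5L, area = 20000L))      # small-area outlier
  out <- qc_filter(recs, qc_thresholds(aspect_z_max = 100))  # isolate non-z rules
  expect_identical(out$accepted, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_match(out$reject_reasons[2], "roundness")
  expect_match(out$reject_reasons[3], "side_length")
  expect_match(out$reject_reasons[4], "side_length")
  expect_match(out$reject_reasons[5], "area")
  # printed-direction area rule flips the area decision
  out2 <- qc_filter(recs, qc_thresholds(aspect_z_max = 100,
                                        area_rule_direction = "greater"))
  expect_true(out2$accepted[5])
  expect_false(out2$accepted[1])   # 65000 > 30000 now rejected
})

test_that("aspect z-scores use the sample-sd convention", {
  # ratios {1, 1, 2}: sd = 0.5774, z3 = (2 - 4/3)/0.5774 = 1.1547 -> kept
  recs <- data.frame(instance = 1:3, row0 = 1L, col0 = 1L, row1 = 300L,
                     col1 = 300L, side_rows = 300L, side_cols = 300L,
                     area = 65000L, roundness = 0.9,
                     aspect_ratio = c(1, 1, 2))
  out <- qc_filter(recs)
  expect_equal(out$aspect_z[3], (2 - 4 / 3) / sd(c(1, 1, 2)), tolerance = 1e-12)
  expect_lt(out$aspect_z[3], 1.5)
  expect_true(all(out$accepted))
  # single record: z defined as 0
  one <- qc_filter(recs[1, ])
  expect_identical(one$aspect_z, 0)
  # idempotence of the decision on a fixed batch
  expect_identical(qc_filter(recs)$accepted, out$accepted)
})

test_that("padding centers crops, preserves content and rejects oversize", {
  crop <- matrix(as.numeric(seq_len(400 * 300)), 400, 300)
  pad <- pad_to_canvas(crop, 600L)
  expect_identical(dim(pad), c(600L, 600L))
  expect_identical(pad[100 + seq_len(400), 150 + seq_len(300)], crop)
  expect_equal(sum(pad), sum(crop))
  # identity on an exact-size crop
  full <- matrix(1, 600, 600)
  expect_equal(pad_to_canvas(full, 600L), full, ignore_attr = TRUE)
  expect_error(pad_to_canvas(matrix(0, 601, 600), 600L), "larger than canvas")
})

test_that("padding a nucleus_image moves mask and channels together", {
  cfg <- small_synth_config()
  fld <- generate_multicell_field(2, 700, 40, cfg, seed = 77)
  recs <- qc_filter(segment_records(fld$instance_mask),
                    qc_thresholds(side_range = c(50, 600), area_px = 1000))
  crops <- extract_crops(fld, recs)
  expect_length(crops, 2)
  p <- pad_to_canvas(crops[[1]], 600L)
  expect_identical(dim(p$mask), c(600L, 600L))
  expect_identical(sum(p$mask), sum(crops[[1]]$mask))
  expect_equal(sum(p$channels$DNA), sum(crops[[1]]$channels$DNA))
})
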