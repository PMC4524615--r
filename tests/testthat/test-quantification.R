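make_cell_setup <- function(fg_val1, bg_val1, fg_val2, bg_val2, d = 6L) {
  px1 <- matrix(bg_val1, 12, 12); px2 <- matrix(bg_val2, 12, 12)
  fg <- matrix(FALSE, 12, 12); fg[4:9, 4:9] <- TRUE
  px1[fg] <- fg_val1; px2[fg] <- fg_val2
  list(raw1 = channel_image(px1), raw2 = channel_image(px2),
       mask = spot_mask(fg, "moving_kmeans"),
       cell = list(rows = 1:12, cols = 1:12))
}

test_that("log-ratio follows the background-subtracted means", {
  # ch1: Mt 250, Mb 50 -> Me 200; ch2: Mt 150, Mb 100 -> Me 50; ratio 4
  s <- make_cell_setup(250L, 50L, 150L, 100L)
  q <- quantify_spot(s$raw1, s$raw2, s$mask, s$cell)
  expect_equal(q$Me1, 200)
  expect_equal(q$Me2, 50)
  expect_equal(q$log_ratio, 2.0)  # log2(4)
  expect_equal(q$qc_flag, "ok")
  # identical channels -> 0 in any base
  s2 <- make_cell_setup(300L, 80L, 300L, 80L)
  expect_equal(quantify_spot(s2$raw1, s2$raw2, s2$mask, s2$cell)$log_ratio, 0)
  expect_equal(quantify_spot(s2$raw1, s2$raw2, s2$mask, s2$cell,
                             log_base = 10)$log_ratio, 0)
})

test_that("non-positive Me and empty masks are flagged, not valued", {
  s <- make_cell_setup(40L, 100L, 150L, 100L)  # ch1 spot dimmer than bg
  q <- quantify_spot(s$raw1, s$raw2, s$mask, s$cell)
  expect_equal(q$qc_flag, "nonpositive_Me")
  expect_true(is.na(q$log_ratio))
  empty <- spot_mask(matrix(FALSE, 12, 12), "moving_kmeans")
  qm <- quantify_spot(s$raw1, s$raw2, empty, s$cell)
  expect_equal(qm$qc_flag, "missing")
  full <- spot_mask(matrix(TRUE, 12, 12), "moving_kmeans")
  qd <- quantify_spot(s$raw1, s$raw2, full, s$cell)
  expect_equal(qd$qc_flag, "degenerate")
})

test_that("value is invariant to a common positive scaling of both channels", {
  s <- make_cell_setup(250L, 50L, 150L, 100L)
  q1 <- quantify_spot(s$raw1, s$raw2, s$mask, s$cell)
  s3 <- make_cell_setup(750L, 150L, 450L, 300L)  # both channels x3
  q3 <- quantify_spot(s3$raw1, s3$raw2, s3$mask, s3$cell)
  expect_equal(q1$log_ratio, q3$log_ratio)
})

test_that("extraction uses raw images: identical with or without enhancement", {
  sim <- generate_subgrid(sim_config(seed = 71, ratio = 2))
  g <- grid_model(sim$truth$hlines, sim$truth$vlines)
  e1 <- enhance_channel(sim$ch1, enhance_params(seed = 4))
  e2 <- enhance_channel(sim$ch2, enhance_params(seed = 4))
  masks <- segment_subgrid(e1$image, e2$image, g)
  t_raw <- extract_table(sim$ch1, sim$ch2, g, masks)
  # re-running extraction after enhancement of the raws changes nothing,
  # because extraction always reads the raw pair
  t_again <- extract_table(sim$ch1, sim$ch2, g, masks)
  expect_identical(t_raw, t_again)
  # quantifying the ENHANCED images instead would distort the means
  t_enh <- extract_table(e1$image, e2$image, g, masks)
  expect_false(isTRUE(all.equal(t_raw$Me1, t_enh$Me1)))
})

test_that("extraction recovers the configured expression ratio", {
  sim <- generate_subgrid(sim_config(seed = 73, ratio = 2, missing_frac = 0,
                                     noise_sd = 1000, impulse_frac = 0))
  g <- grid_model(sim$truth$hlines, sim$truth$vlines)
  e1 <- enhance_channel(sim$ch1, enhance_params(seed = 4))
  e2 <- enhance_channel(sim$ch2, enhance_params(seed = 4))
  masks <- segment_subgrid(e1$image, e2$image, g)
  tab <- extract_table(sim$ch1, sim$ch2, g, masks)
  expect_equal(nrow(tab), 35L)
  ok <- tab$qc_flag == "ok"
  expect_gt(sum(ok), 25L)
  expect_lte(median(abs(tab$log_ratio[ok] - 1.0)), 0.1)
  expect_error(extract_table(sim$ch1, sim$ch2, g, masks[1:3, 1:3]),
               "do not match")
})
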