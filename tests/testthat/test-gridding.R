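test_that("projection profiles conserve total intensity", {
  img <- matrix(3L, 12, 20)  # h=12, w=20
  H <- project(img, "horizontal")
  V <- project(img, "vertical")
  expect_equal(H$values, rep(3 * 20, 12))  # constant c*w per row
  expect_equal(length(V$values), 20L)
  expect_equal(sum(H$values), sum(img))
  expect_equal(sum(V$values), sum(img))
  one <- matrix(0L, 10, 10); one[4, 7] <- 55L
  expect_equal(project(one, "horizontal")$values, c(rep(0, 3), 55, rep(0, 6)))
  expect_equal(project(one, "vertical")$values, c(rep(0, 6), 55, rep(0, 3)))
})

test_that("h-dome filter reproduces the iterative geodesic oracle", {
  # constant profile: marker 0 everywhere -> unchanged
  cst <- hdome_filter(rep(5, 8))
  expect_equal(cst$values, rep(5, 8))
  # 5-point spike: hand-derivable case
  v <- c(0, 0, 10, 0, 0)
  expect_equal(hdome_filter(v)$values, oracle_hdome(v))
  set.seed(29)
  for (i in 1:200) {
    v <- round(runif(sample(5:40, 1), 0, 100))
    got <- hdome_filter(v)$values
    expect_equal(got, oracle_hdome(v))
    expect_true(all(got >= 0 & got <= v))
  }
})

test_that("between-class threshold equals a brute-force argmax, bit-exactly", {
  set.seed(31)
  for (i in 1:1000) {
    lev <- random_levels(sample(50:400, 1))
    if (length(unique(lev)) < 2L) next
    expect_identical(between_class_threshold(lev),
                     oracle_bcv_threshold(lev))
  }
})

test_that("threshold separates two well-separated level clusters", {
  lev <- c(rep(1L, 50), rep(200L, 50))
  t_star <- between_class_threshold(lev)
  expect_gte(t_star, 1L)
  expect_lt(t_star, 200L)
  expect_error(between_class_threshold(rep(5, 30)), "degenerate")
})

test_that("literal criterion variant runs and returns a valid threshold", {
  set.seed(37)
  lev <- random_levels(200)
  t_lit <- between_class_threshold(lev, criterion = "literal")
  expect_true(t_lit >= 1L && t_lit <= 255L)
})

test_that("binarization thresholds quantized levels", {
  expect_equal(binarize_profile(c(10L, 200L, 10L), 50L), c(0L, 1L, 0L))
  expect_equal(binarize_profile(c(1L, 2L, 3L), 10L), c(0L, 0L, 0L))
  expect_equal(binarize_profile(c(0L, 1L, 0L, 1L), 0L), c(0L, 1L, 0L, 1L))
})

test_that("edge-hop line extraction places boundary and gap-midpoint lines", {
  # two 3-long bands at 4..6 and 10..12 in a length-15 signal
  b <- c(0, 0, 0, 1, 1, 1, 0, 0, 0, 1, 1, 1, 0, 0, 0)
  got <- extract_lines(b)
  expect_equal(got$n_spots, 2L)
  expect_equal(got$lines, c(2L, 8L, 14L))
  expect_error(extract_lines(rep(0, 10)), "no spot")
  one <- extract_lines(c(1, 1, 1, 0))
  expect_equal(one$n_spots, 1L)
  expect_equal(length(one$lines), 2L)
  # band flush to both ends: boundary lines at the signal ends
  flush <- extract_lines(c(1, 1, 1))
  expect_equal(flush$lines, c(1L, 3L))
})

test_that("line refinement snaps on-spot lines and repairs spacing outliers", {
  b <- c(rep(c(0, 0, 1, 1, 1, 0), 5), 0)
  lines <- c(1L, 7L, 13L, 19L, 25L, 31L)
  expect_equal(refine_lines(lines, b), lines)  # already a fixed point
  # a line on a band moves onto a zero
  moved <- refine_lines(c(1L, 4L, 13L, 19L, 25L, 31L), b)
  expect_true(all(b[moved] == 0))
  # a missing interior line (double spacing) gets one inserted
  gap <- refine_lines(c(1L, 7L, 19L, 25L, 31L), b)
  expect_equal(length(gap), 6L)
  # two nearly coincident lines collapse to one
  near <- refine_lines(c(1L, 7L, 8L, 13L, 19L, 25L, 31L), b)
  expect_equal(length(near), 6L)
})

test_that("gridding recovers the true layout and respects cell tiling", {
  sim <- generate_subgrid(sim_config(seed = 101, missing_frac = 0))
  e1 <- enhance_channel(sim$ch1, enhance_params(seed = 1))
  e2 <- enhance_channel(sim$ch2, enhance_params(seed = 1))
  g <- grid_image(e1$image, e2$image)
  expect_equal(g$n_rows, 5L)
  expect_equal(g$n_cols, 7L)
  # every present spot center strictly inside its own cell
  sp <- sim$truth$spots
  for (k in seq_len(nrow(sp))) {
    r <- sp$spot_row[k]; c <- sp$spot_col[k]
    expect_true(sp$center_y[k] >= g$hlines[r] &&
                  sp$center_y[k] < g$hlines[r + 1L])
    expect_true(sp$center_x[k] >= g$vlines[c] &&
                  sp$center_x[k] < g$vlines[c + 1L])
  }
  # cells tile the spanned region disjointly
  cover <- matrix(0L, sim$ch1$h, sim$ch1$w)
  for (r in seq_len(g$n_rows)) for (c in seq_len(g$n_cols)) {
    cell <- grid_cell(g, r, c)
    cover[cell$rows, cell$cols] <- cover[cell$rows, cell$cols] + 1L
  }
  span <- cover[min(g$hlines):(max(g$hlines) - 1L),
                min(g$vlines):(max(g$vlines) - 1L)]
  expect_true(all(span == 1L))
  expect_true(all(cover <= 1L))
})

test_that("gridding tolerates missing spots and transposition", {
  sim <- generate_subgrid(sim_config(seed = 7, preset = "ucsf",
                                     missing_frac = 0.1))
  e1 <- enhance_channel(sim$ch1, enhance_params(seed = 2))
  e2 <- enhance_channel(sim$ch2, enhance_params(seed = 2))
  g <- grid_image(e1$image, e2$image)
  expect_equal(g$n_rows, 14L)
  expect_equal(g$n_cols, 15L)
  gt <- grid_image(t(e1$image$pixels), t(e2$image$pixels))
  expect_equal(gt$n_rows, g$n_cols)
  expect_equal(gt$n_cols, g$n_rows)
  expect_equal(gt$hlines, g$vlines)
  expect_equal(gt$vlines, g$hlines)
})
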