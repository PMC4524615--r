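test_that("feature construction covers both modes", {
  cell <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(build_features(cell), c(1, 2, 3, 4))
  expect_equal(build_features(cell, cell), c(2, 4, 6, 8))
  expect_equal(build_features(matrix(5, 1, 1)), 5)
  f5 <- build_features(matrix(1:12, 3, 4), mode = "full5")
  expect_equal(colnames(f5), c("i", "j", "delta", "gR", "gG"))
  nz <- apply(f5, 2, sd) > 0
  expect_true(all(abs(apply(f5[, nz], 2, sd) - 1) < 1e-12))
  expect_error(build_features(NULL), "empty")
})

test_that("k-means separates two-valued cells exactly", {
  cell <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
  m <- kmeans_segment(cell)
  expect_equal(m$N_t, 40L)
  expect_true(all(cell[m$foreground] == 200))
  expect_equal(m$method_flag, "kmeans")
  cst <- kmeans_segment(matrix(9, 5, 5))
  expect_equal(cst$N_t, 0L)
  expect_true(cst$degenerate)
})

test_that("converged k-means satisfies the fixed-point property exactly", {
  set.seed(41)
  for (i in 1:100) {
    rc <- random_cell(size = sample(8:16, 1), amp = runif(1, 50, 400),
                      sd = runif(1, 5, 60), diameter = 5L)
    m <- kmeans_segment(rc$cell)
    if (m$degenerate) next
    g <- as.numeric(rc$cell)
    fg <- as.vector(m$foreground)
    c_fg <- mean(g[fg]); c_bg <- mean(g[!fg])
    # each member is at least as close to its own center (ties to class 1)
    expect_true(all(abs(g[fg] - c_fg) <= abs(g[fg] - c_bg)))
    expect_true(all(abs(g[!fg] - c_bg) < abs(g[!fg] - c_fg)
                    | abs(g[!fg] - c_bg) <= abs(g[!fg] - c_fg)))
    # reassigning from the converged centers reproduces the mask
    d_hi <- abs(g - max(c_fg, c_bg)); d_lo <- abs(g - min(c_fg, c_bg))
    expect_identical(fg, if (c_fg >= c_bg) d_hi <= d_lo else !(d_hi <= d_lo))
  }
})

test_that("moving k-means matches k-means on separable cells and terminates", {
  cell <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
  expect_identical(moving_kmeans_segment(cell)$foreground,
                   kmeans_segment(cell)$foreground)
  expect_error(moving_kmeans_segment(cell, alpha0 = 0.5), "alpha0")
  cst <- moving_kmeans_segment(matrix(3, 6, 6))
  expect_true(cst$degenerate)
})

test_that("moving k-means recovers dim spots with high Dice", {
  set.seed(43)
  dcs <- replicate(30, {
    cell <- matrix(20, 18, 18)
    sp <- render_spot("circle", 12, 10)
    cell[4:15, 4:15] <- cell[4:15, 4:15] + sp$patch
    truth <- matrix(FALSE, 18, 18); truth[4:15, 4:15] <- sp$mask
    noisy <- matrix(pmax(0, round(cell + rnorm(324, 0, 2))), 18, 18)
    dice(moving_kmeans_segment(noisy)$foreground, truth)
  })
  expect_gte(median(dcs), 0.8)
})

test_that("clustering is invariant to an additive intensity shift", {
  set.seed(47)
  rc <- random_cell()
  for (fn in list(kmeans_segment, moving_kmeans_segment)) {
    m0 <- fn(rc$cell)
    m1 <- fn(rc$cell + 500)
    expect_identical(m0$foreground, m1$foreground)
  }
})

test_that("combination obeys the N_t < N_b trigger and the union law", {
  # N_t >= N_b: returned unchanged
  cell <- matrix(c(rep(10, 40), rep(200, 60)), 10, 10)
  g1 <- moving_kmeans_segment(cell)
  expect_gte(g1$N_t, g1$N_b)
  expect_identical(combine_masks(cell, g1), g1)
  # trigger fires: foreground is exactly the union of both methods
  set.seed(53)
  fired <- 0L
  for (i in 1:200) {
    rc <- random_cell(size = 12L, amp = runif(1, 30, 120),
                      sd = runif(1, 10, 50), diameter = 6L)
    g1 <- moving_kmeans_segment(rc$cell)
    comb <- combine_masks(rc$cell, g1)
    if (g1$N_t >= g1$N_b) {
      expect_identical(comb$foreground, g1$foreground)
    } else {
      fired <- fired + 1L
      g2 <- kmeans_segment(rc$cell)
      expect_identical(comb$foreground, g1$foreground | g2$foreground)
      expect_true(all(comb$foreground[g1$foreground]))  # superset
      expect_equal(comb$method_flag, "combined")
    }
  }
  expect_gt(fired, 0L)
})

test_that("circle fallback rasterizes a disk at the intensity centroid", {
  cell <- matrix(0, 21, 21)
  cell[8:12, 10:14] <- 100  # bright blob centered at (10, 12)
  m <- circle_fallback(cell, 9)
  expect_equal(m$N_t, oracle_disk_count(21, 21, 10, 12, 9))
  expect_equal(m$method_flag, "circle")
  # diameter 1 -> single pixel
  expect_equal(circle_fallback(cell, 1)$N_t, 1L)
  expect_error(circle_fallback(cell, 0), "positive")
  # constant cell falls back to the geometric center
  flat <- circle_fallback(matrix(5, 11, 11), 5)
  expect_true(flat$foreground[6, 6])
  # centroid lands within 2 px of a synthetic weak spot's center
  set.seed(59)
  weak <- matrix(round(rnorm(441, 50, 3)), 21, 21)
  sp <- render_spot("circle", 9, 30)
  weak[7:15, 7:15] <- weak[7:15, 7:15] + sp$patch
  mc <- circle_fallback(weak, 9)
  idx <- which(mc$foreground, arr.ind = TRUE)
  expect_lt(sqrt((mean(idx[, 1]) - 11)^2 + (mean(idx[, 2]) - 11)^2), 2)
})

test_that("sub-grid segmentation returns a full mask map matching truth", {
  sim <- generate_subgrid(sim_config(seed = 61, missing_frac = 0,
                                     noise_sd = 500))
  g <- grid_model(sim$truth$hlines, sim$truth$vlines)
  e1 <- enhance_channel(sim$ch1, enhance_params(seed = 1))
  e2 <- enhance_channel(sim$ch2, enhance_params(seed = 1))
  masks <- segment_subgrid(e1$image, e2$image, g)
  expect_equal(dim(masks), c(5L, 7L))
  dcs <- numeric(0)
  for (r in 1:5) for (c in 1:7) {
    tm <- truth_cell_mask(sim$truth, g, r, c)
    expect_equal(masks[[r, c]]$N_t + masks[[r, c]]$N_b, length(tm))
    dcs <- c(dcs, dice(masks[[r, c]]$foreground, tm))
  }
  expect_gte(mean(dcs), 0.9)
})

test_that("an all-background sub-grid degrades to circle/degenerate masks", {
  # flat background with salt impulses: clustering isolates the impulses
  # (tiny N_t, triggering the fallback) or finds nothing at all
  sim <- generate_subgrid(sim_config(seed = 67, missing_frac = 1,
                                     noise_sd = 0, impulse_frac = 0.005))
  g <- grid_model(sim$truth$hlines, sim$truth$vlines)
  masks <- segment_subgrid(sim$ch1$pixels, sim$ch2$pixels, g)
  flags <- vapply(masks, function(m)
    if (m$degenerate) "degenerate" else m$method_flag, character(1))
  expect_true(all(flags %in% c("circle", "degenerate")))
  area <- vapply(masks, function(m) m$N_t / (m$N_t + m$N_b), numeric(1))
  expect_true(all(area < 0.5))
})
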