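#' Enhancement parameters
#'
#' Tunables of the automatic contrast-enhancement stage. The gain applied to
#' above-background pixels is `gain_numerator / C`, where the contrast degree
#' `C` is estimated from the image itself (see [contrast_degree()]); the
#' background level `k` below which pixels are left untouched is estimated by
#' repeated sampling of blocks in the image border band (see
#' [background_level()]).
#'
#' @param block_size side, in pixels, of the square sampling blocks (default 10).
#' @param blocks_per_edge blocks placed in each of the four edge regions per
#'   repetition (default 3, i.e. 12 blocks per repetition).
#' @param reps number of repetitions `m` whose minima are averaged (default 10).
#' @param gain_numerator numerator of the gain `gain_numerator / C` (default 10000).
#' @param gain_cap output intensities are clamped here (default 65535).
#' @param edge_frac width of the border band used for background sampling, as
#'   a fraction of the corresponding image dimension (default 0.1; never
#'   narrower than one block).
#' @param seed optional integer seed for block placement; `NULL` uses the
#'   current RNG state.
#' @return A list of class `enhance_params`.
#' @export
enhance_params <- function(block_size = 10L, blocks_per_edge = 3L, reps = 10L,
                           gain_numerator = 10000, gain_cap = 65535,
                           edge_frac = 0.1, seed = NULL) {
  stopifnot(block_size >= 1L, blocks_per_edge >= 1L, reps >= 1L,
            gain_numerator > 0, gain_cap > 0, edge_frac > 0)
  structure(list(block_size = as.integer(block_size),
                 blocks_per_edge = as.integer(blocks_per_edge),
                 reps = as.integer(reps),
                 gain_numerator = gain_numerator,
                 gain_cap = gain_cap,
                 edge_frac = edge_frac,
                 seed = seed),
            class = "enhance_params")
}

#' Automatic contrast degree
#'
#' Estimates the contrast degree `C = s / (s4 / s2^2)^(1/4)` from the
#' flattened pixel values, where `s2` and `s4` are the population second and
#' fourth central moments and `s = sqrt(s2)`. The denominator is the fourth
#' root of the kurtosis, so heavy-tailed (spotty) images get a larger `C`
#' than `s` alone would suggest, and hence a smaller enhancement gain.
#'
#' @param pixels numeric vector (or matrix, flattened) of intensities.
#' @return The scalar contrast degree `C > 0`.
#' @export
contrast_degree <- function(pixels) {
  p <- as.numeric(pixels)
  if (length(p) < 2L) stop("need at least 2 pixels to estimate contrast")
  pbar <- mean(p)
  d <- p - pbar
  s2 <- mean(d^2)
  if (s2 == 0) stop("degenerate contrast: image is constant (s = 0)")
  s4 <- mean(d^4)
  sqrt(s2) / (s4 / s2^2)^(1 / 4)
}

# Random block placement band along each edge. Returns max(blocks) minima
# machinery for background_level(); band is at least one block wide and
# blocks always fit fully inside the image.
edge_band <- function(extent, block_size, edge_frac) {
  band <- max(block_size, as.integer(round(edge_frac * extent)))
  min(band, extent)
}

#' Background gray level from edge-region block sampling
#'
#' For each of `reps` repetitions, places `blocks_per_edge` random
#' `block_size` x `block_size` blocks in each of the top, left, right and
#' bottom border bands, takes the maximum intensity inside each block, and
#' keeps the minimum of those block maxima. The background level `k` is the
#' mean of the per-repetition minima, rounded to the nearest integer. Taking
#' block maxima then the minimum over blocks makes the estimate robust to a
#' single dark or bright outlier region, while restricting placement to the
#' border keeps spots (which live in the interior) out of the estimate.
#'
#' @param img a [channel_image] or intensity matrix.
#' @param params an [enhance_params()] list.
#' @return Integer background level `k`.
#' @export
background_level <- function(img, params = enhance_params()) {
  img <- as_channel_image(img)
  px <- img$pixels
  h <- img$h; w <- img$w
  bs <- params$block_size
  if (h < bs || w < bs)
    stop("image (", h, "x", w, ") smaller than sampling block (", bs, ")")
  if (!is.null(params$seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(params$seed)
  }
  band_h <- edge_band(h, bs, params$edge_frac)
  band_w <- edge_band(w, bs, params$edge_frac)
  # start-coordinate ranges (row0, col0) keeping the block inside each band
  regions <- list(
    top    = list(r = c(1L, max(1L, band_h - bs + 1L)), c = c(1L, w - bs + 1L)),
    bottom = list(r = c(max(1L, h - band_h + 1L), h - bs + 1L), c = c(1L, w - bs + 1L)),
    left   = list(r = c(1L, h - bs + 1L), c = c(1L, max(1L, band_w - bs + 1L))),
    right  = list(r = c(1L, h - bs + 1L), c = c(max(1L, w - band_w + 1L), w - bs + 1L))
  )
  minima <- vapply(seq_len(params$reps), function(rep) {
    maxima <- unlist(lapply(regions, function(rg) {
      vapply(seq_len(params$blocks_per_edge), function(b) {
        r0 <- if (rg$r[1L] >= rg$r[2L]) rg$r[1L] else
          sample(rg$r[1L]:rg$r[2L], 1L)
        c0 <- if (rg$c[1L] >= rg$c[2L]) rg$c[1L] else
          sample(rg$c[1L]:rg$c[2L], 1L)
        max(px[r0:(r0 + bs - 1L), c0:(c0 + bs - 1L)])
      }, numeric(1))
    }))
    min(maxima)
  }, numeric(1))
  as.integer(round(mean(minima)))
}

#' Contrast-enhance a channel
#'
#' Applies the gain `gain_numerator / C` to every pixel strictly above the
#' background level `k` and leaves pixels at or below `k` untouched:
#' `g = f * (gain_numerator / C)` where `f > k`, else `g = f`. Amplified
#' values are clamped at `gain_cap`. `C` and `k` default to the automatic
#' estimates on this channel's raw pixels.
#'
#' @param img a [channel_image] or intensity matrix (raw channel).
#' @param params an [enhance_params()] list.
#' @param C contrast degree; estimated via [contrast_degree()] if `NULL`.
#' @param k background level; estimated via [background_level()] if `NULL`.
#' @return A list with the enhanced [channel_image] (`image`) and the
#'   parameters used (`C`, `k`, `gain`).
#' @export
enhance <- function(img, params = enhance_params(), C = NULL, k = NULL) {
  img <- as_channel_image(img)
  if (is.null(k)) k <- background_level(img, params)
  if (is.null(C)) C <- contrast_degree(img$pixels)
  if (C <= 0) stop("contrast degree C must be positive")
  gain <- params$gain_numerator / C
  px <- img$pixels
  out <- matrix(as.numeric(px), nrow(px), ncol(px))
  above <- px > k
  out[above] <- pmin(round(out[above] * gain), params$gain_cap)
  list(image = channel_image(out, img$channel), C = C, k = k, gain = gain)
}

#' 3x3 median filter with edge replication
#'
#' Replaces every pixel by the median of its 3x3 neighbourhood; borders are
#' handled by replicating the edge rows/columns. Removes salt impulses while
#' preserving spot edges, which a linear smoother would blur.
#'
#' @param img a [channel_image] or intensity matrix.
#' @return A [channel_image] of the same size.
#' @export
median3x3 <- function(img) {
  img <- as_channel_image(img)
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  # replicate-pad by one pixel, then slice the nine shifted neighbourhoods
  pad <- px[c(1L, seq_len(h), h), c(1L, seq_len(w), w), drop = FALSE]
  n <- vector("list", 9L)
  idx <- 1L
  for (dr in 0:2) for (dc in 0:2) {
    n[[idx]] <- pad[dr + seq_len(h), dc + seq_len(w), drop = FALSE]
    idx <- idx + 1L
  }
  # median of 9 via the 19-comparator exchange network (vectorised pmin/pmax)
  sw <- function(i, j) {
    lo <- pmin(n[[i]], n[[j]]); hi <- pmax(n[[i]], n[[j]])
    n[[i]] <<- lo; n[[j]] <<- hi
  }
  sw(2,3); sw(5,6); sw(8,9); sw(1,2); sw(4,5); sw(7,8)
  sw(2,3); sw(5,6); sw(8,9); sw(1,4); sw(6,9); sw(5,8)
  sw(4,7); sw(2,5); sw(3,6); sw(5,8); sw(5,3); sw(7,5); sw(5,3)
  channel_image(matrix(n[[5]], h, w), img$channel)
}

#' Full enhancement stage: estimate k and C, enhance, median-denoise
#'
#' Convenience wrapper running the module in its canonical order
#' (background level, contrast degree, gain, 3x3 median) on one channel.
#'
#' @inheritParams enhance
#' @return A list with `image` (enhanced + denoised [channel_image]),
#'   `C`, `k` and `gain`.
#' @export
enhance_channel <- function(img, params = enhance_params()) {
  res <- enhance(img, params)
  res$image <- median3x3(res$image)
  res
}
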