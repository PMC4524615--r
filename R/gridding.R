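#' Projection profile of a sub-grid image
#'
#' Sums intensities along one image axis. The horizontal profile has one
#' value per image row, `H(y) = sum_x g(x, y)`; the vertical profile one per
#' column, `V(x) = sum_y g(x, y)`. Spot rows/columns show up as peaks, the
#' gutters between them as valleys.
#'
#' @param img a [channel_image] or intensity matrix (enhanced channel, or the
#'   elementwise sum of both enhanced channels).
#' @param axis `"horizontal"` (per-row) or `"vertical"` (per-column).
#' @return A list of class `projection_profile` with `values`, `axis` and
#'   `mean`.
#' @export
project <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  img <- as_channel_image(img)
  v <- if (axis == "horizontal") rowSums(img$pixels) else colSums(img$pixels)
  structure(list(values = as.numeric(v), axis = axis, mean = mean(v)),
            class = "projection_profile")
}

profile_values <- function(profile) {
  if (inherits(profile, "projection_profile")) profile$values
  else as.numeric(profile)
}

# one-step 3-point dilation (running max over each point and its neighbours)
dilate1 <- function(x) {
  n <- length(x)
  if (n == 1L) return(x)
  pmax(x, c(x[-1L], x[n]), c(x[1L], x[-n]))
}

#' h-dome filter of a projection profile
#'
#' Subtracts from the profile its morphological reconstruction by dilation
#' under itself, started from the marker `max(H - mean(H), 0)`. The
#' reconstruction recovers everything reachable by flooding from the
#' above-mean peaks, so the difference keeps only bounded-height domes:
#' baseline drift and broad background are removed while spot peaks of
#' height up to the profile mean survive. The marker is clipped at zero so
#' that it stays below the mask and the reconstruction stays non-negative.
#'
#' @param profile a `projection_profile` (or numeric vector).
#' @return A `projection_profile` with the filtered values (same axis).
#' @export
hdome_filter <- function(profile) {
  v <- profile_values(profile)
  marker <- pmax(v - mean(v), 0)
  rec <- marker
  for (i in seq_len(length(v) + 1L)) {
    nxt <- pmin(dilate1(rec), v)
    if (identical(nxt, rec)) break
    rec <- nxt
  }
  out <- v - rec
  structure(list(values = out,
                 axis = if (inherits(profile, "projection_profile"))
                   profile$axis else "horizontal",
                 mean = mean(out)),
            class = "projection_profile")
}

#' Quantize a profile to integer gray levels 1..L
#'
#' Linear rescale of the profile onto `L` integer levels before histogram
#' thresholding.
#'
#' @param profile a `projection_profile` or numeric vector.
#' @param L number of levels (default 256).
#' @return Integer vector of levels in `[1, L]`.
#' @export
quantize_profile <- function(profile, L = 256L) {
  v <- profile_values(profile)
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stop("degenerate profile: all values equal, cannot threshold")
  1L + as.integer(round((v - rng[1L]) / (rng[2L] - rng[1L]) * (L - 1L)))
}

#' Maximum between-class-variance threshold of a quantized profile
#'
#' Exhaustively evaluates a two-class separation criterion at every
#' candidate threshold `t` in `[1, L - 1]` of the level histogram and
#' returns the maximizing `t` (ties break to the smallest `t`). The default
#' criterion is the between-class variance
#' `d(t) = (ubar * omega(t) - u_t)^2 / (omega(t) * (1 - omega(t)))`,
#' built from the class probability `omega(t) = sum_{i<=t} P_i`, the first
#' cumulative moment `u_t = sum_{i<=t} i P_i` and the global mean
#' `ubar = sum_i i P_i`. `criterion = "literal"` instead maximizes
#' `mu_d2 * (omega - mu_dt2)^2 / (omega * (1 - omega))` with the global
#' average variance `mu_d2 = (1/L) sum_i (i - ubar)^2 P_i` and class average
#' variance `mu_dt2 = (1/t) sum_{i<=t} (i - u_t)^2 P_i`.
#'
#' @param profile a `projection_profile`, numeric vector, or an integer
#'   vector of pre-quantized levels.
#' @param L number of quantization levels (default 256).
#' @param criterion `"variance"` (between-class variance, default) or
#'   `"literal"`.
#' @return The optimal threshold `t*` (integer level).
#' @export
between_class_threshold <- function(profile, L = 256L,
                                    criterion = c("variance", "literal")) {
  criterion <- match.arg(criterion)
  v <- profile_values(profile)
  lev <- if (!inherits(profile, "projection_profile") &&
             all(v == round(v)) && min(v) >= 1 && max(v) <= L) {
    if (length(unique(v)) < 2L)
      stop("degenerate profile: all values equal, cannot threshold")
    as.integer(v)  # already quantized levels
  } else quantize_profile(profile, L)
  n_i <- tabulate(lev, nbins = L)
  P <- n_i / length(lev)
  i <- seq_len(L)
  ubar <- sum(i * P)
  omega <- cumsum(P)
  u_t <- cumsum(i * P)
  ts <- seq_len(L - 1L)
  d <- if (criterion == "variance") {
    (ubar * omega[ts] - u_t[ts])^2 / (omega[ts] * (1 - omega[ts]))
  } else {
    mu_d2 <- sum((i - ubar)^2 * P) / L
    mu_dt2 <- cumsum((i - u_t[i])^2 * P)[ts] / ts
    mu_d2 * (omega[ts] - mu_dt2)^2 / (omega[ts] * (1 - omega[ts]))
  }
  d[!is.finite(d)] <- -Inf
  which.max(d)  # first maximum -> smallest t
}

#' Binarize a quantized profile at a threshold
#'
#' @param levels integer levels (see [quantize_profile()]), or a raw profile
#'   which is quantized first.
#' @param t threshold; output is 1 where `levels > t`, else 0.
#' @param L levels used if quantization is needed.
#' @return Integer 0/1 vector.
#' @export
binarize_profile <- function(levels, t, L = 256L) {
  if (inherits(levels, "projection_profile") || !all(levels == round(levels)))
    levels <- quantize_profile(levels, L)
  as.integer(levels > t)
}

#' Grid-line coordinates from a binary projection signal
#'
#' Runs of 1s are spot bands; each gap of 0s between consecutive bands
#' contributes one grid line at its midpoint. One boundary line is added
#' before the first band (midpoint of the leading gap, or coordinate 1) and
#' one after the last (midpoint of the trailing gap, or the last
#' coordinate). For `n` bands this yields `n + 1` lines.
#'
#' @param binary integer 0/1 vector.
#' @return A list with `lines` (sorted 1-based coordinates, length
#'   `n_spots + 1`) and `n_spots`.
#' @export
extract_lines <- function(binary) {
  b <- as.integer(binary != 0)
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs1 <- which(r$values == 1L)
  if (length(runs1) == 0L) stop("no spot bands found in binary signal")
  n_spots <- length(runs1)
  lines <- integer(n_spots + 1L)
  # leading boundary
  first_start <- starts[runs1[1L]]
  lines[1L] <- if (first_start > 1L)
    as.integer(floor((1L + first_start - 1L) / 2)) else 1L
  # interior lines: midpoints of the zero gaps between consecutive bands
  if (n_spots > 1L) {
    for (k in seq_len(n_spots - 1L)) {
      gap_start <- ends[runs1[k]] + 1L
      gap_end <- starts[runs1[k + 1L]] - 1L
      lines[k + 1L] <- as.integer(floor((gap_start + gap_end) / 2))
    }
  }
  # trailing boundary
  last_end <- ends[runs1[n_spots]]
  lines[n_spots + 1L] <- if (last_end < length(b))
    as.integer(floor((last_end + 1L + length(b)) / 2)) else length(b)
  list(lines = lines, n_spots = n_spots)
}

#' Refine grid lines by valley snapping and spacing statistics
#'
#' Two heuristic repairs on the raw line set: (a) a line that falls on a
#' spot band (binary value 1) is moved to the nearest coordinate whose
#' binary value is 0 (ties to the smaller coordinate); (b) spacing outliers
#' relative to the median spacing `dm` are repaired — a gap wider than
#' `split_factor * dm` gets lines inserted at multiples of `dm`, and a gap
#' narrower than `collapse_factor * dm` collapses its two lines to their
#' midpoint. The result is sorted and deduplicated.
#'
#' @param lines integer line coordinates.
#' @param binary the 0/1 signal the lines were extracted from.
#' @param split_factor,collapse_factor outlier thresholds (defaults 1.5, 0.5).
#' @return Integer vector of refined line coordinates.
#' @export
refine_lines <- function(lines, binary, split_factor = 1.5,
                         collapse_factor = 0.5) {
  b <- as.integer(binary != 0)
  n <- length(b)
  zeros <- which(b == 0L)
  # (a) snap on-spot lines to the nearest zero coordinate
  if (length(zeros)) {
    lines <- vapply(lines, function(x) {
      if (b[x] == 0L) return(as.integer(x))
      zeros[which.min(abs(zeros - x))]
    }, integer(1))
  }
  lines <- sort(unique(as.integer(lines)))
  if (length(lines) >= 3L) {
    sp <- diff(lines)
    dm <- stats::median(sp)
    if (dm > 0) {
      out <- lines[1L]
      for (k in seq_along(sp)) {
        gap <- sp[k]
        if (gap > split_factor * dm) {
          n_ins <- round(gap / dm) - 1L
          if (n_ins > 0L)
            out <- c(out, as.integer(round(lines[k] + dm * seq_len(n_ins))))
          out <- c(out, lines[k + 1L])
        } else if (gap < collapse_factor * dm) {
          # collapse the pair to its midpoint
          out[length(out)] <- as.integer(floor((lines[k] + lines[k + 1L]) / 2))
        } else {
          out <- c(out, lines[k + 1L])
        }
      }
      lines <- sort(unique(pmin(pmax(out, 1L), n)))
    }
  }
  lines
}

#' Grid model: cell boundaries of a sub-grid
#'
#' @param hlines,vlines strictly increasing 1-based row/column coordinates;
#'   `length(hlines) = n_rows + 1`, `length(vlines) = n_cols + 1`.
#' @return A list of class `grid_model` with `hlines`, `vlines`, `n_rows`,
#'   `n_cols`. Cell `(r, c)` covers rows `[hlines[r], hlines[r+1])` and
#'   columns `[vlines[c], vlines[c+1])` (half-open).
#' @export
grid_model <- function(hlines, vlines) {
  hlines <- as.integer(hlines); vlines <- as.integer(vlines)
  if (any(diff(hlines) <= 0L) || any(diff(vlines) <= 0L))
    stop("grid lines must be strictly increasing")
  if (length(hlines) < 2L || length(vlines) < 2L)
    stop("a grid needs at least 2 lines per axis")
  structure(list(hlines = hlines, vlines = vlines,
                 n_rows = length(hlines) - 1L, n_cols = length(vlines) - 1L),
            class = "grid_model")
}

#' @export
print.grid_model <- function(x, ...) {
  cat(sprintf("<grid_model: %d x %d spots, rows [%d..%d], cols [%d..%d]>\n",
              x$n_rows, x$n_cols, min(x$hlines), max(x$hlines),
              min(x$vlines), max(x$vlines)))
  invisible(x)
}

#' Row/column pixel ranges of one grid cell
#'
#' @param grid a [grid_model()].
#' @param r,c 1-based spot row and column.
#' @return List with integer vectors `rows` and `cols` (the half-open cell
#'   `[hlines[r], hlines[r+1])` x `[vlines[c], vlines[c+1])`).
#' @export
grid_cell <- function(grid, r, c) {
  stopifnot(r >= 1L, r <= grid$n_rows, c >= 1L, c <= grid$n_cols)
  list(rows = grid$hlines[r]:(grid$hlines[r + 1L] - 1L),
       cols = grid$vlines[c]:(grid$vlines[c + 1L] - 1L))
}

grid_axis <- function(img, axis, L, criterion, refine = TRUE) {
  pr <- project(img, axis)
  filt <- hdome_filter(pr)
  t_star <- between_class_threshold(filt, L, criterion)
  bin <- binarize_profile(quantize_profile(filt, L), t_star)
  ext <- extract_lines(bin)
  lines <- if (refine) refine_lines(ext$lines, bin) else ext$lines
  list(lines = lines, n_spots = length(lines) - 1L)
}

#' Grid a sub-grid image
#'
#' Full gridding chain on both axes: projection, h-dome filtering,
#' between-class-variance thresholding, binarization, edge-hop line
#' extraction and heuristic refinement. Operates on the enhanced,
#' median-filtered image; when both channels are supplied their pixel sums
#' are gridded so that a spot dark in one dye still anchors the grid.
#'
#' @param img enhanced [channel_image] (or matrix); if `img2` is given the
#'   two are summed first.
#' @param img2 optional second enhanced channel.
#' @param L quantization levels for thresholding (default 256).
#' @param criterion threshold criterion, see [between_class_threshold()].
#' @param refine apply [refine_lines()] (default TRUE).
#' @return A [grid_model()].
#' @export
grid_image <- function(img, img2 = NULL, L = 256L,
                       criterion = c("variance", "literal"), refine = TRUE) {
  criterion <- match.arg(criterion)
  img <- as_channel_image(img)
  px <- img$pixels
  if (!is.null(img2)) {
    img2 <- as_channel_image(img2)
    stopifnot(identical(dim(px), dim(img2$pixels)))
    px <- pmin(px + img2$pixels, 65535L)
  }
  hz <- grid_axis(px, "horizontal", L, criterion, refine)
  vt <- grid_axis(px, "vertical", L, criterion, refine)
  grid_model(hz$lines, vt$lines)
}
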