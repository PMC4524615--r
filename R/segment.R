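#' Per-pixel clustering features for one grid cell
#'
#' In `"intensity"` mode (the default used by the clustering steps, which
#' compare scalar gray values against cluster centers) the feature is the
#' summed intensity `g_R + g_G` per pixel (a single channel contributes its
#' own intensity). In `"full5"` mode the feature vector is
#' `(i, j, delta, g_R, g_G)` — pixel row, pixel column, Euclidean distance
#' to the current cluster center position, and the two channel intensities —
#' with every coordinate z-scaled to unit variance over the cell; the
#' distance column is recomputed from the current centers at every
#' clustering iteration, so here it is initialized against the cell center.
#'
#' @param cell1 intensity matrix of the cell (first/green channel).
#' @param cell2 optional second (red) channel cell matrix.
#' @param mode `"intensity"` or `"full5"`.
#' @return `"intensity"`: numeric vector, one value per pixel (column-major).
#'   `"full5"`: numeric matrix with columns `i`, `j`, `delta`, `gR`, `gG`.
#' @export
build_features <- function(cell1, cell2 = NULL, mode = c("intensity", "full5")) {
  mode <- match.arg(mode)
  if (is.null(cell1) || length(cell1) == 0L) stop("empty cell")
  g <- as.numeric(cell1)
  if (!is.null(cell2)) {
    stopifnot(length(cell2) == length(cell1))
    g <- g + as.numeric(cell2)
  }
  if (mode == "intensity") return(g)
  nr <- nrow(cell1); nc <- ncol(cell1)
  ij <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  delta <- sqrt((ij$i - (nr + 1) / 2)^2 + (ij$j - (nc + 1) / 2)^2)
  gR <- if (is.null(cell2)) as.numeric(cell1) else as.numeric(cell2)
  gG <- as.numeric(cell1)
  feats <- cbind(i = ij$i, j = ij$j, delta = delta, gR = gR, gG = gG)
  apply(feats, 2L, function(col) {
    s <- stats::sd(col)
    if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
}

#' Binary spot mask for one grid cell
#'
#' @param foreground logical matrix over the cell (`TRUE` = spot).
#' @param method_flag which method produced the mask.
#' @param degenerate flag set when the cell was constant and no clustering
#'   was possible.
#' @param warning_flag set when an iteration guard tripped before formal
#'   convergence.
#' @return A list of class `spot_mask` with `foreground`, `N_t`, `N_b`,
#'   `method_flag`, `degenerate`, `warning_flag`.
#' @export
spot_mask <- function(foreground,
                      method_flag = c("moving_kmeans", "kmeans", "combined",
                                      "circle"),
                      degenerate = FALSE, warning_flag = FALSE) {
  method_flag <- match.arg(method_flag)
  stopifnot(is.matrix(foreground))
  fg <- foreground != 0
  structure(list(foreground = fg,
                 N_t = sum(fg), N_b = sum(!fg),
                 method_flag = method_flag,
                 degenerate = degenerate, warning_flag = warning_flag),
            class = "spot_mask")
}

# scalar/vector nearest-center assignment; ties go to class 1
assign_classes <- function(feat, c1, c2) {
  if (is.matrix(feat)) {
    d1 <- sqrt(rowSums((feat - matrix(c1, nrow(feat), length(c1), byrow = TRUE))^2))
    d2 <- sqrt(rowSums((feat - matrix(c2, nrow(feat), length(c2), byrow = TRUE))^2))
  } else {
    d1 <- abs(feat - c1); d2 <- abs(feat - c2)
  }
  d1 <= d2
}

center_of <- function(feat, members, fallback) {
  if (!any(members)) return(fallback)
  if (is.matrix(feat)) colMeans(feat[members, , drop = FALSE]) else
    mean(feat[members])
}

fitness_of <- function(feat, members, center) {
  if (!any(members)) return(0)
  if (is.matrix(feat)) {
    sum((feat[members, , drop = FALSE] -
           matrix(center, sum(members), length(center), byrow = TRUE))^2)
  } else sum((feat[members] - center)^2)
}

# scalar intensity coordinate used for max/min initialization, for the
# "below the higher-fitness center" transfer test, and for picking the
# foreground class
intensity_coord <- function(feat) {
  if (is.matrix(feat)) feat[, "gR"] + feat[, "gG"] else feat
}
center_intensity <- function(center) {
  if (length(center) > 1L) center[["gR"]] + center[["gG"]] else center
}

init_centers <- function(feat) {
  ic <- intensity_coord(feat)
  hi <- which.max(ic); lo <- which.min(ic)
  if (is.matrix(feat)) list(c1 = feat[hi, ], c2 = feat[lo, ])
  else list(c1 = feat[hi], c2 = feat[lo])
}

update_delta <- function(feat, in1, c1, c2) {
  if (!is.matrix(feat)) return(feat)
  # distance of each pixel to its current class center position (i, j)
  d <- numeric(nrow(feat))
  d[in1] <- sqrt((feat[in1, "i"] - c1[["i"]])^2 + (feat[in1, "j"] - c1[["j"]])^2)
  d[!in1] <- sqrt((feat[!in1, "i"] - c2[["i"]])^2 + (feat[!in1, "j"] - c2[["j"]])^2)
  s <- stats::sd(d)
  feat[, "delta"] <- if (is.na(s) || s == 0) 0 else (d - mean(d)) / s
  feat
}

finish_mask <- function(in_fg, dims, method_flag, degenerate = FALSE,
                        warning_flag = FALSE) {
  spot_mask(matrix(in_fg, dims[1L], dims[2L]), method_flag,
            degenerate = degenerate, warning_flag = warning_flag)
}

#' Two-class k-means segmentation of one cell
#'
#' Standard 2-class k-means with the clustering centers initialized at the
#' pixels of maximum and minimum gray value; assignment and center updates
#' iterate until the assignment is stable (or `max_iter`). The foreground is
#' the class whose final center has the higher intensity. A constant cell
#' cannot be clustered and yields an all-background mask with the
#' `degenerate` flag set.
#'
#' @param cell1,cell2 cell intensity matrices (second channel optional).
#' @param mode feature mode, see [build_features()].
#' @param max_iter assignment/update iteration cap (default 1000).
#' @return A [spot_mask()] with `method_flag = "kmeans"`.
#' @export
kmeans_segment <- function(cell1, cell2 = NULL,
                           mode = c("intensity", "full5"), max_iter = 1000L) {
  mode <- match.arg(mode)
  dims <- dim(cell1)
  feat <- build_features(cell1, cell2, mode)
  if (length(unique(intensity_coord(feat))) < 2L)
    return(finish_mask(rep(FALSE, prod(dims)), dims, "kmeans",
                       degenerate = TRUE))
  cen <- init_centers(feat)
  in1 <- assign_classes(feat, cen$c1, cen$c2)
  warn <- TRUE
  for (it in seq_len(max_iter)) {
    cen$c1 <- center_of(feat, in1, cen$c1)
    cen$c2 <- center_of(feat, !in1, cen$c2)
    feat <- update_delta(feat, in1, cen$c1, cen$c2)
    nxt <- assign_classes(feat, cen$c1, cen$c2)
    if (identical(nxt, in1)) { warn <- FALSE; break }
    in1 <- nxt
  }
  fg1 <- center_intensity(cen$c1) >= center_intensity(cen$c2)
  finish_mask(if (fg1) in1 else !in1, dims, "kmeans", warning_flag = warn)
}

#' Moving k-means segmentation of one cell
#'
#' Two-class moving k-means: after ordinary assignment and center updates,
#' the fitness `F(c) = sum of squared member distances to c` of each center
#' is compared, and while the lower fitness stays below `alpha_a` times the
#' higher, members of the higher-fitness class whose gray value lies below
#' that class's center are transferred to the lower-fitness class (both
#' centers recomputed, `alpha_a` halved). All pixels are then reassigned and
#' the outer loop repeats with `alpha_a` reset to `alpha_0` and `alpha_b`
#' halved, until the lower fitness reaches `alpha_b` times the higher. The
#' transfers stop either cluster's fitness collapsing onto an outlier, which
#' is what makes the method robust to low-contrast noisy spots. The
#' foreground is the class with the higher-intensity final center.
#'
#' @param cell1,cell2 cell intensity matrices (second channel optional).
#' @param mode feature mode, see [build_features()].
#' @param alpha0 control parameter in `(0, 1/3)` (default 0.3).
#' @param max_inner,max_outer iteration guards (defaults 1000, 100); if the
#'   outer guard trips, the current state is returned with `warning_flag`.
#' @return A [spot_mask()] with `method_flag = "moving_kmeans"`.
#' @export
moving_kmeans_segment <- function(cell1, cell2 = NULL,
                                  mode = c("intensity", "full5"),
                                  alpha0 = 0.3,
                                  max_inner = 1000L, max_outer = 100L) {
  mode <- match.arg(mode)
  if (alpha0 <= 0 || alpha0 >= 1 / 3)
    stop("alpha0 must lie strictly between 0 and 1/3")
  dims <- dim(cell1)
  feat <- build_features(cell1, cell2, mode)
  if (length(unique(intensity_coord(feat))) < 2L)
    return(finish_mask(rep(FALSE, prod(dims)), dims, "moving_kmeans",
                       degenerate = TRUE))
  cen <- init_centers(feat)
  alpha_a <- alpha0; alpha_b <- alpha0
  in1 <- assign_classes(feat, cen$c1, cen$c2)
  cen$c1 <- center_of(feat, in1, cen$c1)
  cen$c2 <- center_of(feat, !in1, cen$c2)
  feat <- update_delta(feat, in1, cen$c1, cen$c2)
  warn <- FALSE
  for (outer in seq_len(max_outer)) {
    F1 <- fitness_of(feat, in1, cen$c1)
    F2 <- fitness_of(feat, !in1, cen$c2)
    inner <- 0L
    repeat {
      F_h <- max(F1, F2); F_l <- min(F1, F2)
      if (F_l >= alpha_a * F_h) break
      h_is_1 <- F1 >= F2
      members_h <- if (h_is_1) in1 else !in1
      ci_h <- center_intensity(if (h_is_1) cen$c1 else cen$c2)
      move <- members_h & (intensity_coord(feat) < ci_h)
      if (!any(move)) break  # nothing transferable; condition cannot change
      in1 <- if (h_is_1) in1 & !move else in1 | move
      cen$c1 <- center_of(feat, in1, cen$c1)
      cen$c2 <- center_of(feat, !in1, cen$c2)
      alpha_a <- alpha_a / 2
      F1 <- fitness_of(feat, in1, cen$c1)
      F2 <- fitness_of(feat, !in1, cen$c2)
      inner <- inner + 1L
      if (inner >= max_inner) { warn <- TRUE; break }
    }
    # reassign all pixels and recompute centers
    in1 <- assign_classes(feat, cen$c1, cen$c2)
    cen$c1 <- center_of(feat, in1, cen$c1)
    cen$c2 <- center_of(feat, !in1, cen$c2)
    feat <- update_delta(feat, in1, cen$c1, cen$c2)
    alpha_a <- alpha0
    alpha_b <- alpha_b / 2
    F1 <- fitness_of(feat, in1, cen$c1)
    F2 <- fitness_of(feat, !in1, cen$c2)
    if (min(F1, F2) >= alpha_b * max(F1, F2)) break
    if (outer == max_outer) warn <- TRUE
  }
  fg1 <- center_intensity(cen$c1) >= center_intensity(cen$c2)
  finish_mask(if (fg1) in1 else !in1, dims, "moving_kmeans",
              warning_flag = warn)
}

#' OR-combination of moving k-means with k-means
#'
#' If the moving k-means mask `g1` already labels at least as many
#' foreground as background pixels (`N_t >= N_b`) it is returned unchanged.
#' Otherwise k-means is run on the same cell and the combined mask is the
#' pixelwise OR of the two foregrounds, `g' = g1 || g2`.
#'
#' @param cell1,cell2 cell intensity matrices.
#' @param g1 [spot_mask()] from [moving_kmeans_segment()].
#' @param mode feature mode.
#' @return A [spot_mask()] (`method_flag = "combined"` when the trigger fired).
#' @export
combine_masks <- function(cell1, g1, cell2 = NULL,
                          mode = c("intensity", "full5")) {
  mode <- match.arg(mode)
  if (g1$N_t >= g1$N_b) return(g1)
  g2 <- kmeans_segment(cell1, cell2, mode)
  spot_mask(g1$foreground | g2$foreground, "combined",
            degenerate = g1$degenerate && g2$degenerate,
            warning_flag = g1$warning_flag || g2$warning_flag)
}

#' Circular fallback segmentation for weak spots
#'
#' When clustering finds too small a foreground (`N_t < 0.3 (N_t + N_b)`),
#' the spot is replaced by a rasterized disk of the given diameter centered
#' at the cell's intensity centroid (geometric cell center when the cell is
#' constant), clipped to the cell. A pixel belongs to the disk when its
#' center lies within `diameter / 2` of the disk center.
#'
#' @param cell intensity matrix of the cell (used only for the centroid).
#' @param diameter disk diameter in pixels (> 0).
#' @return A [spot_mask()] with `method_flag = "circle"`.
#' @export
circle_fallback <- function(cell, diameter) {
  if (diameter <= 0) stop("circle diameter must be positive")
  nr <- nrow(cell); nc <- ncol(cell)
  w <- as.numeric(cell) - min(cell)
  if (sum(w) > 0) {
    ij <- expand.grid(i = seq_len(nr), j = seq_len(nc))
    y0 <- sum(ij$i * w) / sum(w)
    x0 <- sum(ij$j * w) / sum(w)
  } else {
    y0 <- (nr + 1) / 2; x0 <- (nc + 1) / 2
  }
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  fg <- (rr - y0)^2 + (cc - x0)^2 <= (diameter / 2)^2
  spot_mask(fg, "circle")
}

#' Segment every cell of a gridded sub-grid
#'
#' Runs the chosen method in each grid cell of the enhanced image pair. The
#' default `"combined"` method is moving k-means followed by the
#' OR-combination with k-means (trigger `N_t < N_b`), followed by the circle
#' fallback whenever the combined foreground still covers less than 30% of
#' the cell (`N_t < 0.3 (N_t + N_b)`). The fallback diameter is the median
#' equivalent diameter `2 sqrt(N_t / pi)` of the cells that did not need the
#' fallback, or half the smaller cell dimension when every cell needs it.
#'
#' @param img1 enhanced [channel_image] (or matrix).
#' @param img2 optional enhanced second channel.
#' @param grid a [grid_model()].
#' @param method `"combined"` (default), `"moving_kmeans"`, `"kmeans"` or
#'   `"circle"` (single-method modes for comparison experiments).
#' @param mode feature mode, see [build_features()].
#' @param alpha0 moving k-means control parameter.
#' @param fallback_frac circle-fallback trigger fraction (default 0.3).
#' @return An `n_rows` x `n_cols` list-matrix of [spot_mask()] objects.
#' @export
segment_subgrid <- function(img1, img2 = NULL, grid,
                            method = c("combined", "moving_kmeans", "kmeans",
                                       "circle"),
                            mode = c("intensity", "full5"),
                            alpha0 = 0.3, fallback_frac = 0.3) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  img1 <- as_channel_image(img1)
  px1 <- img1$pixels
  px2 <- if (is.null(img2)) NULL else as_channel_image(img2)$pixels
  masks <- matrix(vector("list", grid$n_rows * grid$n_cols),
                  grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      cell <- grid_cell(grid, r, c)
      c1 <- px1[cell$rows, cell$cols, drop = FALSE]
      c2 <- if (is.null(px2)) NULL else px2[cell$rows, cell$cols, drop = FALSE]
      masks[[r, c]] <- switch(
        method,
        kmeans = kmeans_segment(c1, c2, mode),
        moving_kmeans = moving_kmeans_segment(c1, c2, mode, alpha0),
        combined = ,
        circle = {
          g1 <- moving_kmeans_segment(c1, c2, mode, alpha0)
          combine_masks(c1, g1, c2, mode)
        })
    }
  }
  if (method %in% c("combined", "circle")) {
    needs_fb <- vapply(masks, function(m)
      method == "circle" || m$N_t < fallback_frac * (m$N_t + m$N_b),
      logical(1))
    good_nt <- vapply(masks[!needs_fb], function(m) m$N_t, numeric(1))
    diam <- if (length(good_nt) > 0)
      stats::median(2 * sqrt(good_nt / pi))
    else {
      cellmin <- min(diff(grid$hlines), diff(grid$vlines))
      0.5 * cellmin
    }
    if (any(needs_fb) && diam > 0) {
      idx <- which(matrix(needs_fb, grid$n_rows, grid$n_cols), arr.ind = TRUE)
      for (k in seq_len(nrow(idx))) {
        r <- idx[k, 1L]; c <- idx[k, 2L]
        cell <- grid_cell(grid, r, c)
        csum <- px1[cell$rows, cell$cols, drop = FALSE]
        if (!is.null(px2)) csum <- csum + px2[cell$rows, cell$cols, drop = FALSE]
        masks[[r, c]] <- circle_fallback(csum, diam)
      }
    }
  }
  masks
}

#' Mosaic per-cell masks back into a full-image mask
#'
#' @param masks list-matrix from [segment_subgrid()].
#' @param grid the [grid_model()] the masks were computed on.
#' @param dim_out `c(h, w)` of the output (defaults to the grid's span).
#' @return Logical matrix; `TRUE` = foreground.
#' @export
mosaic_masks <- function(masks, grid, dim_out = NULL) {
  if (is.null(dim_out))
    dim_out <- c(max(grid$hlines), max(grid$vlines))
  out <- matrix(FALSE, dim_out[1L], dim_out[2L])
  for (r in seq_len(grid$n_rows)) for (c in seq_len(grid$n_cols)) {
    cell <- grid_cell(grid, r, c)
    out[cell$rows, cell$cols] <- masks[[r, c]]$foreground
  }
  out
}
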