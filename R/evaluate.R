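#' Dice coefficient of two binary masks
#'
#' @param a,b logical matrices of equal size.
#' @return `2|A and B| / (|A| + |B|)`; defined as 1 when both are empty.
#' @export
dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1)
  2 * sum(a & b) / denom
}

#' Judge one detected spot against truth
#'
#' The detected foreground is hole-filled first; if the Dice coefficient of
#' the filled mask against truth reaches `dice_min` the detection's edge is
#' considered correct, and the verdict is `"correctly"` when the foreground
#' had no enclosed holes, `"marginally"` when it did (the edge is right but
#' the interior has dropouts); anything below `dice_min` is
#' `"incorrectly"`. For a truly missing spot (empty truth) an empty
#' detection is `"correctly"` and any detection `"incorrectly"`.
#'
#' @param detected a [spot_mask()] or logical matrix.
#' @param truth logical matrix of the true spot pixels (same cell).
#' @param dice_min Dice threshold for a correct edge (default 0.8).
#' @return List of class `spot_verdict`: `category`, `dice`, `holes`.
#' @export
judge_spot <- function(detected, truth, dice_min = 0.8) {
  det <- if (inherits(detected, "spot_mask")) detected$foreground
         else detected != 0
  truth <- truth != 0
  stopifnot(identical(dim(det), dim(truth)))
  if (!any(truth)) {
    cat_ <- if (!any(det)) "correctly" else "incorrectly"
    return(structure(list(category = cat_, dice = if (any(det)) 0 else 1,
                          holes = 0L), class = "spot_verdict"))
  }
  if (!any(det)) {
    return(structure(list(category = "incorrectly", dice = 0, holes = 0L),
                     class = "spot_verdict"))
  }
  filled <- EBImage::fillHull(matrix(as.integer(det), nrow(det), ncol(det))) > 0
  holes <- sum(filled) - sum(det)
  dc <- dice(filled, truth)
  cat_ <- if (dc >= dice_min) {
    if (holes == 0L) "correctly" else "marginally"
  } else "incorrectly"
  structure(list(category = cat_, dice = dc, holes = as.integer(holes)),
            class = "spot_verdict")
}

#' Segmentation accuracy over a set of verdicts
#'
#' Fraction of spots judged `"correctly"` out of all judged spots.
#'
#' @param verdicts list of `spot_verdict`s (or character vector of
#'   categories).
#' @return Numeric fraction in `[0, 1]`.
#' @export
accuracy <- function(verdicts) {
  cats <- verdict_categories(verdicts)
  if (length(cats) == 0L) stop("cannot compute accuracy of zero verdicts")
  mean(cats == "correctly")
}

#' Category rates over a set of verdicts
#'
#' @inheritParams accuracy
#' @return Named numeric vector with `correctly`, `marginally`,
#'   `incorrectly` fractions (summing to 1).
#' @export
verdict_rates <- function(verdicts) {
  cats <- verdict_categories(verdicts)
  if (length(cats) == 0L) stop("cannot compute rates of zero verdicts")
  c(correctly = mean(cats == "correctly"),
    marginally = mean(cats == "marginally"),
    incorrectly = mean(cats == "incorrectly"))
}

verdict_categories <- function(verdicts) {
  if (is.character(verdicts)) return(verdicts)
  vapply(verdicts, function(v) v$category, character(1))
}

#' Root-mean-square error of per-spot foreground pixel counts
#'
#' `sqrt(mean((m_i - m'_i)^2))` between detected and true pixel counts.
#'
#' @param counts detected foreground pixel counts.
#' @param truth_counts true pixel counts (same length).
#' @return Scalar RMSE.
#' @export
pixel_rmse <- function(counts, truth_counts) {
  if (length(counts) != length(truth_counts))
    stop("count vectors differ in length")
  if (length(counts) < 1L) stop("need at least one spot")
  sqrt(mean((as.numeric(counts) - as.numeric(truth_counts))^2))
}

#' Mean squared deviation of log-ratio intensities from zero
#'
#' For self-self style comparisons most spots should have log-ratio near
#' zero; the intensity MSE `mean(value^2)` measures how far a method's
#' extracted values scatter from it. Flagged (non-`ok`) spots must be
#' excluded by the caller.
#'
#' @param values finite log-ratio values of ok-flagged spots.
#' @return Scalar MSE.
#' @export
intensity_mse <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no ok-flagged spots: intensity MSE undefined")
  mean(values^2)
}

#' Evaluate a segmented sub-grid against simulator truth
#'
#' Judges every grid cell's mask against the corresponding truth mask and
#' aggregates: verdict rates, mean Dice over present spots, pixel-count
#' RMSE over present spots, and the intensity MSE of ok-flagged log-ratios
#' when an intensity table is supplied.
#'
#' @param masks list-matrix from [segment_subgrid()].
#' @param truth the `truth` element of [generate_subgrid()].
#' @param grid the [grid_model()] used for segmentation.
#' @param table optional intensity table from [extract_table()].
#' @param dice_min Dice threshold for [judge_spot()].
#' @return List with `verdicts`, `rates`, `accuracy`, `mean_dice`,
#'   `pixel_rmse` and (if `table` given) `intensity_mse`.
#' @export
evaluate_subgrid <- function(masks, truth, grid, table = NULL,
                             dice_min = 0.8) {
  stopifnot(grid$n_rows == truth$n_rows, grid$n_cols == truth$n_cols)
  verdicts <- vector("list", grid$n_rows * grid$n_cols)
  dices <- counts <- tcounts <- numeric(0)
  k <- 1L
  for (r in seq_len(grid$n_rows)) for (c in seq_len(grid$n_cols)) {
    tm <- truth_cell_mask(truth, grid, r, c)
    verdicts[[k]] <- judge_spot(masks[[r, c]], tm, dice_min)
    if (any(tm)) {
      dices <- c(dices, verdicts[[k]]$dice)
      counts <- c(counts, masks[[r, c]]$N_t)
      tcounts <- c(tcounts, sum(tm))
    }
    k <- k + 1L
  }
  out <- list(verdicts = verdicts,
              rates = verdict_rates(verdicts),
              accuracy = accuracy(verdicts),
              mean_dice = if (length(dices)) mean(dices) else NA_real_,
              pixel_rmse = if (length(counts)) pixel_rmse(counts, tcounts)
                           else NA_real_)
  if (!is.null(table)) {
    ok <- table$qc_flag == "ok" & is.finite(table$log_ratio)
    out$intensity_mse <- if (any(ok)) intensity_mse(table$log_ratio[ok])
                         else NA_real_
  }
  out
}
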