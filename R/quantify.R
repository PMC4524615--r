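#' Quantify one spot from the raw images
#'
#' Intensity extraction always reads the ORIGINAL raw channels, never the
#' enhanced ones: enhancement multiplies above-background pixels by a
#' per-channel gain, so means computed on the enhanced image would be
#' inflated by that gain and the two channels by different amounts. Per
#' channel the summed foreground and background intensities `R_t`, `R_b`,
#' their means `M_t = R_t / N_t`, `M_b = R_b / N_b` and the
#' background-subtracted mean `M_e = M_t - M_b` are computed over the
#' foreground mask and the within-cell complement; the expression readout is
#' `value = log(M_e1 / M_e2)` in the chosen base (default 2, the microarray
#' convention). A non-positive `M_e` in either channel flags the spot
#' instead of producing a value.
#'
#' @param raw1,raw2 raw [channel_image]s (or matrices) of both channels
#'   (`raw2` may be `NULL` for single-channel quantification, in which case
#'   no ratio is computed).
#' @param mask [spot_mask()] for the cell.
#' @param cell cell pixel ranges from [grid_cell()].
#' @param log_base base of the ratio logarithm (default 2).
#' @return A one-row data frame with `Nt`, `Nb`, `Mt1`, `Mb1`, `Me1`,
#'   `Mt2`, `Mb2`, `Me2`, `log_ratio`, `method_flag`, `qc_flag`.
#' @export
quantify_spot <- function(raw1, raw2, mask, cell, log_base = 2) {
  px1 <- as_channel_image(raw1)$pixels[cell$rows, cell$cols, drop = FALSE]
  px2 <- if (is.null(raw2)) NULL else
    as_channel_image(raw2)$pixels[cell$rows, cell$cols, drop = FALSE]
  fg <- mask$foreground
  stopifnot(identical(dim(fg), dim(px1)))
  N_t <- sum(fg); N_b <- sum(!fg)
  ch_stats <- function(px) {
    if (is.null(px)) return(list(Mt = NA_real_, Mb = NA_real_, Me = NA_real_))
    Mt <- if (N_t > 0) sum(px[fg]) / N_t else NA_real_
    Mb <- if (N_b > 0) sum(px[!fg]) / N_b else NA_real_
    list(Mt = Mt, Mb = Mb, Me = Mt - Mb)
  }
  s1 <- ch_stats(px1); s2 <- ch_stats(px2)
  qc <- "ok"; value <- NA_real_
  if (N_t == 0L) qc <- "missing"
  else if (N_b == 0L) qc <- "degenerate"
  else if (is.null(px2)) qc <- "ok"
  else if (s1$Me <= 0 || s2$Me <= 0) qc <- "nonpositive_Me"
  else value <- log(s1$Me / s2$Me, base = log_base)
  data.frame(Nt = N_t, Nb = N_b,
             Mt1 = s1$Mt, Mb1 = s1$Mb, Me1 = s1$Me,
             Mt2 = s2$Mt, Mb2 = s2$Mb, Me2 = s2$Me,
             log_ratio = value,
             method_flag = mask$method_flag,
             qc_flag = if (mask$degenerate && qc == "ok") "degenerate" else qc,
             stringsAsFactors = FALSE)
}

#' Per-spot intensity table for a whole sub-grid
#'
#' One record per grid cell in row-major order (row 1 columns 1..s, then
#' row 2, ...), each produced by [quantify_spot()] on the raw images.
#'
#' @param raw1,raw2 raw [channel_image]s of both channels.
#' @param grid a [grid_model()].
#' @param masks list-matrix of [spot_mask()]s from [segment_subgrid()].
#' @param log_base base of the ratio logarithm (default 2).
#' @return Data frame with the columns of [write_intensity_table()].
#' @export
extract_table <- function(raw1, raw2, grid, masks, log_base = 2) {
  if (!identical(dim(masks), c(grid$n_rows, grid$n_cols)))
    stop("mask map dimensions (", paste(dim(masks), collapse = "x"),
         ") do not match grid (", grid$n_rows, "x", grid$n_cols, ")")
  rows <- vector("list", grid$n_rows * grid$n_cols)
  k <- 1L
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      cell <- grid_cell(grid, r, c)
      rec <- quantify_spot(raw1, raw2, masks[[r, c]], cell, log_base)
      rec <- cbind(data.frame(spot_row = r, spot_col = c), rec)
      rows[[k]] <- rec
      k <- k + 1L
    }
  }
  do.call(rbind, rows)
}
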