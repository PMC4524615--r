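#' Single-channel microarray sub-grid image
#'
#' A `channel_image` wraps an integer matrix of 16-bit gray levels together
#' with a channel tag. Rows index the vertical (y) direction and columns the
#' horizontal (x) direction, so `pixels[y, x]` is the intensity at column x of
#' row y. All downstream stages (enhancement, gridding, segmentation,
#' quantification) consume this container.
#'
#' @param pixels integer or numeric matrix with values in `[0, 65535]`.
#' @param channel one of `"ch1"` (green/Cy3), `"ch2"` (red/Cy5) or `"mono"`.
#' @return An object of class `channel_image`: a list with elements
#'   `pixels` (integer matrix), `w` (width, columns), `h` (height, rows)
#'   and `channel`.
#' @examples
#' img <- channel_image(matrix(0L, 20, 30))
#' dim(img$pixels)  # 20 rows (h) x 30 cols (w)
#' @export
channel_image <- function(pixels, channel = c("mono", "ch1", "ch2")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1x1")
  if (anyNA(pixels)) stop("image contains NA pixels")
  if (min(pixels) < 0 || max(pixels) > 65535)
    stop("intensities must lie in [0, 65535]")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, w = ncol(pixels), h = nrow(pixels), channel = channel),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image %s: %d x %d (w x h), range [%d, %d]>\n",
              x$channel, x$w, x$h, min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Accept either a channel_image or a bare matrix everywhere.
as_channel_image <- function(x, channel = "mono") {
  if (inherits(x, "channel_image")) x else channel_image(x, channel)
}
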