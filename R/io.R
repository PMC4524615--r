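#' Read a single-plane grayscale TIFF as a channel image
#'
#' Microarray scanners store each fluorescence channel as a 16-bit grayscale
#' TIFF. 8-bit inputs are promoted to the 16-bit range by multiplying by 257
#' (so 255 maps to 65535). Multi-sample (RGB) TIFFs are rejected: the two
#' channels of a two-dye experiment live in separate files.
#'
#' @param path path to a single-plane grayscale TIFF file.
#' @param channel channel tag to attach (`"ch1"`, `"ch2"` or `"mono"`).
#' @return A [channel_image].
#' @export
read_tiff <- function(path, channel = "mono") {
  if (!file.exists(path)) stop("cannot read TIFF: file not found: ", path)
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                   error = function(e) stop("cannot read TIFF '", path, "': ",
                                            conditionMessage(e)))
  if (is.list(info) && !is.data.frame(info)) info <- info[[1L]]
  if (!is.null(info$samples.per.pixel) && info$samples.per.pixel != 1L)
    stop("unsupported TIFF format: expected single-channel grayscale, got ",
         info$samples.per.pixel, " samples per pixel")
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] != 1L)
      stop("unsupported TIFF format: multi-plane image")
    px <- px[, , 1L]
  }
  bits <- info$bits.per.sample
  if (!is.null(bits) && length(bits) == 1L && !is.na(bits) && bits == 8L)
    px <- px * 257L
  channel_image(px, channel)
}

#' Write a channel image as a 16-bit grayscale TIFF
#'
#' Inverse of [read_tiff()]: the write/read round trip is bit-exact.
#'
#' @param img a [channel_image] or intensity matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path) {
  img <- as_channel_image(img)
  ok <- tiff::writeTIFF(img$pixels / 65535, path, bits.per.sample = 16L)
  if (!isTRUE(ok == 1L)) stop("failed to write TIFF: ", path)
  invisible(path)
}

#' Write a binary spot mask as an 8-bit PNG (0 = background, 255 = foreground)
#'
#' @param mask logical or 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  png::writePNG(m, path)
  invisible(path)
}

#' Read a mask PNG written by [write_mask_png()]
#' @param path path to an 8-bit mask PNG.
#' @return Logical matrix (`TRUE` = foreground).
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0.5
}

#' Write grid-line coordinates, one integer per line
#'
#' @param lines integer vector of sorted line coordinates (1-based pixel rows
#'   or columns).
#' @param path output path (TSV with a single column, no header).
#' @return `path`, invisibly.
#' @export
write_grid_lines <- function(lines, path) {
  writeLines(as.character(as.integer(lines)), path)
  invisible(path)
}

#' @rdname write_grid_lines
#' @export
read_grid_lines <- function(path) as.integer(readLines(path))

intensity_table_cols <- c("spot_row", "spot_col", "Nt", "Nb",
                          "Mt1", "Mb1", "Me1", "Mt2", "Mb2", "Me2",
                          "log_ratio", "method_flag", "qc_flag")

#' Write the per-spot intensity table as CSV
#'
#' One row per grid cell in row-major order, with the columns
#' `spot_row, spot_col, Nt, Nb, Mt1, Mb1, Me1, Mt2, Mb2, Me2, log_ratio,
#' method_flag, qc_flag`. Cells flagged `missing` keep their row with an
#' empty `log_ratio`. An empty input yields a header-only CSV.
#'
#' @param rows data frame of spot quantifications (see [extract_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) {
    rows <- as.data.frame(setNames(rep(list(character(0)),
                                       length(intensity_table_cols)),
                                   intensity_table_cols))
  }
  missing_cols <- setdiff(intensity_table_cols, names(rows))
  if (length(missing_cols))
    stop("intensity table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  rows <- rows[, intensity_table_cols, drop = FALSE]
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an intensity table CSV written by [write_intensity_table()]
#' @param path CSV path.
#' @return Data frame with one row per grid cell.
#' @export
read_intensity_table <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE)
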