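#' Run the full sub-grid pipeline
#'
#' End-to-end processing of one sub-grid: per-channel automatic contrast
#' enhancement and 3x3 median denoising, gridding on the summed enhanced
#' channels, per-cell combined-clustering segmentation on the enhanced
#' images, and intensity extraction on the untouched RAW images.
#'
#' @param raw1 raw [channel_image] (or matrix) of channel 1.
#' @param raw2 optional raw channel 2.
#' @param params [enhance_params()]; its `seed` drives the only stochastic
#'   step (background block sampling), so a fixed seed makes the whole run
#'   deterministic.
#' @param method segmentation method, see [segment_subgrid()].
#' @param mode feature mode.
#' @param alpha0 moving k-means control parameter.
#' @param log_base ratio log base.
#' @return List with `enhanced1`, `enhanced2` (enhancement results incl.
#'   `C`, `k`, `gain`), `grid`, `masks` and `table`.
#' @export
run_pipeline <- function(raw1, raw2 = NULL, params = enhance_params(seed = 1L),
                         method = "combined", mode = "intensity",
                         alpha0 = 0.3, log_base = 2) {
  raw1 <- as_channel_image(raw1, "ch1")
  e1 <- enhance_channel(raw1, params)
  e2 <- NULL
  if (!is.null(raw2)) {
    raw2 <- as_channel_image(raw2, "ch2")
    e2 <- enhance_channel(raw2, params)
  }
  grid <- grid_image(e1$image, if (is.null(e2)) NULL else e2$image)
  masks <- segment_subgrid(e1$image, if (is.null(e2)) NULL else e2$image,
                           grid, method = method, mode = mode, alpha0 = alpha0)
  table <- extract_table(raw1, raw2, grid, masks, log_base = log_base)
  list(enhanced1 = e1, enhanced2 = e2, grid = grid, masks = masks,
       table = table)
}
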