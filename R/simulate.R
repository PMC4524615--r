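#' Simulator configuration
#'
#' Describes one synthetic two-channel sub-grid: an `n_rows` x `n_cols`
#' layout of spots on a regular pitch, with per-spot shape, optional center
#' jitter, missing spots, additive truncated-Gaussian noise, salt impulses
#' and an optional bright blob artifact. Defaults emulate a small SIB-style
#' sub-grid: 5 x 7 spots on an 18-pixel pitch (each spot living in an
#' 18 x 18 cell), background around 1000 gray levels, spot amplitude 8000
#' with channel-2 amplitude `amp / ratio`, Gaussian noise of sd
#' `amplitude / 8`, 10% missing spots and jitter up to 10% of the pitch —
#' the regime of small, slightly imperfect scanner sub-grids.
#'
#' @param n_rows,n_cols spot layout (default 5 x 7).
#' @param pitch center-to-center spot spacing in pixels (default 18).
#' @param diameter spot diameter in pixels (default 12; must be < pitch).
#' @param shape `"circle"`, `"doughnut"`, `"egg"`, `"crescent"`, `"peak"`
#'   or `"volcano"`.
#' @param background_level additive background intensity (default 1000).
#' @param amplitude channel-1 spot amplitude above background (default 8000).
#' @param ratio true channel-1 / channel-2 amplitude ratio per spot; either
#'   a scalar or an `n_rows` x `n_cols` matrix (default 1).
#' @param noise_sd sd of additive Gaussian noise (default `amplitude / 8`,
#'   i.e. SNR 8).
#' @param impulse_frac fraction of pixels replaced by bright salt impulses
#'   (default 0.001).
#' @param missing_frac probability a spot is absent (default 0.1).
#' @param jitter maximum per-axis center offset in pixels (default
#'   `round(0.1 * pitch)`).
#' @param margin border margin around the spot lattice (default `pitch / 2`,
#'   rounded).
#' @param artifact optional list `list(row, col, radius, level)` adding a
#'   bright blob artifact.
#' @param seed integer RNG seed (default 1).
#' @param preset `"sib"` (5 x 7, pitch 18), `"ucsf"` (14 x 15, pitch 8) or
#'   `"derisi"` (40 x 40, pitch 8): layout presets matching common public
#'   sub-grid geometries. Explicit arguments override preset values.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_rows = 5L, n_cols = 7L, pitch = 18L, diameter = 12L,
                       shape = c("circle", "doughnut", "egg", "crescent",
                                 "peak", "volcano"),
                       background_level = 1000, amplitude = 8000, ratio = 1,
                       noise_sd = amplitude / 8, impulse_frac = 0.001,
                       missing_frac = 0.1, jitter = round(0.1 * pitch),
                       margin = round(pitch / 2), artifact = NULL, seed = 1L,
                       preset = NULL) {
  shape <- match.arg(shape)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("sib", "ucsf", "derisi"))
    p <- switch(preset,
                sib    = list(n_rows = 5L, n_cols = 7L, pitch = 18L, diameter = 12L),
                ucsf   = list(n_rows = 14L, n_cols = 15L, pitch = 8L, diameter = 5L),
                derisi = list(n_rows = 40L, n_cols = 40L, pitch = 8L, diameter = 5L))
    mc <- names(match.call())
    if (!("n_rows" %in% mc)) n_rows <- p$n_rows
    if (!("n_cols" %in% mc)) n_cols <- p$n_cols
    if (!("pitch" %in% mc)) { pitch <- p$pitch; jitter <- round(0.1 * pitch)
                              margin <- round(pitch / 2) }
    if (!("diameter" %in% mc)) diameter <- p$diameter
  }
  stopifnot(pitch > diameter, diameter >= 1,
            background_level >= 0, background_level <= 65535,
            amplitude >= 0, missing_frac >= 0, missing_frac <= 1)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch = as.integer(pitch), diameter = as.integer(diameter),
                 shape = shape, background_level = background_level,
                 amplitude = amplitude, ratio = ratio, noise_sd = noise_sd,
                 impulse_frac = impulse_frac, missing_frac = missing_frac,
                 jitter = as.integer(jitter), margin = as.integer(margin),
                 artifact = artifact, seed = as.integer(seed)),
            class = "sim_config")
}

#' Render one spot patch
#'
#' Produces an intensity patch (amplitude above background) and its binary
#' mask for one of the spot morphologies seen on real slides: a filled
#' `circle`; a `doughnut` (central dropout: disk minus a concentric disk of
#' 0.4 x radius); an `egg` (ellipse with axis ratio 1.3); a `crescent`
#' (disk minus an offset disk); a `peak` (radial Gaussian); and a `volcano`
#' (radial profile with a central dip). The mask is the set of pixels whose
#' rendered intensity exceeds 10% of the peak level.
#'
#' @param shape one of the six shape names.
#' @param diameter spot diameter in pixels.
#' @param level peak amplitude.
#' @return List with `patch` (numeric matrix, `diameter` x `diameter`) and
#'   `mask` (logical matrix).
#' @export
render_spot <- function(shape, diameter, level) {
  shapes <- c("circle", "doughnut", "egg", "crescent", "peak", "volcano")
  if (!shape %in% shapes)
    stop("unknown spot shape: ", shape)
  if (diameter < 1) stop("diameter must be >= 1")
  d <- as.integer(diameter)
  ctr <- (d + 1) / 2
  r <- d / 2
  rr <- matrix(seq_len(d), d, d) - ctr          # row offsets
  cc <- matrix(seq_len(d), d, d, byrow = TRUE) - ctr
  rho <- sqrt(rr^2 + cc^2)
  patch <- switch(
    shape,
    circle = level * (rho <= r),
    doughnut = level * ((rho <= r) & (rho > 0.4 * r)),
    egg = level * ((rr / r)^2 + (cc / (r / 1.3))^2 <= 1),
    crescent = level * ((rho <= r) &
                          (sqrt((rr - r / 2)^2 + cc^2) > r * 0.75)),
    peak = level * exp(-rho^2 / (2 * (r / 2)^2)),
    volcano = level * pmax(exp(-(rho - 0.6 * r)^2 / (2 * (0.25 * r)^2)),
                           0.3 * (rho <= 0.6 * r)) * (rho <= r)
  )
  patch <- matrix(as.numeric(patch), d, d)
  list(patch = patch, mask = patch > 0.1 * level)
}

#' Generate a synthetic two-channel sub-grid with ground truth
#'
#' Lays out the configured spot lattice with per-spot center jitter, deletes
#' a Bernoulli subset of spots, scales channel 2 by the per-spot ratio, adds
#' background, truncated-Gaussian noise and salt impulses, clamps to
#' `[0, 65535]` and rounds to integers. The returned truth records, for
#' every lattice position: center, presence, true ratio, and the spot mask
#' inside a whole-image label matrix (0 = background, spot index otherwise),
#' plus the true grid-line coordinates (midlines between adjacent spot
#' rows/columns and outer boundaries). The same seed reproduces the output
#' bit-exactly.
#'
#' @param cfg a [sim_config()].
#' @return List with `ch1`, `ch2` ([channel_image]s), and `truth`: a list
#'   with `spots` (data frame: `spot_row`, `spot_col`, `center_y`,
#'   `center_x`, `present`, `ratio`), `label` (integer matrix, row-major
#'   spot index or 0), `hlines`, `vlines`, `n_rows`, `n_cols`, and the
#'   noise-free images `clean1`, `clean2`.
#' @export
generate_subgrid <- function(cfg = sim_config()) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  l <- cfg$n_rows; s <- cfg$n_cols
  h <- 2L * cfg$margin + cfg$pitch * l
  w <- 2L * cfg$margin + cfg$pitch * s
  if (h > 20000L || w > 20000L) stop("requested grid exceeds supported image size")
  clean1 <- matrix(0, h, w)
  clean2 <- matrix(0, h, w)
  label <- matrix(0L, h, w)
  ratio_m <- if (is.matrix(cfg$ratio)) cfg$ratio else matrix(cfg$ratio, l, s)
  spots <- expand.grid(spot_col = seq_len(s), spot_row = seq_len(l))
  spots <- spots[, c("spot_row", "spot_col")]
  spots$present <- stats::runif(nrow(spots)) >= cfg$missing_frac
  spots$ratio <- as.numeric(t(ratio_m))[seq_len(nrow(spots))]
  spots$center_y <- NA_real_; spots$center_x <- NA_real_
  d <- cfg$diameter
  half <- (d - 1L) %/% 2L
  for (k in seq_len(nrow(spots))) {
    r <- spots$spot_row[k]; c <- spots$spot_col[k]
    cy <- cfg$margin + as.integer(round((r - 0.5) * cfg$pitch))
    cx <- cfg$margin + as.integer(round((c - 0.5) * cfg$pitch))
    if (cfg$jitter > 0L) {
      cy <- cy + sample(-cfg$jitter:cfg$jitter, 1L)
      cx <- cx + sample(-cfg$jitter:cfg$jitter, 1L)
    }
    spots$center_y[k] <- cy; spots$center_x[k] <- cx
    if (!spots$present[k]) next
    sp <- render_spot(cfg$shape, d, cfg$amplitude)
    ys <- cy - half + seq_len(d) - 1L
    xs <- cx - half + seq_len(d) - 1L
    keep_y <- ys >= 1L & ys <= h
    keep_x <- xs >= 1L & xs <= w
    py <- ys[keep_y]; px <- xs[keep_x]
    patch <- sp$patch[keep_y, keep_x, drop = FALSE]
    msk <- sp$mask[keep_y, keep_x, drop = FALSE]
    clean1[py, px] <- clean1[py, px] + patch
    clean2[py, px] <- clean2[py, px] + patch / spots$ratio[k]
    lab <- label[py, px]
    lab[msk] <- k
    label[py, px] <- lab
  }
  clean1 <- clean1 + cfg$background_level
  clean2 <- clean2 + cfg$background_level
  if (!is.null(cfg$artifact)) {
    a <- cfg$artifact
    rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    blob <- (rr - a$row)^2 + (cc - a$col)^2 <= a$radius^2
    clean1[blob] <- clean1[blob] + a$level
    clean2[blob] <- clean2[blob] + a$level
  }
  noisify <- function(clean) {
    px <- clean
    if (cfg$noise_sd > 0) px <- px + stats::rnorm(h * w, 0, cfg$noise_sd)
    if (cfg$impulse_frac > 0) {
      n_imp <- round(cfg$impulse_frac * h * w)
      if (n_imp > 0) {
        at <- sample.int(h * w, n_imp)
        px[at] <- stats::runif(n_imp, 0.8, 1) * 65535
      }
    }
    matrix(as.integer(pmin(pmax(round(px), 0), 65535)), h, w)
  }
  ch1 <- noisify(clean1)
  ch2 <- noisify(clean2)
  hlines <- cfg$margin + cfg$pitch * (0:l)
  hlines[1L] <- max(1L, hlines[1L]); hlines[l + 1L] <- min(h, hlines[l + 1L])
  vlines <- cfg$margin + cfg$pitch * (0:s)
  vlines[1L] <- max(1L, vlines[1L]); vlines[s + 1L] <- min(w, vlines[s + 1L])
  list(ch1 = channel_image(ch1, "ch1"),
       ch2 = channel_image(ch2, "ch2"),
       truth = list(spots = spots, label = label,
                    hlines = as.integer(hlines), vlines = as.integer(vlines),
                    n_rows = l, n_cols = s,
                    clean1 = clean1, clean2 = clean2))
}

#' Ground-truth mask of one spot inside its grid cell
#'
#' @param truth the `truth` element of [generate_subgrid()].
#' @param grid a [grid_model()] (typically built from `truth$hlines`/`vlines`).
#' @param r,c spot row/column.
#' @return Logical matrix over the cell (`TRUE` where the spot's label is).
#' @export
truth_cell_mask <- function(truth, grid, r, c) {
  cell <- grid_cell(grid, r, c)
  k <- (r - 1L) * truth$n_cols + c
  truth$label[cell$rows, cell$cols, drop = FALSE] == k
}
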