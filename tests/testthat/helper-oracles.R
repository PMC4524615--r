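# Independent oracles used to cross-check the package implementations.
# These are deliberately written as plain, slow, loop-based re-derivations
# so they share no code path with the package.

# Brute-force two-class between-class-variance argmax over all thresholds.
# Works directly on integer levels in 1..L; explicit loops, no cumsums.
oracle_bcv_threshold <- function(levels, L = 256L) {
  N <- length(levels)
  P <- numeric(L)
  for (i in seq_len(L)) P[i] <- sum(levels == i) / N
  ubar <- sum(seq_len(L) * P)
  best_t <- NA_integer_; best_d <- -Inf
  for (t in seq_len(L - 1L)) {
    w <- sum(P[1:t])
    if (w <= 0 || w >= 1) next
    ut <- sum((1:t) * P[1:t])
    d <- (ubar * w - ut)^2 / (w * (1 - w))
    if (is.finite(d) && d > best_d) { best_d <- d; best_t <- t }
  }
  best_t
}

# Iterative geodesic reconstruction-by-dilation oracle on a 1-D signal:
# pointwise loop version of marker <- min(3-point max of marker, mask).
oracle_reconstruct <- function(marker, mask) {
  n <- length(marker)
  rec <- marker
  repeat {
    nxt <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
      nxt[i] <- min(max(rec[lo:hi]), mask[i])
    }
    if (all(nxt == rec)) return(rec)
    rec <- nxt
  }
}

oracle_hdome <- function(v) {
  marker <- pmax(v - mean(v), 0)
  v - oracle_reconstruct(marker, v)
}

# Brute-force rasterized disk pixel count in an nr x nc cell.
oracle_disk_count <- function(nr, nc, y0, x0, diameter) {
  cnt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if ((i - y0)^2 + (j - x0)^2 <= (diameter / 2)^2) cnt <- cnt + 1L
  cnt
}

# Reference 3x3 median with edge replication via direct neighbourhood sort.
oracle_median3x3 <- function(px) {
  h <- nrow(px); w <- ncol(px)
  out <- px
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- pmin(pmax(i + (-1:1), 1L), h)
    cj <- pmin(pmax(j + (-1:1), 1L), w)
    out[i, j] <- median(px[ri, cj])
  }
  out
}

# A random quantized profile with two well-separated modes plus stragglers.
random_levels <- function(n, L = 256L) {
  sample.int(L, n, replace = TRUE,
             prob = dgamma(seq_len(L), shape = runif(1, 0.5, 3),
                           rate = runif(1, 0.01, 0.1)) + 1e-6)
}

# Small noisy spot cell for clustering tests: circle of given amplitude on
# a flat background, Gaussian noise, integer gray levels.
random_cell <- function(size = 14L, amp = 200, bg = 50, sd = 20,
                        diameter = 8L) {
  diameter <- min(as.integer(diameter), size - 2L)
  cell <- matrix(bg, size, size)
  sp <- spotclust::render_spot("circle", diameter, amp)
  at <- floor((size - diameter) / 2) + seq_len(diameter)
  cell[at, at] <- cell[at, at] + sp$patch
  truth <- matrix(FALSE, size, size)
  truth[at, at] <- sp$mask
  noisy <- matrix(pmax(0, round(cell + rnorm(size^2, 0, sd))), size, size)
  list(cell = noisy, truth = truth)
}
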