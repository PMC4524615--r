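# spotclust

Combined-clustering segmentation and quantification of two-channel cDNA
microarray sub-grid images.

## What it does, and for whom

A two-dye microarray scan yields two co-registered 16-bit grayscale TIFFs
per sub-grid (Cy3/green and Cy5/red). Turning them into per-gene expression
values requires gridding the image into one cell per spot, labeling each
cell's spot pixels, and extracting a background-subtracted log ratio — and
all three steps degrade on real images with low contrast, noise, dust,
missing spots and irregular spot shapes. `spotclust` is for anyone who
needs a self-contained, fully testable implementation of that pipeline:

* **enhancement** — automatic contrast gain `10000 / C` applied only to
  pixels above an edge-sampled background level `k`, where the contrast
  degree `C = s / (s4/s2²)^¼` is the standard deviation deflated by the
  fourth root of the kurtosis; then a 3×3 median filter;
* **gridding** — projection profiles `H(y) = Σ_x g(x,y)`,
  `V(x) = Σ_y g(x,y)`, h-dome filtering by 1-D geodesic reconstruction,
  exhaustive maximum between-class-variance thresholding
  `d(t) = (ū·ω − u_t)² / (ω(1−ω))`, edge-hop line extraction and
  statistical line refinement;
* **segmentation** — per cell, two-class *moving k-means* (fitness-balanced
  member transfers controlled by `α₀ ∈ (0, 1/3)`) OR-combined with plain
  k-means when the foreground is the minority (`N_t < N_b`), plus a
  rasterized-disk fallback when `N_t < 0.3 (N_t + N_b)`;
* **quantification** — on the *raw* images only:
  `M_e = M_t − M_b` per channel and `value = log₂(M_e1 / M_e2)`;
* **simulator + metrics** — ground-truthed synthetic sub-grids (six spot
  morphologies, noise, impulses, jitter, missing spots) and the
  correctly/marginally/incorrectly verdict taxonomy, pixel-count RMSE and
  intensity MSE.

See `vignettes/spotclust-methods.Rmd` for the full model description and
design rationale.

## Worked example

```r
library(spotclust)

# a 5x7 sub-grid, channel ratio 2 (true log2 ratio = 1), 10% missing spots
sim <- generate_subgrid(sim_config(seed = 11, ratio = 2))
res <- run_pipeline(sim$ch1, sim$ch2, params = enhance_params(seed = 11))

round(c(C = res$enhanced1$C, k = res$enhanced1$k, gain = res$enhanced1$gain), 2)
#>       C       k    gain
#> 1375.42 3096.00    7.27

res$grid
#> <grid_model: 5 x 7 spots, rows [7..101], cols [8..138]>

head(res$table[, c("spot_row", "spot_col", "Nt", "Me1", "Me2",
                   "log_ratio", "qc_flag")], 4)
#>   spot_row spot_col  Nt       Me1       Me2 log_ratio        qc_flag
#> 1        1        1 115 7639.2920 3916.5769 0.9638457             ok
#> 2        1        2 196  340.9268  155.2960 1.1344413             ok
#> 3        1        3 112 7638.2232 3766.8484 1.0198791             ok
#> 4        1        4 175  290.3659 -131.8646        NA nonpositive_Me
```

Channel 1's contrast was magnified 7.3×; the grid was recovered at the true
5×7 layout; spot (1,1) has background-subtracted means 7639 vs 3917 gray
levels, i.e. a log2 ratio of 0.96 against the simulated truth of 1.0. Spot
(1,4) is one of the simulated *missing* spots: its cell contains only
noise, so its channel-1 `M_e` is near zero (here slightly negative) and the
spot is flagged rather than valued.

Scoring against the simulator's truth:

```r
ev <- evaluate_subgrid(res$masks, sim$truth, res$grid, res$table)
round(c(ev$rates, dice = ev$mean_dice, rmse = ev$pixel_rmse), 3)
#>   correctly  marginally incorrectly        dice        rmse
#>       0.829       0.000       0.171       0.994       1.850
```

Mean Dice 0.994 and a pixel-count RMSE below 2 pixels on the present spots;
the "incorrect" verdicts are the missing spots, where the circle fallback
draws a disk on an empty cell and the scorer conservatively counts that as
a false detection.

A command-line interface wrapping the same functions is installed at
`exec/spotclust` (verbs `simulate`, `enhance`, `grid`, `segment`,
`extract`, `evaluate`, `run`).

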