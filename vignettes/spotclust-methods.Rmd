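---
title: "Combined-clustering segmentation of microarray sub-grids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined-clustering segmentation of microarray sub-grids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotclust)
```

## The problem

A two-dye cDNA microarray experiment produces, for every sub-grid of the
slide, two co-registered 16-bit grayscale TIFF images — the Cy3 (green) and
Cy5 (red) channels. Each printed spot's expression readout is the log ratio
of its background-subtracted mean intensities in the two channels. Getting
from pixels to that number requires three image-analysis stages, each of
which degrades badly on real scanner output (low contrast, photon and
electronic noise, dust, missing spots, doughnut- or crescent-shaped spots):

1. **gridding** — partition the sub-grid into one rectangular cell per spot;
2. **segmentation** — label each cell's pixels as spot foreground or
   background;
3. **quantification** — turn the labels into a per-spot log ratio.

`spotclust` implements a complete pipeline for this, built around a
combination of two clustering algorithms, plus the synthetic-image
simulator and the metrics needed to test every stage without any slide
images.

## Contrast enhancement

Spots in low-quality scans sit barely above background, and gridding by
projection fails when they do. The enhancement stage multiplies every pixel
strictly above an estimated background level $k$ by an automatic gain,

$$g(x,y) = \begin{cases} f(x,y)\cdot\frac{10000}{C} & f(x,y) > k \\
f(x,y) & \text{otherwise,}\end{cases}$$

and leaves background untouched. The contrast degree
$C = s\,/\,(s_4/s_2^2)^{1/4}$ is computed from the population moments of
the pixel values ($s_2$, $s_4$: second and fourth central moments,
$s=\sqrt{s_2}$). The denominator is the fourth root of the kurtosis:
a spotty, heavy-tailed image already has visible structure and gets a
larger $C$ — hence a *smaller* gain — than its standard deviation alone
would suggest. A low-contrast image gets a large gain. The constant 10000
is a fixed scale factor (`gain_numerator` in `enhance_params()`), and
amplified values are clamped at 65535 — the product can exceed the 16-bit
range, so all arithmetic is done in doubles and rounded once at the end.

The background level $k$ is estimated by sampling: in each of `reps = 10`
repetitions, three random 10×10 blocks are placed in each of the four
border bands of the image, the maximum is taken inside each block, the
minimum of the twelve maxima is kept, and $k$ is the rounded mean of the
ten minima. Block maxima make the estimate sit at the *top* of the
background noise distribution (so noise is not amplified), and the minimum
over blocks rejects any block that accidentally caught a bright artifact.
The border band is 10% of the corresponding image dimension, never
narrower than one block — spots live in the interior of a sub-grid, so the
band sees only background. Block placement is the pipeline's only
stochastic step; `enhance_params(seed = )` pins it.

Order of operations per channel: estimate $k$ on the raw channel, estimate
$C$ on the raw channel, apply the gain, then a 3×3 median filter
(edge-replicated borders) to remove salt impulses. The two channels are
enhanced independently, because their contrasts genuinely differ — gains of
order 10–25× on one channel and half that on the other are typical.

Two consequences worth knowing:

* pixels at or below $k$ are bit-identical before and after enhancement,
  and the intensity *order* of pixels above $k$ is preserved (the gain is a
  single positive constant);
* when the noise sd approaches the spot amplitude, $k$ (which sits near the
  top of the noise) can exceed dim spot levels entirely, and those spots
  are not amplified. This is inherent to the thresholded-gain design, not
  an implementation artifact.

## Gridding

Gridding runs on the enhanced, median-filtered image — on the elementwise
sum of the two enhanced channels when both are available, so that a spot
expressed in only one dye still anchors the grid. Per axis:

1. **Projection.** $H(y) = \sum_x g(x,y)$ (one value per row) and
   $V(x) = \sum_y g(x,y)$ (one per column). Spot rows are peaks, gutters
   are valleys.
2. **h-dome filtering.** $H' = H - \mathrm{rec}(\max(H-\bar H, 0) \mid H)$,
   where $\mathrm{rec}(m \mid f)$ is 1-D grayscale geodesic reconstruction
   by dilation (iterate $m \leftarrow \min(\mathrm{dilate}_3(m), f)$ to a
   fixed point; the 3-point dilation is a running max). The marker is
   clipped at zero so it stays below the mask and the reconstruction stays
   non-negative. The effect: valleys go to zero, peaks are clipped at
   bounded height — baseline drift and broad background trends vanish while
   every spot band survives at comparable height. The fixed point is
   reached in at most `length(profile)` iterations (information travels one
   position per sweep).
3. **Thresholding.** The filtered profile is linearly quantized to
   $L = 256$ integer levels, and a two-class between-class-variance
   criterion
   $d(t) = (\bar u\,\omega(t) - u_t)^2 / \big(\omega(t)(1-\omega(t))\big)$
   is evaluated exhaustively at every $t \in [1, L-1]$;
   $\omega(t)$ is the class probability below $t$, $u_t$ the first
   cumulative moment, $\bar u$ the global mean. Ties break to the smallest
   $t$, for determinism. Printed forms of this criterion vary and are often
   typographically ambiguous; since all its auxiliary quantities are
   exactly those of the classical between-class-variance threshold, that
   reading is the default, and an alternative reading
   $\mu_\delta^2(\omega - \mu_{\delta t}^2)^2/(\omega(1-\omega))$ is kept
   available as `criterion = "literal"`.
4. **Binarization and edge-hop extraction.** The profile becomes 0/1 at the
   threshold; runs of 1s are spot bands, the band count is the spot count,
   and grid lines are placed at the midpoints of the zero gaps between
   bands, plus one boundary line on each side (gap midpoint, or the signal
   end when a band touches it). For $n$ bands this yields $n+1$ lines.
5. **Refinement.** Two statistical repairs: a line that landed on a band is
   snapped to the nearest zero coordinate, and spacing outliers relative to
   the median spacing $\Delta_m$ are fixed — gaps wider than
   $1.5\,\Delta_m$ get lines inserted at multiples of $\Delta_m$, gaps
   narrower than $0.5\,\Delta_m$ collapse to their midpoint. Both factors
   are arguments of `refine_lines()`. This is a deliberately simple
   substitute for more elaborate heuristic rule sets used in production
   gridders; on simulated sub-grids with ≤ 15% pitch jitter it is
   sufficient for exact layout recovery.

Cells are half-open rectangles $[h_r, h_{r+1}) \times [v_c, v_{c+1})$ in
1-based pixel coordinates, so they tile the spanned region disjointly.

## Segmentation

Within each cell, pixels are clustered into two classes on a scalar
feature: the summed intensity $g_R + g_G$ (a single channel contributes its
own intensity). A five-feature mode — pixel row, column, distance to the
current cluster center, and the two channel intensities, each z-scaled to
unit variance over the cell — is available as `mode = "full5"`, but the
scalar mode is the default because the clustering's transfer test
("gray value below the center") is only well defined on a scalar; in
`full5` mode that test and the initialization use the combined-intensity
coordinate.

**k-means** (`kmeans_segment()`): centers initialized at the maximum and
minimum gray values, then standard nearest-center assignment (ties to the
first class) and center-mean updates to convergence. At the fixed point
each center equals the mean of its members and reassignment reproduces the
labels exactly — this is checked, not assumed.

**Moving k-means** (`moving_kmeans_segment()`): same initialization, but
after each assignment round the *fitness* $F(c) = \sum_{i \in c} \|g_i -
c\|^2$ of the two centers is compared. While the lower fitness is below
$\alpha_a$ times the higher, members of the higher-fitness class with gray
value below that class's center are transferred to the lower-fitness
class, both centers are recomputed as member means, and $\alpha_a$ halves.
Then all pixels are reassigned, $\alpha_a$ resets to $\alpha_0$, $\alpha_b$
halves, and the outer loop repeats until the lower fitness reaches
$\alpha_b$ times the higher. The transfers keep one cluster from collapsing
onto a few extreme pixels, which is exactly the failure mode of plain
k-means on low-contrast noisy spots. $\alpha_0$ must lie in $(0, 1/3)$;
the default is 0.3, at the top of the admissible range (slow relaxations of
the balance condition). Two termination guards exist beyond the formal
condition: if no member qualifies for transfer the inner loop cannot make
progress and exits (with $F(c_l) = 0$ the formal condition can never be
met), and iteration caps (inner 1000, outer 100) set a `warning_flag`
rather than loop forever.

**Combination** (`combine_masks()`): if the moving k-means mask already has
$N_t \ge N_b$ it stands. Otherwise k-means runs too and the final
foreground is the pixelwise OR of both foregrounds. The union can only add
pixels, so whenever the trigger fires the combined foreground is a superset
of the moving k-means foreground. With spots that occupy less than half
their cell — the usual geometry — the trigger fires on nearly every cell,
so "combined" really is the OR of both methods almost everywhere.

**Circle fallback** (`circle_fallback()`): when even the combined
foreground covers less than 30% of the cell ($N_t < 0.3(N_t+N_b)$), the
spot is replaced by a rasterized disk at the cell's intensity centroid.
The disk diameter is taken from the segmentation results themselves: the
median equivalent diameter $2\sqrt{N_t/\pi}$ over the cells that did *not*
need the fallback, or half the smaller cell dimension if every cell needs
it. The fallback fires on genuinely weak spots and also, by construction,
on missing spots — a disk is drawn where nothing is. Downstream, such
cells are distinguishable by their `method_flag` and usually by a
near-zero $M_e$; the evaluation module scores a detection on an empty
truth mask as incorrect, which is the conservative choice.

One behavior to be aware of: on a featureless cell containing only
continuous Gaussian noise, any two-class clusterer splits the noise
roughly in half, so $N_t \approx N_b$ and the fallback does *not* trigger.
The fallback-everywhere degradation is only guaranteed for near-constant
cells (where clustering is degenerate) or impulse-dominated cells (where
the bright class is tiny).

## Quantification

Intensity extraction always reads the **raw** images — never the enhanced
ones. Enhancement multiplies above-background pixels by a per-channel
gain (and the two channels by *different* gains), so means computed on the
enhanced images would be distorted by exactly those factors. Per channel:
$R_t$, $R_b$ (summed foreground/background intensity over the cell),
$M_t = R_t/N_t$, $M_b = R_b/N_b$, and the background-subtracted mean
$M_e = M_t - M_b$; the background region is the within-cell complement of
the foreground mask. The readout is

$$\mathrm{value} = \log_2\!\big(M_{e1}/M_{e2}\big),$$

base 2 by convention (configurable, `log_base`). Flags instead of errors:
$N_t = 0$ → `missing`; $N_b = 0$ → `degenerate`; $M_e \le 0$ in either
channel → `nonpositive_Me` with no value. The value is invariant to a
common positive rescaling of both channels' $M_e$, and re-running
extraction after enhancement is bit-identical, because the raw inputs are
untouched.

## The simulator

`generate_subgrid()` renders an $l \times s$ lattice of spots at a fixed
pitch with per-spot center jitter, Bernoulli missing spots, additive
Gaussian noise (truncated by the clamp to $[0, 65535]$), uniform bright
salt impulses, an optional blob artifact, and six spot morphologies seen
on real slides: filled circle, doughnut (central dropout), egg (1.3-axis
ellipse), crescent (offset-disk bite), peak (radial Gaussian) and volcano
(bright rim with a dim center). Channel 2 is channel 1 scaled by the
per-spot ratio before noise, so the noise-free realized ratio is exact.
Ground truth records every spot's center, presence, ratio and pixel mask
(as a label matrix), plus the true grid lines.

Defaults describe a small, slightly imperfect sub-grid: 5×7 spots on an
18-pixel pitch (12-pixel diameter), background 1000, channel-1 amplitude
8000, Gaussian noise sd `amplitude/8`, 0.1% impulses, 10% missing spots,
jitter up to 10% of the pitch. Presets `sib` (5×7, pitch 18), `ucsf`
(14×15, pitch 8) and `derisi` (40×40, pitch 8) mirror published sub-grid
geometries so tests can span sparse-large-spot and dense-small-spot
regimes.

What the simulator does **not** model: scanner point-spread blur, spatially
correlated background gradients, channel misregistration, and rotated or
sheared grids. Passing tests on simulated sub-grids therefore demonstrate
the algorithmic properties (oracle equivalences, fixed points, recovery
under noise/jitter/missingness as configured) — not performance on any
particular scanner's output.

## Verification choices and problem sizes

The test suite checks every numeric kernel against an independent oracle:
the threshold search against a loop-based brute-force argmax (1,000 random
profiles, bit-exact), the h-dome filter against a pointwise iterative
geodesic-dilation reference (200 profiles), the median filter against a
direct neighbourhood sort, disk rasterization against pixel enumeration,
and k-means convergence against its fixed-point definition (500 random
cells). Pipeline-level checks use 100 simulated sub-grids (presets `sib`
and `ucsf`, SNR 4, 10% missing, jitter ≤ 15% of pitch) for exact layout
recovery, and a 315-spot batch at spot amplitude equal to the noise sd
(SNR 1, the regime where clustering robustness matters) for the method
comparison, where the correctly-segmented rate orders
k-means ≤ moving k-means ≤ combined. These sizes keep the whole suite
under a minute on one core while leaving the statistical margins
comfortable.

A spot verdict is `correctly` when the hole-filled detected mask reaches
Dice ≥ 0.8 against truth with no enclosed holes, `marginally` with holes,
`incorrectly` below the Dice threshold — the threshold is an operational
proxy for "the edge is right" and is configurable in `judge_spot()`.

## Known limitations

* Single sub-grid per image; no meta-grid detection or rotation correction.
* Registration of the two channels is assumed perfect.
* Exactly two clusters; spots are assumed bright on a dark background.
* The circle fallback cannot distinguish a weak spot from a missing one;
  it marks both with `method_flag = "circle"` and leaves the decision to
  the quality flags downstream.
* The refinement heuristics assume an approximately uniform pitch; strongly
  non-uniform layouts would need the split/collapse factors retuned.
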