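---
title: "Models and measurement methods in angioquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement methods in angioquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioquant)
```

This vignette documents the generative models behind the synthetic data,
the measurement algorithms applied to them, and the numerical choices made
along the way. The guiding design rule is that every measured quantity has
a generator counterpart with a known (usually analytic) ground truth, so
the full measurement chain can be validated end to end.

## Angular conventions

All directional quantities share one frame. A `wound_edge(point,
normal_deg)` carries a unit inward normal $\hat n$ (into the cell-free
side) and a unit edge direction $\hat e = R(-90^\circ)\,\hat n$, so
$(\hat e, \hat n)$ is right-handed. The signed angle of a vector $v$ is

$$\alpha = \operatorname{atan2}(v\cdot\hat n,\; v\cdot\hat e)$$

in degrees, wrapped to $(-180, 180]$. "Oriented" always means
$\alpha \in [60^\circ, 120^\circ]$, a closed window; its mass under a
uniform angular distribution is exactly $1/6$, which the test suite uses as
a null calibration.

Under a rigid rotation of scene plus edge, $\alpha$ is invariant; under a
mirror across the edge line, $\alpha \mapsto -\alpha$; under a mirror
across the normal axis, $\alpha \mapsto 180^\circ - \alpha$ (wrapped).
These identities are asserted in the tests at $10^{-6}$-degree precision.

## Migration: biased persistent random walks

`simulate_tracks()` draws, per cell and frame, a heading from a von Mises
distribution whose mean is the circular weighted mean of the previous
heading (weight 1) and the inward wound normal (weight `bias_weight`), with
concentration `persistence_kappa`; the step length is Normal
(`speed_mean_um`, `speed_sd_um`), truncated at zero by resampling. Defaults
(37 frames at 10-minute intervals, so a 6-hour period) mirror a typical
scratch-wound time-lapse.

Degenerate limits are exact: `persistence_kappa = Inf` with
`bias_weight = Inf` yields perfectly straight, edge-normal tracks;
both parameters zero yield an isotropic random walk, which the tests
compare against an independently coded cumulative-sum walk.

`track_statistics()` reports per track the total path length, net
displacement, their ratio (persistence), and the net direction. Persistence
of a track with zero total displacement is undefined and flagged rather
than forced to a value. Von Mises sampling uses the Best–Fisher rejection
algorithm (implemented in the package; no circular-statistics dependency),
and concentration recovery uses the maximum-likelihood equation
$A_1(\kappa) = \bar R$ solved by `uniroot()` on exponentially scaled Bessel
functions, switching to the large-$\kappa$ expansion
$\kappa \approx 1/(2(1-\bar R))$ beyond the root bracket.

## Tracking from rendered movies

Rendering uses analytic Gaussian spots (outer products over a $\pm4\sigma$
halo) on a pixel grid whose pixel $(i, j)$ has its centre at
$((i-\tfrac12)\,\text{px}, (j-\tfrac12)\,\text{px})$; matrices are indexed
`[ix, iy]`. Detection applies a difference-of-Gaussians band-pass, local
maxima with non-maximum suppression, and intensity-weighted sub-pixel
refinement with local background subtraction.

Frame-to-frame linking solves, per frame pair, a padded square linear
assignment problem in the style of standard particle-tracking costs: link
costs are Euclidean distances up to a gate `max_disp_um`, birth/death
diagonal entries equal the gate, and the auxiliary block is zero; the
problem is solved exactly with `clue::solve_LSAP()`. There is no gap
closing — an unmatched detection starts a new track. The test suite checks
exact agreement with a brute-force enumeration of all partial matchings on
one hundred random instances.

## Golgi–nucleus polarity

`generate_monolayer_scene()` places nuclei by jittered-grid hard-core
sampling: grid pitch $g = s/0.6$ and jitter $\pm 0.2g$ guarantee the
minimum spacing $s$ by construction, and an infeasible request fails with
the achievable count instead of degrading silently. Each Golgi sits at an
absolute direction $(\text{normal}_\circ - 90) + \alpha$ from its nucleus
with $\alpha \sim \mathrm{vM}(90^\circ, \kappa)$, so the generated signed
angle is exactly $\alpha$ and the analytic oriented fraction is the von
Mises window mass, computed by `stats::integrate()` and cross-checked
against a Riemann sum.

Measurement mirrors a real two-channel image analysis: Otsu thresholding
and connected components per channel (`segment_blobs()`), mutual
nearest-neighbour Golgi–nucleus pairing under a distance gate (ties broken
to the lower index and flagged), signed polarization angles, and layer
assignment `ceiling(d / layer_width)` from the edge with cells beyond
`n_layers` or on the wound side excluded — matching the practice of scoring
only the first few rows of cells at a wound.

`estimate_wound_edge()` emulates drawing the leading edge by hand: cells
are binned along an approximate edge axis, the wound-most cell per bin
defines frontier points, and a total-least-squares line through them gives
the edge, with the normal oriented toward the sparse side. When the field
extent is supplied, a frontier hugging the field border is rejected
explicitly ("no scratch in view"), since positions alone cannot
distinguish a full field from an off-screen wound.

## Vascular front, filopodia, sprouts, retina

The synthetic front is a sine polyline with analytic tangents; tip-cell
directions are drawn at von Mises angles about the local inward normal.
Measurement re-estimates the tangent by a total-least-squares fit over a
window of vertices around the nearest vertex, shrunk symmetrically near
polyline ends to avoid one-sided curvature bias (residual error is a few
hundredths of a degree). The orientation reference point must lie on the
avascular side; the generator places it effectively at infinity along the
inward direction so the normal never flips at the ends.

Filopodia are measured on binary masks: Zhang–Suen skeletonization, local
width as twice the Euclidean distance transform along each skeleton branch,
acceptance when the mean width is below 0.1 µm, and length as the straight
base-to-tip chord, with branch walks terminating at skeleton junctions or
on entering the cell body (local width at or above the cut-off). The pixel
grid must resolve the diameter rule (`pixel_size_um <= diameter_max_um`),
otherwise the measurement refuses to run.

Spheroid sprouts are read from the radial occupancy profile about the mask
centroid: the body radius is the outermost 1-pixel annulus with at least
`body_quantile` occupancy (exact grid-pixel denominators), and sprouts are
wrap-aware connected angular components of pixels beyond the body radius,
excluding the sub-pixel rasterisation rim, each measured as maximal radial
extent minus body radius.

Retina masks combine a disc retina, a central avascular disc (or annulus
sector) hitting an analytic area target, a jittered rectangular capillary
grid with analytic fill fraction $1-(1-t/s)^2$, and a vessel ring along the
avascular border so mesh gaps stay enclosed. `vessel_density()` is a pixel
fraction over any sub-region; `avascular_fraction()` closes the vessel
raster morphologically (dilation followed by erosion, so inter-capillary
gaps are bridged *without* shrinking a genuine lesion), labels connected
avascular regions, discards those below an area threshold, and reports kept
avascular area over retina area.

## Statistics

`welch_t_test()` wraps `stats::t.test()` with explicit handling of
zero-variance degenerate groups (equal constants give $p = 1$; unequal
constants are flagged with $p = 0$). `anova2_bonferroni()` fits
`value ~ f1 * f2` via `stats::aov()`, reduces to one-way with a warning
when a factor is constant, and follows with pairwise Welch tests between
factor-level cells, Bonferroni-adjusted ($p \times m$, capped at 1) over a
caller-specifiable comparison family. Null calibration of both tests is
part of the acceptance suite (rejection rates within three binomial
standard errors of $\alpha = 0.05$ over 2,000 simulations).

## Pipeline and reproducibility

`run_pipeline()` executes any subset of the four stages for a named set of
conditions. Per-condition seeds are derived deterministically from the
master seed (condition index × 1000, plus a per-stage offset), so reruns
are byte-identical; outputs are plain CSV, a JSON summary, and a log.
All generators take explicit integer seeds and never touch the global RNG
outside `set.seed(seed)` at entry.

```{r example, eval = FALSE}
report <- run_pipeline(list(
  seed = 1, stages = c("tracks", "retina"),
  conditions = list(
    control   = list(tracks = list(bias_weight = 2),
                     retina = list(vo_fraction_target = 0.05)),
    knockdown = list(tracks = list(bias_weight = 0),
                     retina = list(vo_fraction_target = 0.15)))),
  out_dir = NULL)
report$track_summary
report$retina
```
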