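---
title: "How faithfully does PIV capture self-propelled particle motion?"
author: "pivalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How faithfully does PIV capture self-propelled particle motion?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pivalign)
```

## The question

Particle image velocimetry (PIV) estimates a displacement field from pairs of
images by matching interrogation windows between frames. In collective cell
migration it is routinely used where tracking individual cells is infeasible.
But PIV returns one vector per grid — an aggregate — while the biology often
asks about individual motility. When cells move like coupled stochastic
agents rather than a viscous flow, how well does the PIV vector actually
represent the motion of the cells around it?

`pivalign` answers this with a fully synthetic, ground-truth-controlled
pipeline: simulate agents whose true velocities are known, render them into
images that carry no information beyond what a microscope-like image would,
run PIV on the images alone, and compare the PIV field against the hidden
trajectories.

## The agent model

Agents follow the Vicsek model: `N` point agents move at a common constant
speed `v0` in a periodic square box of side `L`. Each step, agent `i` adopts
the circular mean heading of all agents within the interaction radius `r`
(itself included), computed as `atan2(sum sin, sum cos)` over the
neighborhood, plus an independent uniform perturbation in
`[-eta0/2, eta0/2]`. Positions advance along the *old* headings (synchronous
update, positions first-order in `dt`). The noise amplitude `eta0` is the
control parameter: low noise produces a globally ordered phase (order
parameter `v_a` near 1), high noise a disordered phase (`v_a` near 0), with
a transition near `eta0 = pi` for the default geometry.

Numerical conventions worth stating:

* the circular mean uses the two-argument arctangent, which is
  quadrant-correct where a naive arctan of the ratio is wrong in quadrants
  II/III; in the measure-zero case where both sums vanish the agent keeps
  its heading;
* noise is drawn per agent per step, not once per system;
* all distances use the periodic minimum-image convention;
* neighbor search uses cell lists (cell width at least `r`), which is exact:
  the suite checks it against an all-pairs reference.

Defaults mirror the standard study conditions: `L = 5` units rendered at 123
px/unit (615-px images), `N = 300`, `v0 = 0.03` units/step (3.7 px/frame),
`r = 0.5` units (61.5 px), `dt = 1`.

## Synthetic images

Each recorded state becomes an 8-bit grayscale frame: one black (intensity 0)
filled oval per agent on a white (255) background, 8 px along the major axis
aligned with the heading, 6 px along the minor axis. Two choices matter:

* **Binary rasterization.** A pixel is foreground iff its center lies inside
  the rotated ellipse. Only two intensity levels exist, so there is no
  anti-aliasing; this is deliberate — the image model states particles as
  0-valued pixels on a 255 background.
* **Subpixel centers.** Agent centers stay at continuous pixel coordinates.
  At 3.7 px/frame, snapping centers to integer pixels would quantize every
  PIV displacement.

Ellipses wrap across edges (the world is periodic) and overlaps simply
union. The coordinate convention — row = y, column = x, origin top-left,
pixel centers at half-integers — is recorded in frame metadata and shared
with the PIV stage. Frames can be written/read as PNG with a JSON sidecar.

What the generator does **not** emulate: photometric noise, blur, uneven
illumination, cell division, death, or shape change. Passing tests therefore
demonstrate correctness of the measurement chain on clean, rigid, constant-
count particles — not robustness to optical artifacts of real microscopy.

## PIV

For each 64-px grid (default), the displacement to the best-matching window
in the next frame is found by maximizing the normalized cross-correlation:
both patches are mean-subtracted and the product sum is normalized by the
two patch norms, so the score lies in [-1, 1]. The search covers all integer
displacements within a margin of 16 px per side (search zone 96 px = grid
64 + step 32). Decisions taken where the procedure is underdetermined:

* **Search geometry.** The "step" enlarges the search zone; it is not grid
  overlap. Vectors sit on a lattice with spacing equal to the grid side.
* **Boundary grids** access pixels periodically, consistent with the
  simulation; a 615-px image with 64-px grids keeps its 10th row/column of
  grids, wrapping the 25-px remainder. (For externally supplied,
  non-periodic images, crop to a multiple of the grid instead.)
* **Empty-grid rule.** If the grid region at `t` or its search region at
  `t + 1` contains no foreground pixel, no vector is computed — degenerate
  grids are *missing*, never zero.
* **Undefined correlations.** Constant windows have undefined correlation
  and are excluded from the argmax; a grid with no defined candidate is
  invalid.
* **Tie-break.** Equal peak scores resolve to the smallest displacement
  magnitude, then lexicographically — determinism matters for reproducible
  tables.
* **Subpixel peak** (default on): a three-point Gaussian fit per axis around
  the integer peak, clamped to half a pixel, applied only when the three
  correlation values are positive and concave. The true displacement
  (3.7 px/frame) is non-integer, so integer peaks alone would alias;
  integer mode is retained because exact-recovery oracles (rigid cyclic
  shifts must be recovered *exactly*) are only meaningful there.
* **Vector validation** (default on): the normalized-median test. Each
  vector's residual from the component-wise median of its up-to-8 lattice
  neighbors (periodic wrap), normalized by the median neighbor residual plus
  0.1 px, must not exceed 2.0. Vectors with fewer than two valid neighbors
  are kept. This is a documented stand-in for outlier screening whose exact
  rule the measurement idea leaves open; it is single-pass and conservative.

The C++ search is checked against an exhaustive direct-formula evaluation on
random images, displacement by displacement.

## Comparison metrics

With the trajectory in hand, the package scores the PIV field at the earlier
frame of each pair:

* `v_a` — global order parameter, the magnitude of the mean unit velocity.
* `v_a^{x,R}` / `v_a^R` — local order within radius `R` of each PIV anchor,
  and its mean over anchors with at least one enclosed agent.
* `A^R` — the alignment score: for each valid PIV vector, the mean cosine
  between the vector and the velocities of agents within `R` of its anchor,
  averaged over vectors. 1 = PIV parallel to nearby agents, -1 =
  antiparallel, 0 = unrelated.
* `D^R` — the coherence difference `|v_a^{R,SPP} - v_a^{R,PIV}|`, where the
  PIV-side local order applies the same formula to unit-normalized valid
  vectors at the same centers.

Exclusion rules are uniform: circles enclosing no agent contribute nothing
(the inner average would be 0/0), invalid vectors never participate, and a
zero-magnitude vector has no direction and is likewise excluded. When
nothing participates the value is `NA` and flagged — missing data never
enter averages as zeros.

Two characteristic scales normalize the axes of the landscape experiments:
`gamma0(N) = Gamma / sqrt(N)`, the grid side holding one agent on average,
and `r0(N) = gamma0 / sqrt(pi)`, the analogous circle radius. For a 615-px
image: `gamma0 = 61.5` px at `N = 100` and `35.5` px at `N = 300`;
`r0 = 34.7` and `20.0` px. A competing convention equates the radius scale
with `gamma0` itself (the largest circle inscribed in a grid has radius
roughly `gamma0/2`, but published radius normalizations sometimes quote
`R/R0 = 1` at the grid scale); `r0(..., convention = "grid")` exposes that
reading, the formula is the default, and experiment tables record which one
was active. The two conventions are *not* silently reconciled.

```{r scales}
c(gamma0(100, 615), r0(100, 615), gamma0(300, 615), r0(300, 615))
```

## Experiment drivers and problem sizes

`run_timeseries` renders consecutive pairs and reports `A^R(t)` and
`D^R(t)`; `run_grid_radius_landscape` and `run_noise_radius_landscape`
evaluate the single late-time pair (`t_eval - 1`, `t_eval`) per trial, when
the order parameter has stabilized, and average over trials;
`run_sampling_rate` varies the recording step `tau` (simulation `dt` stays
1) and warns when `tau * v0 * px_per_unit` exceeds the search margin;
`find_transition` sweeps `eta0`, averages `v_a` over the stationary window
`t` in [200, 300], and interpolates the 0.5 crossing — 0.5 being the
conventional marker for the order-disorder midpoint.

Trial `i` uses seed `seed + i - 1`, and the same trial seeds are reused
across noise levels (a paired design that removes initial-condition variance
from cross-noise comparisons). Identical configurations reproduce identical
tables bit for bit.

The shipped defaults run the full published geometry (615-px images, 300
agents, 300 steps). The package's own test suite exercises the complete
pipeline at that scale for the headline checks — low-noise convergence of
`A^R`, the high-noise landscape peak near `(gamma/gamma0, R/R0) = (1, 1)`
with 5 trials, and the transition sweep with 5 trials × 7 noise levels —
and uses a scaled-down 128-px / 30-agent configuration for the remaining
behavioral tests. Those sizes were chosen so the whole suite completes in a
few minutes while every scientific claim is still checked at the scale where
it is stated.

A typical desk-scale replication:

```{r example, eval = FALSE}
cfg <- experiment_config(vicsek = vicsek_params(eta0 = pi / 6),
                         radii = 30, steps = 300, seed = 1)
ts <- run_timeseries(cfg, t_range = c(150, 300))
mean(ts$value[ts$metric == "A_R"], na.rm = TRUE)
#> 0.9914571   (low noise: PIV vectors align almost perfectly with agents)
```

## Known limitations

* The renderer's clean, binary, constant-size particles are the best case
  for correlation matching; real fluorescence or phase-contrast images will
  degrade the correlation peak in ways this toolkit deliberately does not
  model.
* `A^R` compares directions only; speed errors are visible in the vector
  magnitudes the field exposes, but no magnitude-error statistic is scored.
* The normalized-median validation is one reasonable outlier rule among
  several; its threshold (2.0) follows common PIV practice and is
  configurable.
* Landscape grid sides must tile the image reasonably; the lattice accepts
  any side and wraps the remainder periodically, so sides near divisors of
  the image are the intended use.
* With very sparse images a search zone can in principle contain two
  identical-looking windows; the deterministic tie-break picks the smaller
  displacement, which is then wrong for the larger true shift. At the
  default densities this is not observed.
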