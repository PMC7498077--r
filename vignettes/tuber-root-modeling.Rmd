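---
title: "Statistical 3D modeling of potato tuber-root systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical 3D modeling of potato tuber-root systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuberoot)
```

## The modeling problem

At harvest, a potato plant's belowground system is a small tree of organs:
the spent seed tuber; the underground portion of the main stem rising from
it; seminal roots descending from the seed tuber; creeping roots and
creeping stems (stolons) branching off the underground stem; and a daughter
tuber swelling at the end of each fruiting stolon. Interaction studies
between digging implements and the soil–tuber–root aggregate need the
*geometry* of this system — where the organs are, how deep, how thick, how
curved — not its physiology. `tuberoot` treats that geometry statistically:
each characterization parameter of each organ class is a probability
distribution estimated from excavated field samples, and a virtual plant is
one joint draw from those distributions, assembled by a small set of
structural rules. Fibrous roots are excluded throughout; they are too slim
to transmit appreciable force.

The model is a harvest-period snapshot. There is no time axis, no
phenology, and no soil-mechanics feedback on trajectories: geotropism and
soil resistance enter only statistically, through the measured distributions
of angles and deflections.

## Parameter databases

A database maps variety → organ class → parameter → distribution spec. Two
spec kinds exist:

* **normal** `N(mu, sigma^2)`, for parameters whose field samples are
  consistent with normality;
* **empirical**, a piecewise-uniform distribution over closed intervals
  `[a_i, b_i]` with probabilities `p_i` (summing to 1 within 1e-6), for
  everything else. Sampling is inverse-CDF: a uniform `u` picks the interval
  `i` with `u` in `(cum_{i-1}, cum_i]`, then the value is uniform within the
  interval.

The one published example bundled with the package is the Zaodabai
creeping-root initial axial angle:

```{r}
zaodabai_axial_angle_spec()
```

Note the 1-degree gaps between the printed integer bins ([70, 85] then
[86, 100], and so on). The bins are kept verbatim — closed intervals, not
auto-bridged — so a sampled angle never falls in a gap. Whether shared
boundaries should be open or closed is not specified anywhere
authoritative; we treat all intervals as closed and resolve the (measure
zero) ambiguity in favour of the lower interval during selection.

### Fitting

`fit_distribution()` chooses the spec kind with a Shapiro–Wilk test at
`alpha = 0.05` (the original field workflow decided normality with an
unnamed non-parametric test; Shapiro–Wilk is this package's choice and the
level is exposed). Rejected samples are
binned into `k = ceiling(1 + log2(n))` equal-width intervals (Sturges) with
relative-frequency probabilities; empty bins are merged into their right
neighbour. Two special cases matter in practice:

* a zero-variance sample becomes a single degenerate interval `[v, v]` with
  probability 1;
* a sample with at most `k` distinct values (integer organ counts,
  coarse-grained readings) is stored as exact point masses rather than
  equal-width bins. Binning gappy integer data and merging the empty bins
  shifts interval midpoints systematically (about a quarter of a count for
  typical count distributions), which is enough to break mean recovery;
  point masses represent such samples exactly.

Fitting requires at least 8 values per (organ, parameter); below that the
caller must supply an explicit spec. Physically nonnegative parameters
(lengths, radii, depths, counts) are sampled with rejection (up to 100
redraws, then clamped to 0); angles are unrestricted. Counts are rounded to
the nearest nonnegative integer after sampling.

## Topology and assembly

Plants are stored in child-chain (child-sibling) notation: every node holds
a first-child and a next-sibling index. The assembly rules in
`build_plant()`:

* the seed potato is the root node (level 1) at `(0, 0, z0)`, `z0` the
  sampled burial depth;
* exactly one underground stem (level 2) rises vertically from the seed
  toward the surface;
* seminal roots (level 2) start at the seed potato center;
* creeping roots and creeping stems (level 3) start on the stem axis at
  their sampled distance-to-seed `h_g`, clamped to `[0, h_j]` (stem
  height); equal `h_g` collisions are permitted — two organs may root at
  the same height at different radial angles;
* each tuber (level 4) sits at the terminal node of a creeping stem. When
  the sampled tuber count is below the stem count, the longest stems fruit
  first; excess tubers beyond the stem count are dropped with a warning.
  Both rules are this package's choices; the source material is silent.

`traverse()` provides preorder and level-order walks over the child-sibling
links, with cycle detection; the test suite checks both against an explicit
adjacency-list oracle on randomized plants.

## Growth trajectories

A root axis grows from its rooting point in unit-length steps. In the tip's
local frame the undeflected step is `(0, l, 0)`; each step applies a radial
deflection `gamma` (about Z) then an axial deflection `theta` (about X), so
the step displacement is `l * (-cos(theta) sin(gamma), cos(theta)
cos(gamma), sin(theta))` (row-vector convention).

Read literally, a homogeneous-transform recurrence that rotates the
translated point about the *global* frame at every step does not produce a
smooth curve; this package instead accumulates an orientation state — each
step's rotation composes onto the frame in application order — which
reproduces the single-step transform exactly from the identity orientation
and yields the depicted smooth, curved trajectories thereafter.

Choices worth knowing:

* **Uniform bending.** The total deflection `Phi` is divided evenly over
  the `N = round(L / l)` steps, treating root bending as a uniform change.
  Per-step deflections can instead be drawn from a database
  (`step_sampler`) or jittered (`jitter_sd`), both off by default.
* **Growth-unit length** `l` defaults to 1 mm. Smaller values give smoother
  axes; segment lengths are exact (rotations are isometries, tested to
  1e-9 relative).
* **Frame conventions.** Right-handed world frame, z = depth, positive
  downward, soil surface at z = 0. The initial axial angle is measured from
  the upward stem direction (180° = straight down, 90° = horizontal); the
  radial angle from +Y in the horizontal plane. One stated example
  elsewhere implies that a zero axial angle grows along +Y; that cannot
  coexist with the angle-from-stem convention, and we follow the
  convention (the +Y case is axial 90°). Coordinates relative to the
  seed-potato center are recovered by subtracting `(0, 0, z0)`.

## Organ geometry

Meshes are plain vertex/face triangle lists, wound outward, exported as
Wavefront OBJ (named groups) or ASCII PLY:

* seed potato: semi-ellipsoid, flat face up, semi-axes LS/2, WS/2 and dome
  height HS;
* underground stem: a stack of cone frusta whose ring centers are jittered
  off-axis (default 5 % of the bottom radius) to imitate the rough, stitched
  look of a real stem; the radius tapers linearly from `RD` to
  `RD * (1 - rD)` globally across segments;
* roots: circular cross-sections swept along the axis polyline with
  parallel-transport frames (no twist at curvature), radius linear in arc
  length from `r0` to `r_tip`; a zero tip radius becomes a cone apex with
  no degenerate faces;
* tubers: ellipsoids classified by aspect ratio `rho = L/W` (dimensions
  sorted `L >= W >= H`): spherical below 1.15, ellipsoid to 1.8, elongated
  above. The cutoffs are this package's configurable choice; only the three
  class names are given in the source material. Tubers lie with the long
  axis horizontal by default.

Volume convergence (divergence-theorem volume vs closed forms) is about
0.4 % for ellipsoids and 0.6 % for frusta at resolution 32, within 2 % from
resolution 16 up; the acceptance tests pin 2 % at resolution 32.

## Validation

`validate_model()` simulates `n_plants` plants, collects every simulated
root's trajectory depth per class, and compares them with measured depths
using RRMSE and the four-level scale (<10 % extremely significant, 10–20 %
significant, 20–30 % general, >=30 % poor; boundary values go to the worse
class, since the published phrasing of the ranges is open on both sides).
Two design points:

* **Rank pairing.** Field plants and simulated plants have no natural
  one-to-one correspondence, so both depth samples are sorted and paired by
  rank (quantile matching when the sizes differ). This makes the comparison
  distributional, which is the only reading the data supports.
* **Trajectory depths, not distribution draws.** The simulated depth is
  what the generated axis actually reached — so validation exercises the
  entire chain (counts, rooting heights, angles, lengths, deflections,
  stem geometry), not just the fitted depth spec.

## The synthetic field survey

The full multi-variety parameter tables behind the original field campaign
are not publicly available; `default_truth()` therefore ships synthetic but
agronomically plausible truth configurations for the three varieties
(codes 1 = Zaodabai, 2 = Helanshiwu, 3 = Fujin). The **only** published
component is the Zaodabai creeping-root axial-angle distribution; every
other spec is a synthetic default chosen once (seed potatoes of roughly
55 × 42 × 34 mm buried ~80 mm; seminal roots descending steeply ~150 mm
long; creeping roots near-horizontal to oblique, ~180 mm; stolons ~120 mm;
root depths spanning roughly 30–250 mm, matching the published measured
depth range of about 28–210 mm).

One derived piece: the per-class **depth specs are computed from the growth
model itself**, by a fixed-seed Monte Carlo (800 virtual roots per class,
growth unit 2 mm) over the other truth specs. In a real survey, measured
depth is automatically consistent with the plant's own geometry; deriving
the synthetic depth spec the same way keeps the synthetic field internally
consistent, so that self-validation measures sampling noise rather than an
arbitrary mismatch between two independently chosen distributions.

`generate_measurements()` then emulates the survey (default 50 plants): per
plant, organ counts are drawn and recorded, then every parameter of every
organ instance is drawn and emitted as one CSV row. Measurement-error
emulation (protractor/caliper quantization) is deliberately not modeled.

What passing tests on this synthetic field do and do not show: they
demonstrate that the fitting recovers the generating distributions at
survey scale (normal means within 0.5 sigma; empirical bin masses within
±0.12), and that the end-to-end simulate–measure–validate loop is
self-consistent (significant-or-better RRMSE in >= 90 % of seeded repeats
at n = 50). They do not certify agreement with any real potato variety —
that requires feeding real measurement tables through `build_database()`.

## Problem sizes and numerical choices

The bundled tests and the acceptance script run at the scale of the
original survey (50 plants, 20 seed repeats, 1e5 sampler draws, mesh
resolutions 16–32, growth unit 1–2 mm); a full suite run takes well under a
minute on one core. Tolerances: probabilities normalized to 1e-6; segment
isometry to 1e-9 relative; RRMSE oracle equivalence to 1e-12; mesh
degeneracy threshold 1e-12 mm². Degenerate inputs are handled explicitly:
zero-variance specs are point masses; a growth unit longer than the root
yields a single-step axis with a warning; a tuber tip radius of zero yields
a cone apex; `rD >= 1` (nonpositive stem top radius) is an error.

## Known limitations

* Statistical, not mechanistic: no soil interaction, no time evolution.
* Root depth is the sole validated output; angles, radii and counts are
  validated only indirectly through it.
* The empirical sampler cannot extrapolate beyond the fitted sample range.
* Synthetic truth configurations are placeholders for the unavailable
  variety tables; conclusions about real varieties require real data.
* Mesh export targets visualization and downstream meshing; the surfaces
  are closed but not guaranteed watertight under extreme self-intersection
  of strongly curved, thick roots.
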