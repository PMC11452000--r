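---
title: "The effective bandwidth of spatial smoothing splines: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The effective bandwidth of spatial smoothing splines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effbw)
```

## Why a bandwidth for splines?

Spatial confounding — an unmeasured, spatially varying factor that drives
both exposure and outcome — is the standing threat to regressions of
health outcomes on environmental exposures. The common defence is to add
unpenalized spatial splines `h_1(s), ..., h_J(s)` to the model, so that
exposure effects are estimated from variation *finer* than what the
splines absorb. But `J` is an abstract knob: 10 splines imply very
different spatial scales on Northern Ireland than on the contiguous United
States. The effective bandwidth translates `J` (equivalently, the basis
degrees of freedom, df) into a distance on the actual study geometry, so
that analysts can choose df by the spatial scale they intend to adjust
for, and can match smoothing scales across regions.

## The model and the statistic

All computations start from locations `s_1, ..., s_n` in a **planar
projected** coordinate system; every reported bandwidth is in the same
length unit as the input coordinates (kilometres throughout this
vignette). Geographic (longitude/latitude) input is rejected rather than
approximated.

The spline basis is the unpenalized thin-plate regression spline (TPRS)
family: from the pairwise distance matrix `D`, the radial matrix
`E_ij = η(D_ij)` with `η(r) = r² log r` (the 2-D second-order thin-plate
function; `η(0) = 0` fills the removable singularity) is eigendecomposed,
and the basis for df splines is

```
H = [1, x, y, u_1, ..., u_{df-2}]  ∈  R^{n × (df+1)}
```

where `u_j` are eigenvectors of `E`. The intercept and linear coordinates
are the thin-plate penalty's null space; the df count includes `x` and `y`
plus the `df − 2` eigen terms, so the hat matrix

```
S = H (HᵀH)⁻¹ Hᵀ
```

is a rank-(df+1) orthogonal projection: symmetric, idempotent, with
`trace(S) = df + 1` and unit row sums. Column `S[, i]` is location `i`'s
*equivalent kernel* — the weight it places on every location when the
splines smooth the data.

The **effective bandwidth** at a given df is computed per location and
then summarised:

* `k̂_i` = the smallest distance `D[j, i]` at which `S[j, i] < 0` — where
  the kernel first changes sign;
* `k̂` = median of the `k̂_i` (mean of the central pair for even counts).

This is a *minimum* smoothing radius. The original formulation of the
statistic instead fits, per location, a loess curve of `S[, i]` against
`D[, i]`, predicts weights on a common distance grid, and takes the first
zero crossing of the across-location median prediction — an *average*
radius that requires a span choice and typically sits above the
minimum-radius value. Both are provided (`effective_bandwidth()`,
`loess_effective_bandwidth()`); comparisons across studies should fix one
variant.

## Parameters that matter

* **`max_df`** (sweep upper end): the basis is nested — the first `j + 1`
  columns of `H` span the `j`-df basis — so `bandwidth_sweep()` pays for
  one eigendecomposition regardless of how many df it reports. df must
  stay below the number of points; at `df + 1 = n` the smoother is the
  identity, has no negative weights, and the bandwidth is refused rather
  than fabricated.
* **`span`** (loess variant only): fraction of points in each local fit,
  `0 < span ≤ 1`. There is no default on purpose — span sensitivity is the
  reason the minimum-radius variant exists. Each local fit is quadratic
  with tricube weights (`stats::loess`, `degree = 2`), predictions are
  taken on `n_eval = 1000` evenly spaced distances over `[0, max(D)]`
  with exact (direct-surface) evaluation so every location contributes at
  every evaluation distance. Spans so small that the local quadratic is
  rank-deficient are rejected with advice to enlarge.
* **`subsample_to` / `seed`**: for large point sets the n × n
  eigendecomposition dominates; a uniform, seeded subsample (drawn once,
  *before* basis construction, and used for basis, smoother and median
  alike) caps the cost. Around 1000–5000 points is the practical range.
  The seed is mandatory whenever subsampling triggers and is echoed in
  every table and log, making subsampled results exactly reproducible.
* **Grid inputs**: `make_rect_grid(width, height, increment)` places
  points at integer multiples of `increment` from the origin;
  `grid_over_polygon()` anchors the grid at the polygon bounding box's
  lower-left corner and keeps points inside or **on** the boundary.
  Boundary inclusiveness is deliberate: dropping coastal grid points by
  floating-point jitter would make counts non-deterministic. A different
  anchoring convention shifts counts by up to one row/column of points —
  worth remembering when comparing point counts across tools.

## Numerical choices

* **Eigenvector retention is by descending |eigenvalue|** (`E` is
  indefinite), ties broken by original index. This is a real choice, not a
  nicety: other TPRS implementations (notably `mgcv`) truncate to a
  *different* eigenvector set, so bandwidths computed from different basis
  builders agree in pattern but not digit-for-digit. We document ours and
  keep it fixed.
* **Magnitude-ordering is discontinuous at magnitude ties.** When the
  retention boundary falls between two eigenvalues of near-equal
  magnitude — generic on highly symmetric grids, where opposite-signed or
  degenerate pairs abound — the retained span is not uniquely determined,
  and `build_tprs_basis()` warns (relative gap below `1e-10`). Property
  tests of rigid-motion invariance use irregular layouts for exactly this
  reason.
* **The projection is computed by Householder QR without column
  pivoting**, never by inverting `HᵀH`: the leading columns of the
  orthonormal factor then span the leading columns of `H`, which is what
  lets one QR serve every df in the sweep. (Pivoting QR variants silently
  reorder columns and break this nesting; the constructor guards against
  it.) Numerical rank is checked against a tolerance of `1e-10` times the
  largest singular value, and collinear or duplicated geometry is rejected
  with the offending columns named.
* **Strict negativity threshold**: a weight counts as negative only below
  `−1e-12`, so exact zeros perturbed by rounding cannot masquerade as sign
  changes.
* **Undefined locations**: a location whose kernel never goes negative
  contributes no `k̂_i`; it is excluded from the median and counted. If
  more than half the locations are undefined the bandwidth itself is
  reported as undefined (NA, with a warning); if all are, that is an
  error. Sweeps flag such df and continue.
* **No internal coordinate rescaling**: bandwidths are reported in input
  units, at the cost of numerical divergence from implementations that
  standardize covariates internally.

## Choosing df from a target bandwidth

`df_for_target_bandwidth()` returns the smallest df whose `k̂` is at or
below the target (boundary-inclusive). The inclusive-minimum rule is this
package's documented convention; since the df → k̂ profile is not strictly
monotone (below), "smallest qualifying df" and "df with k̂ closest to the
target" can differ by one or two df near the target.

## What the fixtures emulate — and what they don't

The built-in fixtures (`make_fixture_polygon()`: an L-shape, a notched
rectangle, a convex blob; plus rectangular and jittered grids) stand in
for projected country boundaries covered by regular analysis grids. They
reproduce the features that drive the statistic — bounded irregular
geometry, boundary points, re-entrant corners, holes — at sizes where
tests run in seconds (25 to ~900 points; the test suite's largest sweeps
use a 20 × 20 grid, and the acceptance script a ~740-point clipped grid).
They do **not** emulate real coastline complexity, thousands-of-points
scale, or the particular projections of real studies, so green tests here
certify the algorithmic contract, not any particular published number for
a real country. `scripts/replicate_countries.R` covers that last step
when externally prepared, projected boundaries are supplied.

## Empirical behaviour worth knowing

* **`k̂` falls with df overall, but not monotonically per df.** On a
  20 × 20 grid the profile decreases sharply to roughly df 14–16, then
  *rises* a few km around df 20 before settling. Over the coarse df grids
  used in reporting (5, 10, 25, 100) the decrease is clean. The wiggles
  are genuine: the minimum-radius scan latches onto the first negative dip
  of an oscillating kernel, and the dip's location moves in steps as
  eigenvectors enter the basis.
* **The loess variant bounds the minimum-radius variant from above** on
  realistic layouts (verified at spans 0.1 and 0.5 across df on regular
  and irregular fixtures), with the gap narrowing as df grows. On tiny
  symmetric grids (5 × 5, 7 × 7) the ordering can invert at isolated df —
  the loess curve averages away the ringing that the minimum-radius scan
  reacts to — so comparisons of the two variants on toy geometries should
  not be over-read.
* **Rigid motions** (rotation + translation) leave every smoother and
  bandwidth unchanged to ~1e-13, as they must: `E` depends only on
  distances and the null space is closed under affine maps.

## Known limitations

* No reprojection: coordinates must arrive projected; results on
  unprojected degrees would be meaningless and are refused only when
  detectably geographic (country replication) — garbage planar input is
  otherwise the caller's responsibility.
* The full eigendecomposition is O(n³): beyond ~5000 points, subsample.
* Only the TPRS basis is implemented; other spline families (e.g. Duchon
  splines) yield smaller bandwidths at low df and are out of scope.
* Exact numerical agreement with other TPRS implementations is not
  promised (eigenvector-selection and standardization differences above);
  agreement is in behaviour and scale, and all cross-tool comparisons
  should hold the basis builder fixed.
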