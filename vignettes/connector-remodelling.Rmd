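---
title: "Connector detection and area-constrained remodelling of fixed partial dentures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connector detection and area-constrained remodelling of fixed partial dentures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`fpdconnect` edits the connectors — the narrow necks joining adjacent
units — of an n-unit fixed partial denture (FPD) given nothing but its
closed surface mesh.  The pipeline is purely geometric: frame the
prosthesis, find the necks, then deform the mesh locally until each neck's
cross-sectional area matches a prescribed value.  Everything downstream of
the STL (slicing, bounding boxes, deformation, root finding) is
deterministic, so a given input and configuration always reproduces the
same output mesh.

All coordinates are interpreted in millimetres.  STL itself is unitless;
the CLI help states this assumption explicitly, and the `qc` subcommand
warns when two meshes differ in extent by a factor near 25.4 (a common
inch/mm confusion).

### Anatomical framing

The smallest oriented bounding box is found approximately: the vertex set
is reduced to a deterministic extreme-point subset (support points of a
600-direction golden-spiral fan), principal axes seed a coordinate-descent
rotation search (1° scan per axis, refined geometrically to below 1e-4°),
and the final extents are measured against the full vertex set so every
vertex is inside the box.  An exact minimum-volume box is unnecessary:
the box's role is to *orient* the algorithm, not to be minimal, and on
prosthesis-like shapes the volume minimum is sharp enough that the search
reproduces the same frame after arbitrary rigid motion to well below the
slice spacing.

A box cannot know which face is occlusal.  Labels come from hint vectors
(defaults: occlusal = +Z, mesial = +X, buccal = +Y, the common scan
convention): the axis of largest extent is mesial–distal, the remaining
axis most aligned with the occlusal hint is occlusal–gingival, the last is
lingual–buccal.  Two mid-planes derive from the box: `E_mid` (normal =
occlusal axis) and `E_mid2` (normal = buccal axis).

### Detection

300 planes, equally spaced along the mesial–distal mid axis with a
half-spacing margin at each end, slice the mesh.  Each intersection curve
set is bounded by a rectangle with sides parallel to the box axes; `E_mid`
clips that one rectangle into an occlusal and a gingival sub-rectangle
(so their areas always sum to the full rectangle).  Connectors appear as
local minima of the two area series.  Minima are detected separately per
side — connectors may be oblique, with occlusal and gingival waists at
different stations — and paired by nearest slice index.

Detection parameters, all exposed with these defaults:

| parameter        | default | units  | role |
|------------------|---------|--------|------|
| `n_planes`       | 300     | —      | slicing resolution (~0.1 mm on a 32.5 mm bridge) |
| `smooth_window`  | 5       | slices | centred moving average before minima detection |
| `prominence`     | 0.05    | fraction of series range | rejects shallow dips (grooves, scan ripple) |
| `pairing_window` | 15      | slices | maximum occlusal/gingival index separation |

The prominence filter also applies an absolute floor (1e-9 mm², scaled to
the series) so a perfectly cylindrical "bridge" with a numerically flat
area series yields zero connectors rather than float-noise minima.  On
necks with genuinely flat bottoms (e.g. a cylindrical waist) the paired
minima can legitimately sit a few slices apart inside the plateau; the
resulting connector plane obliquity is a fraction of a degree per slice
and harmless, since any plane inside the plateau is an equally valid
reference section.

Each pair defines a connector site: `L_o`, the occlusal edge of the
occlusal rectangle at the occlusal minimum; `L_g`, the gingival edge at
the gingival minimum; the connector mid-plane through both edges; and a
right-handed local frame with origin at the intersection of the three
planes, x toward occlusal, y along buccal, z = x × y (the mid-plane
normal).  The initial area `A0` is the shoelace area of the section loop
in that plane.

### Remodelling law

Vertices strictly closer than `w` to the connector mid-plane (default
`w` = 1 mm) are selected and split by local coordinate sign into
occlusal (x > 0), gingival (x < 0), buccal (y > 0) and lingual (y < 0)
subsets.  The occlusal law is

$$x_{new} = x - k \, d_{yz} \, B(d_{xy}) \, x, \qquad
  d_{yz} = |x|, \quad d_{xy} = |z|,$$

$$B(t) = (w-t)^3 w + 3t(w-t)^2 \cdot 0.9w + 3t^2(w-t) \cdot 0.1w ,$$

i.e. a relative shrink toward the occluso-gingival mid-plane, weighted by
a strictly decreasing cubic Bézier-type falloff with control values
(1, 0.9, 0.1, 0)·w⁴: full effect on the connector plane, exactly zero at
distance `w`, so the deformation is C⁰-matched to the untouched surface
and visually smooth.  The gingival law is the same formula restricted to
x < 0 (the |x| factor makes it sign-symmetric); lingual/buccal exchange
the roles of x and y; `iso` applies all four with one shared k.  Because
only coordinate magnitudes shrink, the y and z coordinates of every
vertex (and all vertices beyond `w`) are bit-identical across an
occlusal/gingival adjustment, which the test suite asserts literally.

**Fold-over guard.**  The in-slice map $x \mapsto x(1 - k\,|x|\,B)$ is
injective only while its derivative $1 - 2k|x|B$ stays positive.  The
package therefore bounds $k \le k_{max} = 0.99 \, / \, (2\,\max d\,B)$
over the addressed vertices.  (Merely keeping the shrink *factor*
positive is not sufficient: beyond the injectivity bound the section
folds onto itself and the measured area is no longer monotone — easy to
demonstrate on a cylindrical fixture.)  Within the guard the mapped
region nests monotonically in k, so the section area is strictly
non-increasing, which makes the solve below well posed.  Practically,
10–20 % reductions use k an order of magnitude below the guard.

### Solving for k

The target is either an absolute area or a fraction of `A0` (resolved
once, at specification time).  Since area is monotone in k, k is found by
deterministic bisection on $[0, k_{max}]$, stopping when
$|A_2 - A_{input}| \le$ 0.001 mm² (the tolerance is a parameter; 0.001 mm²
is the default contract).  A stochastic/evolutionary optimiser would add
nothing here: the objective is scalar, monotone and cheap.  Two
conventions matter and are fixed deliberately:

* the area is always measured at the connector's *original* mid-plane —
  the post-deformation minimal section may migrate slightly, but
  re-detecting it during the solve would make the objective
  discontinuous;
* each evaluation starts from the original coordinates (the law is
  parametric in k, not incremental), so the solve has no path dependence.

Reported per adjustment: k, initial and final area, iteration count,
achieved |ΔA|, displaced vertex count.  Unreachable targets (below the
area at `k_max`) abort with the minimum achievable area in the message;
in CLI sweeps such cells become error rows without stopping the sweep.

### Cross-section kernel

Mesh/plane intersection collects one segment per crossing triangle
(vertices exactly on the plane are nudged by 1e-9 mm so crossings are
well defined), then chains segments into closed loops by endpoint
matching on a hashed 1e-6 mm rounding grid with neighbour-cell fallback —
robust even when a plane passes exactly through a vertex ring, which is
common on lathe-like meshes.  Degenerate segments are dropped; open
chains indicate a non-watertight mesh and are discarded with a warning.
Loops are cleaned (consecutive duplicates at 1e-7 mm, collinear points at
1e-9 mm), normalised counter-clockwise, and measured by the shoelace
formula; metrics add the centroid, chart-axis extents ("height" =
occluso-gingival, "length" = bucco-lingual — the package's reading of the
usual clinical descriptors) and principal second moments from the
standard polygon moment formulas.  The user-facing `polygon_area`
verifies simplicity (O(n²) segment test) before measuring; the solver's
inner loop uses the unchecked shoelace for speed.

### Remeshing and QC

Scanned STLs often need a uniform vertex distribution before slicing.
`remesh_uniform` is an incremental isotropic remesher: split edges above
4/3 of the target length, collapse below 4/5 (with link-condition and
long-edge guards), flip toward valence 6, tangentially relax and
back-project every vertex onto the *input* surface.  The target length is
re-aimed between passes, so the final count lands within 20 % of the
request (default 120 000 triangles ≈ 60 000 quads split in two).  Quality
control is a sampled symmetric Hausdorff distance: area-weighted uniform
surface samples (default 100 000 per side, seed recorded in the report),
exact point-to-triangle distances via a compiled uniform-grid kernel,
max and pooled mean reported.  Back-projection keeps remeshed vertices on
the source surface, so the deviation is the chord error of the new
triangulation — about l²/8 times the local curvature.

### Synthetic prostheses and what the tests show

No scanned FPD ships with the package.  The generator instead sweeps a
superellipse cross-section along the mesial–distal axis: wide, tall
sections at the crowns (exponent 3, a squarish occlusal table), narrow
oval sections at the necks, blended by a C¹ smoothstep with a plateau
fraction (default 0.3) that keeps crowns full and necks sharply defined.
Because the smoothstep has zero slope at its ends, each neck is a true
local waist *exactly* at its construction station.  The neck superellipse
exponent is solved (via the Gamma-function area formula) so the section
area equals the requested connector area exactly; defaults emulate a
4-unit posterior bridge: 32.5 × 11.7 × 9.0 mm overall, neck
heights 5.7/5.7/5.8 mm, lengths 6.8/6.0/6.8 mm, areas
33.1/28.5/33.2 mm².  Meshing uses a 0.15 mm pitch by default
(≈ 95 000 triangles); optional seeded vertex jitter emulates scan noise,
and jitter 0 makes generation bit-reproducible.  Dumbbell (two spheres
plus a cylindrical neck) and capped-cylinder fixtures are surfaces of
revolution with closed-form section areas.

An implicit-surface + marching-cubes construction was considered and
rejected: the swept-profile construction is watertight by construction,
cheaper, and — decisive for testing — its ground truth (neck station,
height, length, area) is exact rather than estimated from a voxelised
field.

These fixtures emulate the *geometry class* of a bridge: a straight long
axis, pronounced necks, oval sections.  They do not have cusps, fissures,
margin lines, or correlated scan artifacts.  Passing tests therefore
demonstrate the algorithmic contract (framing, detection, area matching,
locality, determinism) — not robustness to every clinical scan; on real
scans the detection parameters (smoothing, prominence) are the knobs to
revisit.

### Numerical choices

* vertex merge on read: 1e-6 mm; facet normals recomputed from winding on
  write; binary STL is float32, so a write/read round trip is faithful to
  ~1e-7 relative.
* plane nudge for on-plane vertices: 1e-9 mm; loop endpoint matching:
  1e-6 mm grid with neighbour-cell fallback.
* bisection: max 200 iterations (the tolerance is always reached long
  before; typical solves take 8–15).
* degenerate inputs fail loudly: flat/linear geometry (no box), empty
  meshes, empty point selections, targets above `A0` or below the
  reachable minimum.

### Problem sizes used by the test-suite

Unit tests run the generators at 0.25–0.4 mm pitch (3 000–30 000
triangles) so the whole suite stays interactive; the acceptance tests run
the full default study — the 0.15 mm-pitch 4-unit FPD, 300 slicing
planes, and the complete 3-connector × 5-direction × 2-level adjustment
grid at the 0.001 mm² tolerance — plus a 20-spec seeded detection-recovery
sweep at 0.25 mm pitch.  These sizes are the package's chosen test scale;
all algorithms are resolution-independent.

### Known limitations

* Straight mid-axis assumption (posterior segments); curved full arches
  would need a curved station parameterisation.
* Labeling depends on orientation hints; with a wildly mis-oriented scan
  the occlusal/gingival split — and hence detection — degrades.
* The remodelling law never adds material (k ≥ 0), and smoothing/fairing
  of the deformed region beyond the built-in falloff is out of scope.
* Section second moments are geometric descriptors, not stress
  surrogates.
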