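# fpdconnect

Automated connector detection and remodelling for fixed partial denture
(FPD) surface meshes.

## The problem

A fixed partial denture (a multi-unit dental bridge) is joined by narrow
**connectors** between adjacent crown/pontic units, and these necks are the
mechanically critical regions of the prosthesis: their cross-sectional area
and the side from which material is removed (for aesthetics or soft-tissue
clearance) strongly influence the stresses the bridge sees in service.
Studying "the same bridge with a 10 % smaller middle connector, thinned
from the gingival side" requires editing a scanned triangle mesh in a
controlled, parametric and reproducible way — something interactive CAD
does poorly.

`fpdconnect` takes a watertight STL of an n-unit FPD (units: mm) and

1. **frames** it in a labeled minimum-volume oriented bounding box
   (mesial–distal / occlusal–gingival / lingual–buccal axes from
   user-supplied orientation hints),
2. **detects the connectors** automatically: 300 equally spaced planes
   perpendicular to the long axis slice the mesh; each intersection curve
   is bounded by a box-aligned rectangle that the occluso-gingival
   mid-plane splits into an occlusal and a gingival part; the paired local
   minima of the two rectangle-area series mark the connector necks
   (computed separately per side, so oblique connectors are allowed),
3. **remodels** any connector to a prescribed cross-sectional area from a
   chosen direction — `occlusal`, `gingival`, `lingual`, `buccal`, or
   `iso` (all four at once) — and writes the adjusted STL.

The remodelling law moves only vertices within a falloff width `w`
(default 1 mm) of the connector mid-plane.  In the connector's local frame
(x toward occlusal, y toward buccal, z normal to the mid-plane) each
selected vertex moves toward the mid-axis:

```
x_new = x − k · d_yz · B(d_xy) · x,      d_yz = |x|,  d_xy = |z|
B(t)  = (w−t)³·w + 3t(w−t)²·0.9w + 3t²(w−t)·0.1w
```

`B` is a cubic Bézier-type falloff (Bernstein weights 1, 0.9, 0.1, 0
scaled by `w⁴`): full effect on the mid-plane, zero at distance `w`, so
the deformation blends smoothly into the untouched surface.  The scale
`k` is solved by bisection — the section area is monotone in `k` — until
the area measured at the original connector mid-plane matches the target
within ±0.001 mm².  A guard `k ≤ k_max` keeps the map injective so the
surface can never fold through itself.

The package also provides isotropic remeshing with sampled-Hausdorff
quality control, planar cross-section metrics (area, centroid, extents,
principal second moments), and a parametric synthetic-FPD generator with
exact connector ground truth for testing the whole pipeline without any
scan data.

## Worked example

```r
library(fpdconnect)

# a synthetic 4-unit FPD, 32.5 x 11.7 x 9.0 mm, three oval connector
# necks with construction areas 33.1 / 28.5 / 33.2 mm^2
gen <- generate_fpd(fpd_spec())
det <- detect_connectors(gen$mesh)
det
#> <connector_detection: 3 site(s)>
#> <connector_site 1: station 8.18 mm, A0 33.23 mm^2, obliquity 0.0 deg>
#> <connector_site 2: station 16.25 mm, A0 28.59 mm^2, obliquity 1.1 deg>
#> <connector_site 3: station 24.32 mm, A0 33.33 mm^2, obliquity 0.0 deg>

# shrink the middle connector 10 % from the gingival side
site <- det$sites[[2]]
adj <- adjust_connector(gen$mesh, site,
                        adjustment_spec(direction = "gingival",
                                        reduction = 0.1, a0 = site$a0))
adj$result
#> <adjustment_result: gingival, A 28.595 -> 25.735 mm^2 (target 25.735),
#>  k = 0.0811933, 9 iterations, |dA| = 0.00015 mm^2>

write_mesh(adj$mesh, "fpd_gin10.stl")
```

The detected stations sit at the constructed necks (8.125 / 16.25 /
24.375 mm) to within a slice spacing, and the initial areas `A0` are
within ~0.5 % of the construction targets; the solver reaches the
requested area to 1.5e-4 mm², well inside the 0.001 mm² stopping
tolerance.

## Command line

A thin Rscript front end (installed at `inst/cli/fpdconnect`) drives the
same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/fpdconnect", package="fpdconnect"))') \
    synth --preset fpd --output model
# detect -> adjust sweep: 3 connectors x {iso,gin,occ,lin,buc} x {10%,20%}
Rscript ... adjust --input model.stl --outdir out \
    --directions iso,gin,occ,lin,buc --reductions 0.1,0.2
Rscript ... qc --input out/adjusted_c2_gin_10.stl --reference model.stl --outdir out
```

Exit codes: 0 success, 2 input/parameter error, 3 no connectors found,
4 solver failure.  All geometry is interpreted in millimetres.

## Limitations

- The long axis is assumed straight (posterior bridge segments); full
  arches with strong curvature are out of scope.
- Anatomical face labels come from orientation hints (default occlusal =
  +Z, mesial = +X, buccal = +Y): a bounding box alone cannot name sides.
- Connector enlargement (k < 0) is not supported; the law only shrinks.
- No stress analysis: section properties are geometric descriptors only.
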