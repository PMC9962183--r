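# boneCSG

Cross-sectional geometry (CSG) analysis of long-bone diaphyses from
watertight surface meshes, aimed at quantifying how osteoporosis alters
femoral structure. The package takes femur-like bone models (STL) with three
anatomical landmarks, extracts evenly spaced diaphyseal cross-sections, and
computes the beam-theory quantities that skeletal biomechanics uses as
proxies for bending, torsional and compressive competence. A parametric
synthetic-bone generator with closed-form ground truth makes every stage of
the pipeline testable without CT data.

Intended users: researchers in musculoskeletal biomechanics, biological
anthropology and orthopaedic engineering who work with segmented bone
surface models.

## The quantities

For a cross-section with periosteal (outer) and endosteal (inner) contours,
the package reports, per section:

- areas: total area `TA`, medullary area `MA`, cortical area
  `CA = TA − MA` (shoelace formula on the extracted contours);
- perimeters of both contours and radial cortical thickness (min / mean /
  max over equiangular rays from the medullary centroid);
- second moments of area about the centroidal mediolateral (x) and
  anteroposterior (y) axes, `Ix = ∫y²dA`, `Iy = ∫x²dA`, `Ixy = ∫xy dA`,
  computed by exact Green's-theorem edge formulas on the contour polygons;
- principal moments `Imin, Imax = (Ix+Iy)/2 ∓ √(((Iy−Ix)/2)² + Ixy²)` and
  the principal-axis angle `θ = ½·atan2(2Ixy, Iy−Ix)`;
- polar moment `J = Ix + Iy`;
- section moduli `Zx = Ix/dy`, `Zy = Iy/dx`, `Zmin = Imin/dxθ`,
  `Zmax = Imax/dyθ`, `Zpol = J/rmax`, where `dx, dy` are maximum chord
  distances from the centroidal axes, `dxθ, dyθ` the same in the principal
  frame, and `rmax` the maximum radial distance to the periosteal contour.

Sampling follows the standard protocol: 60 evenly spaced sections between
20% (distal) and 80% (proximal) of *biomechanical length* (the mean
distance from the superior femoral neck point to the two distal condyle
points), with 21 equiangular semilandmarks per contour per section (1260
per contour surface per specimen). Meshes are cleaned, decimated to a
consistent complexity of 20,000 triangular faces, and oriented by their
landmarks before sectioning.

## Worked example

```r
library(boneCSG)

# a healthy femur-like synthetic bone (BL = 420 mm, elliptical annular
# cross-sections) -- generated oriented, with landmarks
spec <- synthetic_bone_spec()
bone <- generate_bone(spec)

# one mid-shaft cross-section with semilandmarks, then its properties
sec   <- sample_semilandmarks(slice_at_level(bone, 0.5))
props <- section_properties(sec)
```

Printed values (mm, mm², mm³, mm⁴):

```
TA 570.8  MA 219.4  CA 351.4
Ix 20526  Iy 23794  J 44320  theta -0.0000
Zx 1579   Zy 1700   Zpol 3166
thickness min/mean/max 4.94 5.12 5.32
```

`CA = 351.4 mm²` is the bone-tissue area of the section (the axial
compressive-strength proxy); the closed-form value for this spec is
`352.0 mm²`, i.e. the mesh pipeline is within 0.2% at this resolution.
`Ix < Iy` says the section resists mediolateral bending slightly more than
anteroposterior bending; `theta ≈ 0` confirms the principal axes are
anatomically aligned for this symmetric phantom.

A full two-group study from the command line:

```sh
Rscript -e 'boneCSG::run_cli()' simulate --out cohort --seed 7
Rscript -e 'boneCSG::run_cli()' process  --in cohort --out processed
Rscript -e 'boneCSG::run_cli()' compare  --in processed --out results
```

`simulate` writes STL + landmark sidecars plus the analytic truth table;
`process` runs clean → decimate → orient → section → measure per specimen
(failures isolated per specimen); `compare` writes per-location
healthy-vs-osteoporotic comparisons (Welch's t by default), ratio-of-means
summaries and significance flags.

## Layout

- `R/` — synthetic bone generator, STL/landmark I/O, mesh cleaning /
  decimation / orientation, sectioning and semilandmarks, section
  properties, cohort statistics, CLI.
- `src/` — quadric edge-collapse decimation, point-in-polygon kernel.
- `tests/testthat/` — unit, property and acceptance suites.
- `inst/extdata/data_dictionary.csv` — column/unit documentation for the
  properties CSV.
- `vignettes/diaphyseal-csg.Rmd` — methods notes: model, conventions,
  numerical choices, limitations.
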