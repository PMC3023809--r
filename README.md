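# atlaskit

Scriptable digital-atlas workflows for volumetric image data: one R package
covering the gather → align → compare loop that atlas-based analysis keeps
repeating.

A digital atlas is a reference volume whose voxels carry integer label ids,
plus one or more *label sets* — single-parent hierarchies mapping each id to
a name, an abbreviation and a color. The same voxel may mean different
things in different contexts (an anatomic name, a functional role), so an
atlas here carries several label layers over one grid and always reports the
*active* layer first. Around that data model the package provides:

- **Volume IO** — NIfTI-1 (`.nii`/`.nii.gz`) and Analyze 7.5 (`.hdr`/`.img`)
  read/write with exact round-trips, orthogonal slice extraction, axis
  reorientation, and voxel ↔ world coordinate conversion under the
  voxel-center convention `xyz = origin + (ijk − 1) ⊙ voxelSize`.
- **Out-of-core streaming** — volumes too large for memory are read plane by
  plane from disk under a byte-bounded, slice-granular LRU cache; every read
  is bit-identical to an in-memory load.
- **Label hierarchies** — an XML "ILF" dialect and OBO 1.2 parsing (is_a
  graphs reduced to trees), inclusive descendant queries, case-insensitive
  text search over names and abbreviations, and two deterministic graph
  layouts: radial (generation *g* on the circle of radius *g·spacing*) and
  linear (x = depth·spacing, parents centered on their children).
- **Atlas semantics** — per-voxel multi-layer label lookup, double-click
  style selection toggling, subtree selection (selecting a parent selects
  all substructures), region masks, background masking, and colored overlay
  rendering with user-controlled opacity.
- **Synchronized views** — an event bus with echo suppression keeps the
  atlas selection and the ontology-graph highlight set identical from either
  direction, and forwards selected structure names or world coordinates to
  the search workspace.
- **Layer compositing** — transformable (scale → rotate → pan), adjustable
  (brightness β, contrast γ about mid-gray: `clamp(γ(v−½)+½+β)`), LUT-mapped
  layers blended bottom-to-top with the straight-alpha over operator;
  master/slave linked groups; dual-view juxtaposition; reproducible scene
  files.
- **Landmark registration** — closed-form rigid (SVD of the centered
  cross-covariance) and affine least squares, and thin-plate splines with
  kernel U(r) = r² log r² solved by the standard bordered system (λ = 0
  interpolates exactly; large λ tends to the affine fit), behind a pluggable
  backend registry (`landmark_warp` built in).
- **Federated search** — one query fanned out to pluggable data sources,
  each receiving only the search types it declares; per-source failures stay
  isolated; results grouped by (source, data type) with sortable,
  hideable, reorderable annotation columns and a global cart.
- **Synthetic fixtures** — deterministic generators (nested-box atlases,
  warped image pairs with exact landmark correspondences, mock source
  registries, large on-disk ramp volumes) so everything builds and tests
  offline.

## Worked example

```r
library(atlaskit)

spec  <- fixtureSpec(seed = 4, volumeShape = c(16, 16, 16),
                     nStructures = 7, hierarchyDepth = 3)
atlas <- makeAtlas(spec)
atlas
#> Atlas 16x16x16: 2 label layer(s) [anatomic, functional], active 1, with reference

labelsAt(atlas, c(8, 8, 8))
#>      setName id abbrev              name   r   g  b
#> 1   anatomic  2    S02      structure 02 255 229 77
#> 2 functional  2     FA functional zone A 255 128  0
```

The voxel (8,8,8) lies inside structure 2 of the anatomic hierarchy and
zone A of the functional one; the anatomic entry is listed first because
layer 1 is active. Selecting the root selects every substructure:

```r
state <- selectSubtree(selectionState(atlas), atlas, 1, 1)
selectedIds(state, 1)
#> [1] 1 2 3 4 5 6 7
```

Registering a synthetically warped image back onto its template with a
thin-plate spline brings the landmark residual to machine precision:

```r
pair <- makeWarpedPair(fixtureSpec(seed = 6), "tps", magnitude = 2)
reg  <- registerImages(pair$source, pair$template, pair$landmarks, "tps")
reg$residual
#> [1] 4.431012e-15
```

A command-line surface over the same functions lives in
`inst/exec/atlaskit`:

```sh
Rscript inst/exec/atlaskit atlas labels-at --atlas synthetic.atlas --ijk 8,8,8 --json
Rscript inst/exec/atlaskit register run --source src.png --template tpl.png \
    --landmarks lms.txt --model tps
```

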