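---
title: "Models and conventions behind atlaskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind atlaskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlaskit)
```

atlaskit implements the recurring loop of atlas-based image analysis —
gather data, align it to a common space, compare it in that space — as a
GUI-free library. This vignette records the models the package implements,
the conventions it fixes where several were defensible, and what its tests
do and do not establish.

## The atlas data model

An `Atlas` is a reference `ImageVolume` plus an ordered list of
`LabelLayer`s on the same voxel grid. Each layer pairs an integer label
volume (0 = background) with a `LabelSet`, a single-parent hierarchy
mapping ids to names, abbreviations and RGB colors. Carrying *several*
layers is the point: one location can have an anatomic name in one context
and a functional role in another, and a single shared id array cannot
encode two independent partitions of the same grid. Label lookups
(`labelsAt`) therefore return one entry per layer, active layer first.

Two conventions are fixed here because every caller must agree on them:

- **Background is id 0.** No file format we read declares a background
  convention, so the package picks the one integer that every labeling
  scheme leaves unused.
- **Empty selection means "show all".** An atlas opened before any
  interaction displays its delineations; the selection filter only becomes
  restrictive once something is selected. `renderLabelOverlay` colors a
  pixel when its id is nonzero and either nothing is selected or the id
  lies in (or below) a selected node.

A label id present in a volume but absent from its hierarchy is reported in
`atlasNotes()` rather than refused: real label volumes drift out of sync
with their hierarchies, and a viewer that refuses to load them is less
useful than one that warns.

## Coordinates, slices, and orientation

Voxel indices are 1-based, following R and every container in its
ecosystem; world coordinates use the voxel-center convention
`xyz = origin + (ijk − 1) ⊙ voxelSize`, and `worldToVoxel` rounds to the
nearest voxel, flagging out-of-grid results instead of erroring so probes
can run along world-space lines. Slices are indexed per array axis with no
anatomical relabeling — orientation codes are carried as metadata
(`axisLabels`) and permuted by `reorientVolume`, but the package does not
interpret them.

Slice intensities are normalized by the *volume's* global value range, not
per slice. Per-slice normalization would make cine stepping flicker as the
plane's local range changes; a global range keeps a given tissue intensity
at a fixed gray level across the whole sweep. NIfTI orientation is honored
only through the diagonal/permutation part of the stored affine; fully
oblique acquisitions would need resampling, which is out of scope, and the
metadata is preserved on read so nothing is silently lost.

## Out-of-core volumes

`openLargeVolume` streams a volume plane-by-plane along the file's
fastest-varying plane (fixed third index, which is contiguous on disk in
column-major layout) under a byte-bounded LRU cache. Whole-plane
granularity is the simplest contract that makes the two guarantees easy to
state and test: reads are bit-identical to an in-memory load, and resident
bytes never exceed the budget. The cache keeps hit/read counters
(`cacheStats`) precisely so tests can compare against a reference LRU
simulation rather than trusting the implementation's own bookkeeping. The
`.lhdr` descriptor is a small YAML text header (dtype, dims, data file,
geometry, value range); the stored value range lets display normalization
avoid a full scan of a file that may not fit in memory.

## Hierarchies, ILF and OBO

No grammar for the ILF hierarchy format is published, so the package
defines a documented XML dialect: a `labelset` root with nested `label`
elements (`id`, `abbrev`, `name`, `color="R,G,B"`), nesting encoding
parentage and document order encoding sibling order. `labelSet()`
normalizes node tables to depth-first pre-order, which makes write → parse
an identity on content regardless of input row order.

OBO 1.2 `is_a` graphs may be DAGs; the layouts and the selection semantics
need a tree. A term with several parents keeps the lexically first one and
the dropped edges are recorded as notes on the result — visible, not
silent. Cycles are an error naming one offending chain. Term ids map to
integer label ids through optional `id-mapping:` header lines or
sequentially in file order.

`descendants` is inclusive of the query node, matching selection semantics:
selecting a parent structure selects the structure itself along with its
substructures. Text search is case-insensitive plain substring over
abbreviation and name — the simplest matching rule; regular expressions
would make common neuroanatomical abbreviations ("CA1", "S1") behave
surprisingly.

In the radial layout, children divide their parent's angular sector
proportionally to leaf counts (ties broken by file order) and sit at sector
midpoints; radius is exactly depth × spacing. In the linear layout leaves
receive consecutive integer y in DFS order and internal nodes the mean of
their children's y. Both are pure functions of the tree, so layouts are
reproducible across runs.

## Events and synchronization

The atlas view, the graph view and the search outbox communicate over a
synchronous FIFO event bus. Two design points matter. Delivery is
queue-based, so a handler that publishes during dispatch appends rather
than recursing. And an event identical to one currently in flight is
suppressed — without this, "atlas highlights graph" and "graph highlights
atlas" echo forever. Handler errors are caught and logged so one faulty
subscriber cannot block the rest. Selection events carry resolved id sets
(a graph click expands to the whole subtree before publishing), which is
what makes the bidirectional invariant — atlas selection equals graph
highlights at quiescence — hold by construction and testable over random
event sequences.

## Compositing

Layers composite bottom-to-top with the straight-alpha over operator; the
accumulator is premultiplied internally, which makes the operator exactly
associative and lets a flattened sub-stack be reused as a layer. Per layer,
the transform order is fixed as scale, then rotation about the image
center, then pan; the order had to be fixed somewhere, and this matches how
interactive viewers behave (rotating a panned layer spins it in place
rather than orbiting the canvas). Resampling is inverse-mapped bilinear
with transparent out-of-bounds — deterministic, smooth, and exact at
integer offsets, so an untransformed same-size layer reproduces its pixels
bit-for-bit.

Photometry uses a mid-gray pivot, `clamp(γ(v − ½) + ½ + β, 0, 1)`, chosen
so the neutral setting (β = 0, γ = 1) is the identity and contrast does not
drag the image toward black. LUTs are 256-entry tables indexed by
`round(v·255)`. Cine stepping clamps at the ends rather than wrapping:
predictable boundary behavior, and a forward sweep followed by a backward
sweep returns to the start. In linked groups, only deltas applied to the
master propagate (identically, to every member, preserving pairwise
relative transforms); slave-initiated deltas stay local. "Zoom" is a
canvas-level uniform scale distinct from per-layer scale, so a user can
zoom a comparison without disturbing the layers' relative geometry.

## Landmark registration

Landmarks are (source, template) point pairs; fitted models map source
coordinates to template coordinates.

- **Rigid**: the rotation is the SVD solution on the centered
  cross-covariance with the reflection corrected to determinant +1; the
  translation maps centroid to centroid. Closed form, no iteration.
- **Affine**: ordinary least squares on the 2×3 matrix; exact on
  affine-generated data, rank-checked against collinear sources.
- **Thin-plate spline**: kernel U(r) = r² log r² with U(0) = 0, solved by
  the dense bordered system `[[K + λI, P], [Pᵀ, 0]]`. The side conditions
  (kernel weights orthogonal to constants and coordinates) hold by
  construction; λ = 0 interpolates the landmarks exactly, and growing λ
  shrinks the kernel part toward the least-squares affine. TPS is used as
  the canonical landmark spline; the landmarks are desk-scale (tens), so a
  direct dense solve is appropriate and no subsampling is done.

Resampling evaluates the map from template grid back to source. For linear
models that inverse is analytic; a TPS warp has no closed-form inverse, so
`registerImages` fits the reverse-direction spline for resampling while
reporting the forward fit's residual and parameters for provenance. 2D-to-3D
alignment is realized as slice selection (`extractSlice`) followed by
2D-2D registration — no volumetric pose search is attempted. Arbitrary
registration algorithms plug in through a name-keyed backend registry whose
contract is only (source, template, options) → (model, aligned image);
failures inside a backend surface as backend errors naming the backend and
leave the registry untouched.

## Federated search

A query holds keywords, field-targeted terms, and the selected source
names. Each source declares which of the two search types it supports and
receives only those parts; a source given nothing it understands is skipped
with an explicit status rather than queried incorrectly. Multi-keyword
matching is AND across keywords, case-insensitive — the reading that makes
adding a term always narrow the result set. Per-source failures become a
`failed` status without touching other groups, and the final table is a
deterministic function of the per-source result sets (groups sorted by
source then data type), so concurrent execution would not change the
output. View operations on the grouped tables (sort, hide, reorder,
expand/collapse) never alter record content; sorts are stable with missing
values last. The cart is a FIFO container with flagged duplicates,
serializable to JSON so separate CLI invocations can share it. Live
adapters for 2010-era web services are deliberately absent; the
source-provider interface plus the directory, table and mock literature
sources carry the architecture and keep everything testable offline.

## Synthetic fixtures and what the tests show

The generators are pure functions of a `fixtureSpec` (seed, volume shape,
structure count, hierarchy depth, noise level), threading one seed through
fixed per-generator offsets. The synthetic atlas uses nested axis-aligned
*boxes* mirroring a random tree — boxes, not spheres, because box voxel
counts and extents have exact closed forms, which turns geometric
containment and mask tests into exact assertions. Warped image pairs are
built template-first: the source is the template pushed through a known
transform, and the landmark pairs are exact correspondences, so the fits'
recovery can be asserted to numerical precision rather than "close".

Test and oracle problem sizes are desk-scale by design: exhaustive
per-voxel oracles on 16³ atlases, 64³ streamed volumes, 200 random event
sequences, 100 random transforms, 50 random trees. These establish that the
implementations match their specifications exactly on inputs where
brute-force verification is possible. They do not exercise anisotropic
clinical-resolution volumes, real ontologies with tens of thousands of
terms, oblique acquisitions, or noisy manually-placed landmarks; on real
data the numerical guarantees carry over, but performance characteristics
and format corner cases (vendor-specific NIfTI extensions, nonstandard
Analyze headers) do not.

## Numerical choices and degenerate inputs

- Volume round-trips store integers as int32 and floats as float64 in both
  NIfTI and Analyze, so write → read is exact rather than rounded through
  float32.
- Identical source landmarks make the TPS system singular and are rejected
  as such; collinear sources fail the affine rank check; coincident source
  points fail rigid fitting with a degeneracy error.
- A degenerate intensity range (constant volume) normalizes to zero instead
  of dividing by zero.
- The out-of-core cache refuses budgets below one slice at open time; a
  budget of exactly one slice works and simply evicts on every miss.
- Angular sector ties in the radial layout and sort ties in result tables
  break by input order, keeping both deterministic.

## Known limitations

DICOM, oblique slice views and volume rendering are out of scope, as are
probabilistic (fractional) label values — ids are integers. Hierarchy
editing is not provided; hierarchies are parsed, traversed and laid out,
not modified. Remote execution and live web-service adapters are
represented only by the registry interfaces they would plug into. The CLI
is a thin delegation layer over the exported functions; anything it can do,
the library can do directly, and the tests enforce that equivalence by
comparing CLI output against library calls.
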