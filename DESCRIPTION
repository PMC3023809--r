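Package: atlaskit
Title: Digital Atlas Workflows: Volumes, Label Hierarchies, Compositing,
    Landmark Registration and Federated Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A scriptable toolkit for digital-atlas analysis of volumetric
    image data. Reads and writes NIfTI-1 and Analyze 7.5 volumes and common
    2D image formats, extracts orthogonal slices, and streams large volumes
    from disk under a bounded slice cache. Models atlases as a reference
    volume plus one or more label layers, each pairing an integer label
    volume with a hierarchical label set (ILF-dialect XML or OBO), with
    label lookup, subtree selection, background masking, colored overlay
    rendering, and an event bus that keeps atlas selection and ontology
    graph highlights synchronized. Provides a layer compositor with
    per-layer transforms, photometric adjustment, color lookup tables,
    linked layer groups and dual-view juxtaposition; landmark-based rigid,
    affine and thin-plate-spline 2D registration behind a pluggable backend
    registry; a federated search engine that fans a single query out to
    pluggable data sources and merges results into grouped annotation
    tables with a shared cart; deterministic synthetic-fixture generators;
    and a command-line interface over the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    RNifti,
    oro.nifti,
    png,
    tiff,
    jpeg,
    xml2,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'hierarchy.R'
    'volume-io.R'
    'atlas.R'
    'atlaskit-package.R'
    'large-volume.R'
    'search.R'
    'image2d.R'
    'registration.R'
    'fixtures.R'
    'compositor.R'
    'cli.R'
    'conditions.R'
    'events.R'
    'zzz.R'
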