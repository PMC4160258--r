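Package: trackfig
Title: Multi-Region, Multi-Track, Multi-Scale Figures of Genetic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Composes publication-ready figures that stack heterogeneous
    genetic data tracks (regional association scatter plots with LD
    colouring and recombination overlay, interval intensity, chromatin-state
    segmentations, Hi-C interaction arches and link blocks, binned contact
    heat maps, gene models and manual annotations) across several genomic
    regions drawn at exactly the same base-pairs-per-unit scale, even when
    the regions lie megabases apart or on different chromosomes.  An
    optional zoom panel magnifies a sub-region and is joined to its parent
    by a connector.  Figures carry a title, per-track reference letters and
    an auto-generated legend, and are written as vector PDF and raster PNG.
    A seeded fixture generator produces a complete synthetic input set so
    the whole pipeline runs without external downloads, and a thin
    command-line driver builds figures from a plain-text configuration
    file.
License: GPL-3
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
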