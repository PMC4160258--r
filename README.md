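# trackfig

Publication-ready figures of heterogeneous genetic data, stacked as tracks
across multiple genomic regions drawn at **exactly the same scale** — even
when the regions lie megabases apart or on different chromosomes — with an
optional zoomed sub-region panel linked back to its parent, auto-generated
legends, track reference letters and vector PDF / raster PNG output.

## Who this is for

Researchers integrating regional GWAS association signals with functional
annotation: chromatin-state segmentations, Hi-C interactions and contact
matrices, interval intensities, gene models and manual highlights. Genome
browsers are built for interactive exploration; `trackfig` is built for the
final, composed figure, with every track aligned to the base pair and no
image editing afterwards.

## The model at the core

All horizontal placement goes through one mapping of the plotted regions
onto the abstract canvas interval [0, 1]. For regions
*r₁ … rₙ* with genomic widths *wᵢ* (bp) and a fixed inter-region gap *g*
(canvas units), each region receives a canvas segment of width

    xᵢ = wᵢ / B,   with  B = (Σ wᵢ) / (1 − g·(n − 1))   bp per canvas unit,

so every region is drawn at the identical scale *B*; the relative deviation
across regions is below 10⁻⁹ by construction. A position *p* in region *i*
maps to `x0ᵢ + (p − startᵢ)/B`, and every renderer — association scatter,
intensity, segmentation, arches, links, heat map, genes, annotations —
places its glyphs through this one function, which is what guarantees
single-base-pair cross-track alignment. A zoom panel is simply a second,
single-region map over the target sub-region (its bp-per-unit is smaller,
i.e. magnified), joined to the main panel by a connector trapezoid whose
upper corners are exactly the canvas images of the target's endpoints.

Track encodings follow field conventions: association points at
−log10 *p*, coloured by r² bin to the index SNP with a recombination-rate
overlay on a secondary axis (the SNAP-plot convention); interaction arches
whose apex height and colour intensity are linear in the interaction's
−log10 *p*; binned contacts as a rotated-triangle heat field; gene models
and link blocks packed into rows by greedy first-fit.

## Worked example

The package ships a seeded generator that writes a complete synthetic
input set — two Mb-scale regions on different chromosomes, an association
peak with LD decay around an index SNP, a chromatin-state segmentation, a
3 kb contact matrix with planted significant interactions, gene models and
annotations — plus a ready-to-run configuration:

```r
library(trackfig)
d <- "demo"
write_fixtures(d, seed = 1)
run(file.path(d, "config.yaml"), out_dir = file.path(d, "out"))
```

which logs:

```
[info] effective config: region_file=regions.tsv tracks=6 zoom=chr8:25421500-25481500 width_mm=180 height_mm=240 formats=pdf,png dpi=150 gap=0.05 log_level=info
[info] mapped 2 region(s) at 1578947.4 bp per canvas unit
[info] track 'GWAS -log10 p' (intensity): 75 record(s), 0 dropped
[info] track 'significant interactions' (links): 11 record(s), 0 dropped
[info] track 'chromatin states' (segmentation): 180 record(s), 0 dropped
[info] track 'association' (association): 801 record(s), 0 dropped
[info] track 'interaction arches' (arcs): 11 record(s), 0 dropped
[info] track 'genes' (genes): 9 record(s), 0 dropped
[info] zoom chr8:25421500-25481500 magnified 26.3x
[info] wrote demo/out/figure.pdf
[info] wrote demo/out/figure.png
```

`1578947.4 bp per canvas unit` is the common scale *B* shared by both
regions (1.5 Mb of genome over 0.95 canvas units at gap 0.05); `magnified
26.3x` is the ratio of the main panel's scale to the zoom panel's. The
figure stacks six lettered main tracks (a–f), the zoom panel over the LD
block with five more tracks, the connector trapezoid, per-region Mb axes
and a single figure-global legend.

The same build runs from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/trackfig.R", package="trackfig"))')" \
    fixtures --out demo --seed 1
Rscript "$(Rscript -e 'cat(system.file("cli/trackfig.R", package="trackfig"))')" \
    plot --config demo/config.yaml --out demo/out
```

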