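---
title: "How trackfig composes multi-region, multi-track, multi-scale figures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How trackfig composes multi-region, multi-track, multi-scale figures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The coordinate model

Everything in a `trackfig` figure hangs off a single object, the
`canvas_map`: an exact mapping of one or more genomic regions onto the
abstract horizontal interval [0, 1]. Given regions with genomic widths
$w_1, \dots, w_n$ (bp) and a fixed inter-region gap $g$ (canvas units),
the available width $1 - g(n-1)$ is divided among the regions in exact
proportion to $w_i$, which defines one common scale

$$B = \frac{\sum_i w_i}{1 - g(n-1)} \quad \text{(bp per canvas unit).}$$

Every region is drawn at this same $B$ whether the regions sit kilobases
apart or on different chromosomes; the construction leaves only
floating-point error, and the test suite and the acceptance script verify
that the relative deviation of per-region scale from $B$ stays below
$10^{-9}$ across randomly generated region sets.

A genomic position maps into its region's canvas segment linearly
(`genome_to_canvas`), and the inverse (`canvas_to_genome`) returns `NA`
inside gaps. Because every renderer places every glyph through this one
function over the same map, two tracks can never disagree about where a
base pair sits — the cross-track alignment property is structural, and is
still asserted directly (to $10^{-9}$ canvas units) on rendered glyphs.

Conventions worth stating explicitly:

* Intervals are 0-based half-open (`[start, end)`), the BED convention.
  Association files carry 1-based single positions and are shifted by
  $-1$ at parse time.
* Point data exactly on a region's right edge is mapped (closed edge), so
  an index SNP at a boundary is never silently dropped.
* Regions are drawn in region-file order, not genome order: the user
  controls the narrative order of loci.
* Features straddling a region edge are clipped at the edge
  (`clip_to_regions`), not dropped, which conserves the visible coverage.

## The zoom panel

A zoom is a second `canvas_map` over a single sub-region of one main
region, spanning [0, 1] on its own panel; its bp-per-unit is strictly
smaller, i.e. magnified (the default fixture figure reports the
magnification factor in its log). The connector keeps the zoom honest: its
two upper anchors are *defined* as `genome_to_canvas` of the target's
endpoints on the main map, so the trapezoid and the highlight box over the
target coincide exactly — the sub-region's location on the full view is
always indicated. One zoom per figure; a zoom of a zoom is out of scope.
The zoom panel may carry a different track list from the main panel (the
default fixture zooms into the LD block with the raw binned contact heat
map, which would be unreadable at Mb scale).

## Track encodings and their parameters

Renderers are pure functions from typed records and a `canvas_map` to a
list of backend-neutral glyphs (point, rect, arc, polygon, segment, line,
text) with x in canvas units and y in track-local [0, 1]. The figure
assembler maps y affinely into each track's vertical extent and never
touches x. All tie-breaks are explicit and no renderer consults the RNG,
so identical inputs yield byte-identical glyph lists.

* **Association (SNAP-style regional plot).** Height is
  $-\log_{10} p$ scaled by the track maximum `y_max` (default: the data
  maximum, at least 4). Point colour encodes the r² bin to the index SNP
  with default edges (0.2, 0.4, 0.6, 0.8) and a five-colour blue→red
  ramp — the de-facto regional-association-plot convention; both are
  parameters. Typed SNPs are circles, imputed triangles; the index SNP
  (r² = 1 or a configured id) is drawn last as a labelled purple diamond.
  Recombination rate (cM/Mb) is a line against a secondary axis scaled to
  its own maximum, broken at region boundaries so it never bridges a gap.
  Records without r² fall back to one neutral colour; records without the
  typed flag are drawn as typed.
* **Intensity.** One full-height rectangle per clipped interval, ramp
  colour over the min–max-normalised value; `vmin`/`vmax` can be fixed
  for cross-figure comparability. Degenerate rule: when all values are
  equal the ramp midpoint is used.
* **Segmentation.** Rectangles coloured by state; abutting same-state
  segments merge into one rectangle. States missing from the colour table
  get fallback colours assigned deterministically in state-name sort
  order. The legend lists exactly the states present, not the table.
* **Arches.** Apex height is *linear* in the interaction score
  ($-\log_{10} p$), normalised by the score maximum, with the top apex
  `h_max` (≤ 1) as a parameter; colour intensity uses the same normalised
  score. The score→height law is a parameterised choice: linear in
  $-\log_{10} p$ reads most directly as "stronger interaction, higher
  arch" and keeps equal scores at equal heights. Arches between regions
  deliberately span the gap. If every score is zero, arches are drawn at
  a small fixed height rather than vanishing. An interaction with one
  unmappable anchor is dropped (and counted in the log), never drawn
  half-way: filtering which interactions belong in the figure is the
  caller's decision, not the renderer's.
* **Links.** Two anchor rectangles joined by a segment, stacked into
  lanes by greedy first-fit over x-extents, processed in (start, input
  order). For interval graphs this greedy is optimal, and the tests check
  the lane count equals the brute-force maximum overlap depth.
* **Contact heat map.** The rotated-triangle convention: each bin pair
  becomes a diamond centred at the midpoint of the two bins' positions,
  raised in proportion to the bin separation, so the diagonal sits on the
  axis. Colour is a white→red ramp over count / count_max; zero counts
  take the background colour, and an all-zero matrix degenerates to a
  uniform background. Bins must sit on the `bin_size` grid (the parser
  enforces it); duplicates of a symmetric pair are summed with a warning
  at parse time so each cell is drawn exactly once.
* **Genes.** Transcript line, exon blocks, strand chevrons, name label
  left of the body (right when the left edge is clipped). Genes pack into
  rows by the same greedy first-fit over the extent of label plus body;
  the row count feeds back into the track's height so dense loci get
  taller gene tracks. Label width uses a fixed per-character estimate in
  canvas units — deterministic and backend-independent, at the cost of
  being approximate for extreme font choices.
* **Annotations.** Highlight boxes are translucent, full-height and at
  layer 0, beneath all data; vertical markers are dashed full-height
  lines with a label; brackets span an interval with a centred label.
  Annotations wholly outside the plotted regions are skipped with a
  warning.

## Figure assembly and output

Tracks are stacked top-to-bottom with vertical extents proportional to
their relative heights. Reference letters are assigned `a, b, c, …` in
stack order across the main panel and then the zoom panel (explicit
letters are preserved; duplicates are an error). The legend is
figure-global — entries collected from all tracks, deduplicated by swatch
plus label in first-appearance order, laid out in rows at the bottom; no
entries, no reserved space. One legend rather than per-track legends
keeps repeated encodings (the r² bins appear in two panels of the default
figure) to a single key. Coordinate axes are drawn per region with ticks
at round positions ($1/2/5 \times 10^k$ bp) and unit auto-selection
(bp/kb/Mb by span); tick positions invert exactly through
`canvas_to_genome`, which the tests assert.

Output goes through the base-graphics device layer: the same glyph list
is drawn once into a vector PDF and once into a PNG rasterised at the
configured dpi (default 300; page default 180 × 240 mm). Two runs of the
same configuration produce identical glyph lists; the PDF bytes may
differ in metadata (creation date), so determinism is asserted
structurally on the glyph lists.

The zoom panel sits below the main panel. Page space is divided among
title strip, panels (proportional to their summed track heights), axis
strips, connector and legend rows.

## The configuration file and CLI

`parse_config()` reads a YAML file whose keys mirror a menu-based
interface: a region file, an ordered track list (type, path, height,
letter, label, per-type params), an optional zoom block with its own
track list (defaulting to the main list), and figure parameters. The
schema is closed: unknown keys error with their key path, because a
silently ignored typo in `formats:` or `bin_size:` is exactly the kind of
failure a figure pipeline should not have. All defaults are resolved up
front and echoed to the log, so a run is reproducible from its log alone.
Strict parsing is the default; `--permissive` drops unparseable lines
with a warning instead. `inst/cli/trackfig.R` wraps `run()`,
`parse_config()` and `write_fixtures()` as `plot`, `validate` and
`fixtures` subcommands.

## The synthetic fixture generator

`write_fixtures()` produces the complete input set the test-suite and the
worked example run on: two regions on different chromosomes
(chr3:9,999,000–10,599,000 and chr8:24,999,000–25,899,000 — synthetic
stand-ins with Mb-scale widths, placed on the 3 kb bin grid; no genome
assembly is implied), ~800 SNPs with a planted association peak
(peak $-\log_{10} p = 8$) whose index SNP carries r² = 1 and the maximum
signal of its region, LD decaying as $\exp(-d/20\,\text{kb})$ with noise,
a recombination overlay with hotspots, a five-state sticky-Markov
segmentation tiling each region exactly, a contact matrix with Poisson
counts decaying as $(1+d)^{-1}$ and a planted five-fold-enriched pair set
emitted as the significant-interaction file (one pair joining the two
regions), gene models including a deliberately overlapping pair, and
annotations (highlight box and bracket over the LD block, marker at the
index SNP). All randomness flows through R's default Mersenne–Twister
from one integer seed; a given seed yields byte-identical files.

What the generator does *not* emulate: realistic LD structure (no
haplotypes, just monotone decay plus noise), Hi-C normalisation artefacts
or domain structure, overlapping transcript isoforms, or assembly-true
coordinates. Passing tests therefore demonstrate the engine's geometry,
encodings and determinism on structurally realistic inputs — not
statistical fidelity of the simulated biology.

## Numerical choices and degenerate inputs

* The last canvas segment edge is pinned to exactly 1 to stop cumulative
  floating-point drift; the scale-equality property is then measured, not
  assumed.
* Empty tracks render as empty glyph lists with axes intact; empty legend
  lists reserve no space.
* Normalisations (intensity value, arch score, heat-map count) are
  per-track min/max by default with optional fixed ranges, so multiple
  figures can share a colour scale when needed.
* Ties in lane/row packing break by (start, then input order);
  fallback state colours assign in state-name sort order — both purely
  for determinism.
* Problem sizes in the shipped tests and acceptance script (200 random
  region sets, 10⁴ round-trip positions, 100 packing instances of ≤ 12
  features, the default fixture figure with 11 tracks) keep the full
  suite under a minute on one CPU while exercising every code path.

## Known limitations

Indexed/binary input formats (tabix, BigWig, .hic, .cool) are not read;
inputs are plain tab-delimited text. No genome-build awareness or
liftover. One zoom level. No square contact-matrix mode, no Circos-style
ribbons, no SVG. Per-SNP r² must be precomputed upstream — computing LD
needs genotypes, which are out of scope for a plotting engine.
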