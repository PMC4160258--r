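# Shared test helpers: a memoised fixture set and small generators.

.fixture_cache <- new.env(parent = emptyenv())

# One full synthetic input set per seed, generated once per test session.
fixture_dir <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(.fixture_cache[[key]])) {
    d <- file.path(tempdir(), paste0("trackfig-fx-", seed))
    if (!dir.exists(d)) write_fixtures(d, seed = seed)
    .fixture_cache[[key]] <- d
  }
  .fixture_cache[[key]]
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Random region set: each region on its own chromosome slot so same-chrom
# overlap can never occur; widths span 1e3..1e7 bp.
random_region_set <- function(n) {
  regions <- lapply(seq_len(n), function(i) {
    w <- round(10^runif(1, 3, 7))
    s <- round(runif(1, 0, 1e8))
    genomic_interval(paste0("chr", i), s, s + w)
  })
  region_set(regions)
}

# A tiny two-region map used across unit tests: chr3:[100,200) and
# chr8:[500,600), gap 0.1 -> segments [0,0.45] and [0.55,1].
tiny_map <- function() {
  rs <- region_set(list(genomic_interval("chr3", 100, 200),
                        genomic_interval("chr8", 500, 600)))
  build_canvas_map(rs, gap = 0.1)
}

# Flatten x coordinates of all glyphs of a rendered track.
glyph_x <- function(track) unlist(lapply(track$glyphs, `[[`, "x"))

# Perceptual luminance of a hex colour (for monotone-intensity checks).
hex_luminance <- function(hex) {
  m <- grDevices::col2rgb(hex)
  as.numeric(0.2126 * m[1, ] + 0.7152 * m[2, ] + 0.0722 * m[3, ])
}
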