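# Track renderers: glyph geometry, encodings and packing.

assoc_df <- function(chrom, pos, pvalue, typed = NA, r2 = NA_real_,
                     recomb = NA_real_, id = NA_character_) {
  data.frame(chrom = chrom, pos = pos, pvalue = pvalue, typed = typed,
             r2 = r2, recomb = recomb, id = id, stringsAsFactors = FALSE)
}

inter_df <- function(chrom1, start1, end1, chrom2, start2, end2, score) {
  data.frame(chrom1 = chrom1, start1 = start1, end1 = end1, chrom2 = chrom2,
             start2 = start2, end2 = end2, score = score,
             stringsAsFactors = FALSE)
}

test_that("association points sit at -log10 p scaled by the track maximum", {
  m <- tiny_map()
  r <- render_association(assoc_df("chr3", c(150, 160), c(0.001, 1)), m,
                          list(y_max = 4))
  pts <- Filter(function(g) g$shape == "point", r$glyphs)
  expect_equal(vapply(pts, `[[`, numeric(1), "y"), c(3 / 4, 0))
  expect_equal(r$y_axis$range, c(0, 4))
  # records outside all regions are dropped, empty input keeps the axes
  r2 <- render_association(assoc_df("chr7", 150, 0.5), m, list())
  expect_equal(length(r2$glyphs), 0L)
  expect_equal(r2$dropped, 1L)
})

test_that("r2 bin colours match brute-force binning on the configured edges", {
  m <- tiny_map()
  edges <- c(0.2, 0.4, 0.6, 0.8)
  cols <- c("#111111", "#222222", "#333333", "#444444", "#555555")
  brute_bin <- function(r2) {
    b <- 1L
    for (e in edges) if (r2 > e) b <- b + 1L
    b
  }
  set.seed(5)
  r2v <- c(0, 0.2, 0.200001, 0.85, 1 - 1e-9, runif(50))
  for (v in r2v) {
    r <- render_association(assoc_df("chr3", 150, 0.01, r2 = v), m,
                            list(r2_edges = edges, r2_colors = cols))
    pt <- Filter(function(g) g$shape == "point", r$glyphs)[[1]]
    expect_equal(pt$fill, cols[brute_bin(v)], info = sprintf("r2=%g", v))
  }
  # 0.85 with the default edges lands in the top bin colour
  r <- render_association(assoc_df("chr3", 150, 0.01, r2 = 0.85), m, list())
  pt <- Filter(function(g) g$shape == "point", r$glyphs)[[1]]
  expect_equal(pt$fill, trackfig:::default_r2_colors[5])
})

test_that("index SNP is drawn last with a distinct marker and label", {
  m <- tiny_map()
  r <- render_association(assoc_df("chr3", c(120, 150), c(0.01, 1e-6),
                                   r2 = c(0.3, 1),
                                   id = c("rs1", "rsTOP")), m, list())
  pts <- Filter(function(g) g$shape == "point", r$glyphs)
  expect_equal(pts[[length(pts)]]$pch, 23)  # index drawn last
  labs <- Filter(function(g) g$shape == "text", r$glyphs)
  expect_equal(labs[[1]]$text, "rsTOP")
})

test_that("intensity normalises min-max with a midpoint degenerate rule", {
  m <- tiny_map()
  recs <- read_bed_like(write_tmp(c("chr3\t100\t120\t0", "chr3\t120\t140\t5",
                                    "chr3\t140\t160\t10")), "intensity")
  r <- render_intensity(recs, m, list(palette = c("#000000", "#FFFFFF")))
  fills <- vapply(r$glyphs, `[[`, character(1), "fill")
  expect_equal(fills, c("#000000", "#7F7F7F", "#FFFFFF"))
  # single record -> palette midpoint
  one <- render_intensity(read_bed_like(write_tmp("chr3\t100\t120\t7"),
                                        "intensity"), m,
                          list(palette = c("#000000", "#FFFFFF")))
  expect_equal(one$glyphs[[1]]$fill, "#7F7F7F")
  # interval straddling the region edge is clipped at the edge
  strad <- render_intensity(read_bed_like(write_tmp("chr3\t50\t150\t1"),
                                          "intensity"), m, list())
  expect_equal(strad$glyphs[[1]]$x[1], 0)
  expect_equal(strad$glyphs[[1]]$x[2], genome_to_canvas(m, "chr3", 150))
})

test_that("segmentation merges abutting same-state runs and legends states present", {
  m <- tiny_map()
  recs <- read_bed_like(write_tmp(c("chr3\t100\t150\tEnh", "chr3\t150\t180\tEnh",
                                    "chr3\t180\t200\tProm")), "segmentation")
  r <- render_segmentation(recs, m, list())
  rects <- Filter(function(g) g$shape == "rect", r$glyphs)
  expect_equal(length(rects), 2L)  # two Enh pieces merged
  expect_equal(rects[[1]]$x, c(0, genome_to_canvas(m, "chr3", 180)))
  expect_equal(vapply(r$legend, `[[`, character(1), "label"), c("Enh", "Prom"))
  # fallback colours are deterministic across re-runs
  r2 <- render_segmentation(recs, m, list())
  expect_identical(lapply(r$glyphs, `[[`, "fill"),
                   lapply(r2$glyphs, `[[`, "fill"))
})

test_that("arc apex heights are linear in score and span the gap", {
  m <- tiny_map()
  recs <- inter_df("chr3", c(110, 110), c(120, 120), "chr3",
                   c(180, 180), c(190, 190), c(2, 4))
  r <- render_arcs(recs, m, list(h_max = 1))
  apex <- vapply(r$glyphs, function(g) g$y[2], numeric(1))
  expect_equal(apex, c(0.5, 1.0))
  # equal scores -> equal heights and colours
  eq <- render_arcs(inter_df("chr3", c(110, 130), c(120, 140), "chr3",
                             c(180, 150), c(190, 160), c(3, 3)), m, list())
  expect_equal(eq$glyphs[[1]]$y[2], eq$glyphs[[2]]$y[2])
  expect_equal(eq$glyphs[[1]]$col, eq$glyphs[[2]]$col)
  # anchors in different regions: the arc x-span crosses the gap
  cross <- render_arcs(inter_df("chr3", 110, 120, "chr8", 580, 590, 5), m,
                       list())
  expect_lt(cross$glyphs[[1]]$x[1], 0.45)
  expect_gt(cross$glyphs[[1]]$x[2], 0.55)
  # an unmappable anchor drops the interaction with a logged count
  expect_message(
    half <- render_arcs(inter_df("chr3", 110, 120, "chr9", 0, 10, 5), m,
                        list()),
    "dropped 1")
  expect_equal(length(half$glyphs), 0L)
  # all-zero scores fall back to the minimum visible height
  z <- render_arcs(inter_df("chr3", 110, 120, "chr3", 180, 190, 0), m,
                   list(min_height = 0.07))
  expect_equal(z$glyphs[[1]]$y[2], 0.07)
})

test_that("link lanes come from greedy first-fit and match brute force", {
  m <- tiny_map()
  disjoint <- render_links(inter_df("chr3", c(100, 160), c(110, 170), "chr3",
                                    c(120, 180), c(130, 190), c(1, 1)), m,
                           list())
  expect_equal(disjoint$n_rows, 1L)
  overlapping <- render_links(
    inter_df("chr3", c(100, 105, 110), c(150, 155, 160), "chr3",
             c(160, 165, 170), c(170, 175, 180), c(1, 1, 1)), m, list())
  expect_equal(overlapping$n_rows, 3L)
  cross <- render_links(inter_df("chr3", 110, 120, "chr8", 580, 590, 5), m,
                        list())
  seg <- Filter(function(g) g$shape == "segment", cross$glyphs)[[1]]
  expect_lt(seg$x[1], 0.45)
  expect_gt(seg$x[2], 0.55)
})

test_that("heatmap diamonds follow the rotated-triangle geometry", {
  rs <- region_set(list(genomic_interval("chr1", 0, 30000)))
  m <- build_canvas_map(rs)
  ct <- read_contacts(write_tmp(c("chr1\t0\tchr1\t0\t10",
                                  "chr1\t0\tchr1\t6000\t0",
                                  "chr1\t3000\tchr1\t9000\t5")), 3000)
  r <- render_heatmap(ct, m, list())
  diag_g <- r$glyphs[[1]]
  expect_equal(min(diag_g$y), 0)  # diagonal diamond touches the axis
  # zero count -> background colour; max count -> ramp(1)
  fills <- vapply(r$glyphs, `[[`, character(1), "fill")
  expect_equal(fills[2], "#F0F0F0")
  expect_equal(fills[1], trackfig:::make_ramp(trackfig:::default_heat_ramp)(1))
  # diamond x centre is the midpoint of the two bin midpoints
  expect_equal(r$glyphs[[3]]$x[2],
               genome_to_canvas(m, "chr1", (3000 + 9000 + 3000) / 2))
  # count_max = 0 -> uniform background
  z <- render_heatmap(read_contacts(write_tmp("chr1\t0\tchr1\t3000\t0"),
                                    3000), m, list())
  expect_equal(z$glyphs[[1]]$fill, "#F0F0F0")
})

test_that("gene packing yields non-overlapping rows and clips bodies", {
  rs <- region_set(list(genomic_interval("chr1", 0, 100000)))
  m <- build_canvas_map(rs)
  bed <- c(
    "chr1\t10000\t30000\tA\t0\t+\t10000\t30000\t0\t1\t20000,\t0,",
    "chr1\t50000\t70000\tB\t0\t-\t50000\t70000\t0\t1\t20000,\t0,")
  two <- render_genes(read_genes(write_tmp(bed)), m, list())
  expect_equal(two$n_rows, 1L)
  bed3 <- c(
    "chr1\t10000\t60000\tA\t0\t+\t10000\t60000\t0\t1\t50000,\t0,",
    "chr1\t20000\t70000\tB\t0\t+\t20000\t70000\t0\t1\t50000,\t0,",
    "chr1\t30000\t80000\tC\t0\t+\t30000\t80000\t0\t1\t50000,\t0,")
  three <- render_genes(read_genes(write_tmp(bed3)), m, list())
  expect_equal(three$n_rows, 3L)
  # gene past the region edge: body clipped, name still drawn
  past <- render_genes(read_genes(write_tmp(
    "chr1\t90000\t150000\tD\t0\t+\t90000\t150000\t0\t1\t60000,\t0,")), m,
    list())
  xs <- glyph_x(past)
  expect_true(all(xs[is.finite(xs)] <= 1 + 1e-9))
  expect_true(any(vapply(past$glyphs, function(g)
    g$shape == "text" && identical(g$text, "D"), logical(1))))
})

test_that("annotation kinds map to their glyph shapes; outside features warn", {
  m <- tiny_map()
  anns <- read_annotations(write_tmp(c(
    "chr3\t120\t160\thighlight-box\t",
    "chr3\t150\t151\tvertical-marker\trsX",
    "chr3\t110\t190\tbracket\tblock")))
  r <- render_annotations(anns, m, list())
  shapes <- vapply(r$glyphs, `[[`, character(1), "shape")
  expect_true("rect" %in% shapes && "segment" %in% shapes &&
                "line" %in% shapes)
  box <- Filter(function(g) g$shape == "rect", r$glyphs)[[1]]
  expect_equal(box$layer, 0L)  # beneath all data layers
  expect_warning(
    out <- render_annotations(read_annotations(write_tmp(
      "chr9\t1\t2\tvertical-marker\tgone")), m, list()),
    "outside")
  expect_equal(length(out$glyphs), 0L)
})

test_that("renderers are deterministic: identical inputs, identical glyphs", {
  d <- fixture_dir()
  m <- build_canvas_map(parse_region_file(file.path(d, "regions.tsv")))
  a <- read_association(file.path(d, "association.tsv"))
  expect_identical(render_association(a, m, list()),
                   render_association(a, m, list()))
  g <- read_genes(file.path(d, "genes.bed"))
  expect_identical(render_genes(g, m, list()), render_genes(g, m, list()))
})
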