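# Track stacking, letters, legend, zoom attachment and file output.

dummy_track <- function(y = c(0, 1)) {
  trackfig:::rendered_track("intensity",
    list(trackfig:::glyph("rect", c(0.1, 0.9), y, fill = "#000000")))
}

test_that("stack_tracks allocates extents proportionally, changing only y", {
  p <- stack_tracks(list(dummy_track(), dummy_track()), heights = c(1, 1))
  expect_equal(unname(p$extents[1, ]), c(0.5, 1))
  expect_equal(unname(p$extents[2, ]), c(0, 0.5))
  p2 <- stack_tracks(list(dummy_track(), dummy_track()), heights = c(3, 1))
  expect_equal(unname(p2$extents[1, 1]), 0.25)
  p1 <- stack_tracks(list(dummy_track()))
  expect_equal(unname(p1$extents[1, ]), c(0, 1))
  # x untouched by stacking
  expect_equal(p$tracks[[1]]$glyphs[[1]]$x, c(0.1, 0.9))
  # y mapped inside the extent
  y <- p$tracks[[2]]$glyphs[[1]]$y
  expect_true(all(y >= 0 & y <= 0.5))
})

test_that("letters auto-assign across main then zoom; duplicates error", {
  l <- assign_letters(rep(list(NULL), 4))
  expect_equal(l$main, c("a", "b", "c", "d"))
  l2 <- assign_letters(rep(list(NULL), 2), rep(list(NULL), 2))
  expect_equal(l2$zoom, c("c", "d"))
  keep <- assign_letters(list("x", "y"))
  expect_equal(keep$main, c("x", "y"))
  mixed <- assign_letters(list("a", NULL))
  expect_equal(mixed$main, c("a", "b"))
  expect_error(assign_letters(list("a", "a")), "duplicate")
})

test_that("legend deduplicates, lays out in rows, and vanishes when empty", {
  e <- function(lbl) trackfig:::legend_entry(lbl, col = "#000000", pch = 21)
  lg <- build_legend(list(e("x"), e("x"), e("y")), max_per_row = 3)
  expect_equal(length(lg$entries), 2L)
  expect_equal(lg$n_rows, 1L)
  lg5 <- build_legend(lapply(paste0("e", 1:5), e), max_per_row = 3)
  expect_equal(lg5$n_rows, 2L)
  empty <- build_legend(list())
  expect_equal(empty$n_rows, 0L)
  expect_equal(length(empty$glyphs), 0L)
})

test_that("zoom connector trapezoid joins the target extent to the zoom panel", {
  m <- tiny_map()
  zm <- build_zoom_map(m, zoom_spec(genomic_interval("chr8", 540, 560),
                                    m$regions))
  g <- attach_zoom(zm$connector, main_extent = c(0.6, 0.9),
                   zoom_extent = c(0.1, 0.4))
  trap <- g[[1]]; box <- g[[2]]
  # upper edge of the trapezoid == highlight box edges == connector anchors
  expect_equal(trap$x[1:2], zm$connector$main)
  expect_equal(box$x, zm$connector$main)
  expect_equal(trap$x[3:4], c(1, 0))
  expect_equal(trap$y[1:2], c(0.6, 0.6))
})

test_that("composition keeps x fixed while mapping track y into extents", {
  d <- fixture_dir()
  cfg <- parse_config(file.path(d, "config.yaml"))
  built <- suppressMessages(build_figure(cfg))
  lay <- built$layout
  expect_s3_class(lay, "figure_layout")
  expect_equal(lay$n_tracks, 11L)
  expect_equal(lay$letters$main, c("a", "b", "c", "d", "e", "f"))
  # one letter glyph per track
  letter_glyphs <- Filter(function(g) {
    g$shape == "text" && !is.na(g$text) &&
      grepl("^[a-z]\\.$", g$text)
  }, lay$glyphs)
  expect_equal(length(letter_glyphs), 11L)
  # a title iff configured, a legend iff entries exist
  expect_true(any(vapply(lay$glyphs, function(g)
    identical(g$text, cfg$figure$title), logical(1))))
  expect_gt(lay$legend$n_rows, 0)
})

test_that("tick positions are round numbers that invert through the map", {
  m <- tiny_map()
  ticks <- trackfig:::nice_ticks(24999000, 25899000)
  expect_true(all(ticks %% 10^floor(log10(diff(range(ticks)) / 4)) == 0))
  r <- m$regions$regions[[1]]
  for (tp in trackfig:::nice_ticks(r$start, r$end)) {
    x <- genome_to_canvas(m, r$chrom, tp)
    back <- canvas_to_genome(m, x)
    expect_equal(back$pos, tp, tolerance = 1e-9)
  }
})

test_that("render_figure writes valid non-empty PDF and PNG from one layout", {
  d <- fixture_dir()
  built <- suppressMessages(build_figure(parse_config(file.path(d,
                                                                "config.yaml"))))
  out <- tempfile("figs")
  paths <- render_figure(built$layout, out_dir = out, name = "fig",
                         formats = c("pdf", "png"), dpi = 96)
  expect_equal(length(paths), 2L)
  expect_true(all(file.exists(paths)))
  expect_true(all(file.info(paths)$size > 0))
  pdf_magic <- readBin(paths[grepl("pdf$", paths)], "raw", 4)
  expect_equal(rawToChar(pdf_magic), "%PDF")
  png_magic <- readBin(paths[grepl("png$", paths)], "raw", 8)
  expect_equal(png_magic[2:4], charToRaw("PNG"))
  expect_error(render_figure(built$layout, formats = character(0)),
               "no output format")
  expect_error(render_figure(built$layout, formats = "svg"),
               "unknown output format")
})
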