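# Figure assembly: stack rendered tracks into panels, attach the zoom
# panel and its connector, compose title / letters / axes / legend, and
# write PDF and PNG through the base-graphics backend.
#
# Two coordinate systems meet here.  Tracks arrive with x in canvas units
# [0, 1] and y in track-local units [0, 1]; assembly maps y affinely into
# each track's vertical extent and then into page-normalised coordinates.
# x is never touched except for the fixed page margins, which preserves
# the cross-track base-pair alignment guarantee.

#' Describe one track of a figure
#'
#' @param type One of `association`, `intensity`, `segmentation`, `arcs`,
#'   `links`, `heatmap`, `genes`, `annotations`.
#' @param path Path to the track's data file (optional when `data` given).
#' @param data Pre-parsed records (optional; used instead of `path`).
#' @param height Relative vertical height of the track (> 0).
#' @param letter Optional explicit single-character track letter.
#' @param label Optional display label.
#' @param params Per-type rendering parameters (see the render functions).
#' @return An object of class `track_spec`.
#' @export
track_spec <- function(type, path = NULL, data = NULL, height = 1,
                       letter = NULL, label = NULL, params = list()) {
  type <- match.arg(type, track_types)
  stopifnot(is.numeric(height), length(height) == 1L, height > 0)
  if (!is.null(letter)) {
    stopifnot(is.character(letter), length(letter) == 1L,
              nchar(letter) == 1L)
  }
  structure(list(type = type, path = path, data = data, height = height,
                 letter = letter, label = label, params = params),
            class = "track_spec")
}

track_types <- c("association", "intensity", "segmentation", "arcs",
                 "links", "heatmap", "genes", "annotations")

#' Describe a whole figure
#'
#' @param tracks List of [track_spec()] for the main panel (at least one).
#' @param title Optional figure title.
#' @param zoom Optional [zoom_spec()] (built against the region set at run
#'   time when coming from a config file).
#' @param zoom_tracks List of [track_spec()] for the zoom panel; may differ
#'   from the main tracks.  Must be empty when no zoom is set.
#' @param page_mm Page size `c(width, height)` in mm.
#' @param formats Output formats, subset of `c("pdf", "png")`.
#' @param dpi PNG resolution in dots per inch.
#' @param gap Inter-region gap in canvas units.
#' @return An object of class `figure_spec`.
#' @export
figure_spec <- function(tracks, title = NULL, zoom = NULL,
                        zoom_tracks = list(), page_mm = c(180, 240),
                        formats = c("pdf", "png"), dpi = 300, gap = 0.05) {
  if (inherits(tracks, "track_spec")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "track_spec")))
  if (inherits(zoom_tracks, "track_spec")) zoom_tracks <- list(zoom_tracks)
  if (length(zoom_tracks) && is.null(zoom)) {
    stop("zoom_tracks given but no zoom target set", call. = FALSE)
  }
  if (length(formats) == 0L) stop("no output format requested", call. = FALSE)
  formats <- vapply(formats, function(f) {
    match.arg(tolower(f), c("pdf", "png"))
  }, character(1), USE.NAMES = FALSE)
  stopifnot(length(page_mm) == 2L, all(page_mm > 0), dpi > 0)
  structure(list(tracks = tracks, title = title, zoom = zoom,
                 zoom_tracks = zoom_tracks, page_mm = page_mm,
                 formats = unique(formats), dpi = dpi, gap = gap),
            class = "figure_spec")
}

# Affine map of a glyph's track-local y into [y0, y1].
shift_glyph_y <- function(g, y0, y1) {
  g$y <- y0 + g$y * (y1 - y0)
  g
}

#' Stack rendered tracks into a panel
#'
#' Vertical extents are allocated proportionally to the requested heights,
#' top to bottom in list order, and each track's glyph y values are mapped
#' affinely into its extent.  x values are untouched.
#'
#' @param rendered List of `rendered_track` objects.
#' @param heights Positive relative heights, one per track.
#' @param map The panel's [build_canvas_map()] result (kept for axes).
#' @return An object of class `track_panel` with per-track extents and
#'   transformed glyphs.
#' @export
stack_tracks <- function(rendered, heights = NULL, map = NULL) {
  stopifnot(length(rendered) >= 1L,
            all(vapply(rendered, inherits, logical(1), "rendered_track")))
  heights <- heights %||% rep(1, length(rendered))
  stopifnot(length(heights) == length(rendered), all(heights > 0))
  hn <- heights / sum(heights)
  tops <- 1 - cumsum(c(0, head(hn, -1L)))
  extents <- cbind(y0 = tops - hn, y1 = tops)
  tracks <- vector("list", length(rendered))
  for (i in seq_along(rendered)) {
    tr <- rendered[[i]]
    # small interior padding so adjacent tracks do not visually fuse
    pad <- 0.04 * hn[i]
    tr$glyphs <- lapply(tr$glyphs, shift_glyph_y,
                        y0 = extents[i, 1L] + pad,
                        y1 = extents[i, 2L] - pad)
    tracks[[i]] <- tr
  }
  structure(list(tracks = tracks, extents = extents, map = map),
            class = "track_panel")
}

#' Assign track reference letters
#'
#' Auto mode assigns `a, b, c, ...` in stack order across the main panel
#' and then the zoom panel; explicit letters in the track specs are
#' preserved.  Duplicate explicit letters are an error.
#'
#' @param main_letters List/vector of explicit letters (or `NULL`s) for the
#'   main-panel tracks.
#' @param zoom_letters Same for the zoom-panel tracks (may be empty).
#' @return List with character vectors `main` and `zoom`.
#' @export
assign_letters <- function(main_letters, zoom_letters = list()) {
  as_chr <- function(x) {
    vapply(x, function(l) if (is.null(l) || is.na(l)) NA_character_ else
      as.character(l), character(1))
  }
  all_l <- c(as_chr(main_letters), as_chr(zoom_letters))
  explicit <- all_l[!is.na(all_l)]
  if (anyDuplicated(explicit)) {
    stop(sprintf("duplicate track letter '%s'",
                 explicit[duplicated(explicit)][1]), call. = FALSE)
  }
  pool <- setdiff(letters, explicit)
  auto_i <- which(is.na(all_l))
  if (length(auto_i) > length(pool)) {
    stop("more tracks than available letters", call. = FALSE)
  }
  all_l[auto_i] <- pool[seq_along(auto_i)]
  n_main <- length(main_letters)
  list(main = all_l[seq_len(n_main)],
       zoom = if (length(zoom_letters))
         all_l[seq.int(n_main + 1L, length(all_l))] else character(0))
}

#' Lay out the figure legend
#'
#' Entries are deduplicated by swatch + label keeping first appearance, and
#' laid out left-to-right in rows.
#'
#' @param entries List of legend entries collected from the tracks.
#' @param max_per_row Maximum entries per legend row.
#' @return List with `glyphs` (in legend-strip coordinates), `n_rows`,
#'   `entries` (the deduplicated list).
#' @export
build_legend <- function(entries, max_per_row = 4L) {
  key <- vapply(entries, function(e) {
    paste(e$label, e$col, e$pch, e$lty, e$fill, sep = "\r")
  }, character(1))
  entries <- entries[!duplicated(key)]
  n <- length(entries)
  if (n == 0L) return(list(glyphs = list(), n_rows = 0L, entries = list()))
  n_rows <- ceiling(n / max_per_row)
  per_row <- min(n, max_per_row)
  glyphs <- list()
  for (i in seq_len(n)) {
    row <- (i - 1L) %/% max_per_row
    col_i <- (i - 1L) %% max_per_row
    x0 <- col_i / per_row + 0.005
    yc <- 1 - (row + 0.5) / n_rows
    e <- entries[[i]]
    if (!is.na(e$pch)) {
      glyphs[[length(glyphs) + 1L]] <- glyph("point", x0 + 0.008, yc,
                                             col = e$col, fill = e$fill,
                                             pch = e$pch, cex = 0.9,
                                             layer = 1L)
    } else if (!is.na(e$lty)) {
      glyphs[[length(glyphs) + 1L]] <- glyph("segment",
                                             c(x0, x0 + 0.016), c(yc, yc),
                                             col = e$col, lty = e$lty,
                                             lwd = 1.5, layer = 1L)
    } else {
      glyphs[[length(glyphs) + 1L]] <- glyph("rect",
                                             c(x0, x0 + 0.016),
                                             c(yc - 0.28 / n_rows,
                                               yc + 0.28 / n_rows),
                                             fill = e$fill, col = "#888888",
                                             lwd = 0.4, layer = 1L)
    }
    glyphs[[length(glyphs) + 1L]] <- glyph("text", x0 + 0.022, yc,
                                           text = e$label, cex = 0.7,
                                           col = "#000000", adj = 0,
                                           layer = 2L)
  }
  list(glyphs = glyphs, n_rows = n_rows, entries = entries)
}

#' Compute the zoom connector geometry in page coordinates
#'
#' Produces the translucent trapezoid joining the zoom target's x-extent at
#' the bottom of the main panel to the full zoom-panel width at its top,
#' plus the highlight box over the target inside the main panel.  The
#' trapezoid's upper corners coincide exactly with the highlight box edges.
#'
#' @param connector Connector from [build_zoom_map()].
#' @param main_extent Page y-extent `c(y0, y1)` of the main panel.
#' @param zoom_extent Page y-extent `c(y0, y1)` of the zoom panel.
#' @return List of glyphs (trapezoid polygon and highlight rectangle) in
#'   page-normalised coordinates (x still canvas units).
#' @export
attach_zoom <- function(connector, main_extent, zoom_extent) {
  xm <- connector$main
  xz <- connector$zoom
  list(
    glyph("polygon",
          c(xm[1], xm[2], xz[2], xz[1]),
          c(main_extent[1], main_extent[1], zoom_extent[2], zoom_extent[2]),
          fill = "#B0C4DE50", col = "#7799BB", lwd = 0.5, layer = 0L),
    glyph("rect", c(xm[1], xm[2]), c(main_extent[1], main_extent[2]),
          fill = "#B0C4DE40", col = "#7799BB", lwd = 0.5, layer = 0L))
}

# Round tick positions at 1/2/5 x 10^k covering [start, end].
nice_ticks <- function(start, end, target_n = 4L) {
  span <- end - start
  stopifnot(span > 0)
  best <- NULL
  for (k in seq.int(floor(log10(span)) + 1L, floor(log10(span)) - 2L)) {
    for (m in c(5, 2, 1)) {
      s <- m * 10^k
      lo <- ceiling(start / s) * s
      hi <- floor(end / s) * s
      if (lo > hi) next
      ticks <- seq(lo, hi, by = s)
      if (length(ticks) >= 2L) {
        best <- ticks
        if (length(ticks) >= target_n) return(best)
      }
    }
  }
  best %||% numeric(0)
}

# Human-readable bp labels with automatic unit (bp / kb / Mb) per span.
format_bp <- function(pos, span) {
  if (span >= 5e5) {
    sprintf("%.4g Mb", pos / 1e6)
  } else if (span >= 5e2) {
    sprintf("%.5g kb", pos / 1e3)
  } else {
    sprintf("%d bp", round(pos))
  }
}

# Axis glyphs for one panel: baseline per region segment, ticks, labels,
# and region display names above the panel.
axis_glyphs <- function(map, panel_extent, strip_h = 0.028,
                        region_labels_on_top = TRUE) {
  g <- list()
  y_base <- panel_extent[1]
  rs <- map$regions
  labs <- region_labels(rs)
  for (i in seq_len(n_regions(rs))) {
    r <- rs$regions[[i]]
    x0 <- map$segments[i, 1L]; x1 <- map$segments[i, 2L]
    g[[length(g) + 1L]] <- glyph("segment", c(x0, x1), c(y_base, y_base),
                                 col = "#000000", lwd = 0.8, layer = 5L)
    span <- r$end - r$start
    for (tp in nice_ticks(r$start, r$end)) {
      xt <- genome_to_canvas(map, r$chrom, tp)
      g[[length(g) + 1L]] <- glyph("segment", c(xt, xt),
                                   c(y_base, y_base - strip_h * 0.3),
                                   col = "#000000", lwd = 0.8, layer = 5L)
      g[[length(g) + 1L]] <- glyph("text", xt, y_base - strip_h * 0.75,
                                   text = format_bp(tp, span), cex = 0.6,
                                   col = "#000000", layer = 5L)
    }
    if (region_labels_on_top) {
      g[[length(g) + 1L]] <- glyph("text", (x0 + x1) / 2,
                                   panel_extent[2] + 0.012,
                                   text = labs[i], cex = 0.75,
                                   col = "#000000", layer = 5L)
    }
  }
  g
}

#' Compose a figure into a page-normalised glyph list
#'
#' Pure assembly step: stacks the main panel, optionally the zoom panel
#' with its connector, adds title, track letters, per-region coordinate
#' axes and the figure-global legend.  The result is deterministic given
#' identical inputs and is what both output backends draw.
#'
#' @param map Main-panel [build_canvas_map()] result.
#' @param rendered_main List of `rendered_track` for the main panel.
#' @param heights_main Relative heights (default all 1).
#' @param title Optional title string.
#' @param zoom Optional list with elements `map`, `connector` (from
#'   [build_zoom_map()]), `rendered` (list of `rendered_track`) and
#'   optionally `heights`.
#' @param letters Optional result of [assign_letters()]; computed in auto
#'   mode when omitted.
#' @return An object of class `figure_layout`: flat glyph list in page
#'   coordinates plus layout metadata.
#' @export
compose_figure <- function(map, rendered_main, heights_main = NULL,
                           title = NULL, zoom = NULL, letters = NULL) {
  heights_main <- heights_main %||% rep(1, length(rendered_main))
  # gene tracks grow with their row count
  heights_main <- adjust_gene_heights(rendered_main, heights_main)
  legend_entries <- unlist(lapply(c(rendered_main, zoom$rendered %||% list()),
                                  `[[`, "legend"), recursive = FALSE)
  legend <- build_legend(legend_entries %||% list())
  letters <- letters %||% assign_letters(
    rep(list(NULL), length(rendered_main)),
    rep(list(NULL), length(zoom$rendered %||% list())))

  margin_l <- 0.055; margin_r <- 0.02
  title_h <- if (!is.null(title) && nzchar(title)) 0.055 else 0.012
  axis_h <- 0.045
  legend_h <- if (legend$n_rows > 0) 0.012 + 0.03 * legend$n_rows else 0
  connector_h <- if (!is.null(zoom)) 0.045 else 0
  pad_bottom <- 0.012
  avail <- 1 - title_h - axis_h - legend_h - pad_bottom - connector_h -
    (if (!is.null(zoom)) axis_h else 0) - 0.02
  wm <- sum(heights_main)
  hz <- if (!is.null(zoom)) {
    h <- zoom$heights %||% rep(1, length(zoom$rendered))
    adjust_gene_heights(zoom$rendered, h)
  } else numeric(0)
  wz <- sum(hz)
  main_h <- if (wz > 0) avail * wm / (wm + wz) else avail
  zoom_h <- avail - main_h

  y_top <- 1 - title_h
  main_extent <- c(y_top - main_h, y_top)
  glyphs <- list()
  if (!is.null(title) && nzchar(title)) {
    glyphs[[length(glyphs) + 1L]] <- glyph("text", 0.5, 1 - title_h / 2,
                                           text = title, cex = 1.2,
                                           col = "#000000", layer = 6L)
  }

  place_panel <- function(panel, extent, letter_set) {
    out <- list()
    for (i in seq_along(panel$tracks)) {
      tr <- panel$tracks[[i]]
      te <- extent[1] + panel$extents[i, ] * (extent[2] - extent[1])
      for (g in tr$glyphs) {
        out[[length(out) + 1L]] <- shift_glyph_y(g, extent[1], extent[2])
      }
      if (length(letter_set) >= i && !is.na(letter_set[i])) {
        out[[length(out) + 1L]] <- glyph("text", -0.045, te[2L] - 0.008,
                                         text = paste0(letter_set[i], "."),
                                         cex = 0.9, col = "#000000",
                                         adj = 0, layer = 6L)
      }
      if (!is.null(tr$y_axis)) {
        out[[length(out) + 1L]] <- glyph("text", -0.028,
                                         mean(te),
                                         text = sprintf("%s (0-%s)",
                                                        tr$y_axis$label,
                                                        fmt_sig(tr$y_axis$range[2])),
                                         cex = 0.5, col = "#444444",
                                         adj = 0.5, layer = 6L)
      }
    }
    out
  }

  main_panel <- stack_tracks(rendered_main, heights_main, map = map)
  glyphs <- c(glyphs, place_panel(main_panel, main_extent, letters$main))
  glyphs <- c(glyphs, axis_glyphs(map, main_extent))

  zoom_extent <- NULL
  if (!is.null(zoom)) {
    zoom_top <- main_extent[1] - axis_h - connector_h
    zoom_extent <- c(zoom_top - zoom_h, zoom_top)
    zoom_panel <- stack_tracks(zoom$rendered, hz, map = zoom$map)
    glyphs <- c(glyphs, attach_zoom(zoom$connector, main_extent, zoom_extent))
    glyphs <- c(glyphs, place_panel(zoom_panel, zoom_extent, letters$zoom))
    glyphs <- c(glyphs, axis_glyphs(zoom$map, zoom_extent,
                                    region_labels_on_top = FALSE))
  }

  if (legend$n_rows > 0) {
    ly0 <- pad_bottom; ly1 <- pad_bottom + 0.03 * legend$n_rows
    glyphs <- c(glyphs, lapply(legend$glyphs, shift_glyph_y, y0 = ly0,
                               y1 = ly1))
  }

  structure(list(glyphs = glyphs, margin_l = margin_l, margin_r = margin_r,
                 main_extent = main_extent, zoom_extent = zoom_extent,
                 letters = letters, legend = legend,
                 n_tracks = length(rendered_main) +
                   length(zoom$rendered %||% list())),
            class = "figure_layout")
}

adjust_gene_heights <- function(rendered, heights) {
  for (i in seq_along(rendered)) {
    if (identical(rendered[[i]]$type, "genes") &&
        !is.null(rendered[[i]]$n_rows)) {
      heights[i] <- heights[i] * max(1, rendered[[i]]$n_rows * 0.6)
    }
  }
  heights
}

# ---- drawing backend -------------------------------------------------------

draw_layout <- function(layout) {
  op <- graphics::par(mar = c(0, 0, 0, 0), xpd = NA)
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), xaxs = "i",
                        yaxs = "i")
  ml <- layout$margin_l; mr <- layout$margin_r
  tx <- function(x) ml + x * (1 - ml - mr)
  ord <- order(vapply(layout$glyphs, `[[`, integer(1), "layer"))
  for (g in layout$glyphs[ord]) {
    draw_glyph(g, tx)
  }
  invisible(NULL)
}

draw_glyph <- function(g, tx) {
  x <- tx(g$x); y <- g$y
  switch(g$shape,
    point = graphics::points(x, y, col = g$col,
                             bg = if (is.na(g$fill)) NA else g$fill,
                             pch = g$pch, cex = g$cex),
    rect = graphics::rect(x[1], y[1], x[2], y[2],
                          col = if (is.na(g$fill)) NA else g$fill,
                          border = if (is.na(g$col)) NA else g$col,
                          lwd = g$lwd),
    segment = graphics::segments(x[1], y[1], x[2], y[2], col = g$col,
                                 lwd = g$lwd, lty = g$lty),
    line = graphics::lines(x, y, col = g$col, lwd = g$lwd, lty = g$lty),
    polygon = graphics::polygon(x, y,
                                col = if (is.na(g$fill)) NA else g$fill,
                                border = if (is.na(g$col)) NA else g$col,
                                lwd = g$lwd),
    arc = {
      t <- seq(0, pi, length.out = 60)
      cx <- (x[1] + x[2]) / 2
      rx <- abs(x[2] - x[1]) / 2
      graphics::lines(cx - rx * cos(t),
                      y[1] + (y[2] - y[1]) * sin(t),
                      col = g$col, lwd = g$lwd)
    },
    text = graphics::text(x, y, labels = g$text, col = g$col, cex = g$cex,
                          adj = g$adj))
  invisible(NULL)
}

#' Write a composed figure to PDF and/or PNG
#'
#' Both formats are drawn from the same glyph list: the PDF through the
#' vector device, the PNG rasterised at the requested resolution.
#'
#' @param layout A [compose_figure()] result.
#' @param out_dir Output directory (created if needed).
#' @param name Base file name without extension.
#' @param formats Subset of `c("pdf", "png")`.
#' @param page_mm Page size `c(width, height)` in mm.
#' @param dpi PNG resolution.
#' @return Character vector of the files written (invisibly).
#' @export
render_figure <- function(layout, out_dir = ".", name = "figure",
                          formats = c("pdf", "png"), page_mm = c(180, 240),
                          dpi = 300) {
  stopifnot(inherits(layout, "figure_layout"))
  if (length(formats) == 0L) stop("no output format requested", call. = FALSE)
  bad <- setdiff(tolower(formats), c("pdf", "png"))
  if (length(bad)) {
    stop(sprintf("unknown output format '%s'", bad[1]), call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  if (!dir.exists(out_dir)) stop("cannot create output directory",
                                 call. = FALSE)
  w_in <- page_mm[1] / 25.4; h_in <- page_mm[2] / 25.4
  paths <- character(0)
  for (f in unique(tolower(formats))) {
    path <- file.path(out_dir, paste0(name, ".", f))
    if (f == "pdf") {
      grDevices::pdf(path, width = w_in, height = h_in, useDingbats = FALSE)
    } else {
      grDevices::png(path, width = w_in, height = h_in, units = "in",
                     res = dpi, type = if (capabilities("cairo")) "cairo"
                     else getOption("bitmapType"))
    }
    ok <- FALSE
    tryCatch({
      draw_layout(layout)
      ok <- TRUE
    }, finally = {
      grDevices::dev.off()
      if (!ok && file.exists(path)) unlink(path)
    })
    paths <- c(paths, path)
  }
  invisible(paths)
}
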