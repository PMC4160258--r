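# Track renderers: typed records + a canvas_map -> glyph lists.
#
# Renderers are pure functions.  A glyph is a backend-neutral drawing
# primitive whose x coordinates are canvas units on [0, 1] and whose y
# coordinates are track-local units on [0, 1]; the figure assembler later
# maps track-local y into each track's vertical extent and a device backend
# turns glyphs into PDF/PNG drawing calls.  Determinism matters: identical
# records and spec must yield identical glyph lists, so all tie-breaks are
# explicit and nothing consults the RNG.

glyph <- function(shape, x, y, col = NA, fill = NA, lwd = 1, lty = 1,
                  pch = NA, cex = 1, text = NA, adj = NULL, alpha = 1,
                  layer = 1L) {
  stopifnot(shape %in% c("point", "rect", "arc", "polygon", "segment",
                         "line", "text"))
  structure(list(shape = shape, x = as.numeric(x), y = as.numeric(y),
                 col = col, fill = fill, lwd = lwd, lty = lty, pch = pch,
                 cex = cex, text = text, adj = adj, alpha = alpha,
                 layer = as.integer(layer)),
            class = "glyph")
}

legend_entry <- function(label, col, pch = NA, lty = NA, fill = NA) {
  stopifnot(is.character(label), nzchar(label))
  list(label = label, col = col, pch = pch, lty = lty, fill = fill)
}

rendered_track <- function(type, glyphs, legend = list(), y_axis = NULL,
                           y2_axis = NULL, n_rows = NULL, dropped = 0L,
                           label = NULL) {
  structure(list(type = type, glyphs = glyphs, legend = legend,
                 y_axis = y_axis, y2_axis = y2_axis, n_rows = n_rows,
                 dropped = dropped, label = label),
            class = "rendered_track")
}

# Colour ramp helper: vector of anchor colours -> function(t in [0,1]) -> hex.
make_ramp <- function(colors) {
  ramp <- grDevices::colorRamp(colors, space = "rgb")
  function(t) {
    t <- pmin(1, pmax(0, t))
    m <- ramp(t)
    grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
  }
}

# SNAP-convention LD colouring: 5 bins on r2 with edges (.2, .4, .6, .8),
# blue (low LD) to red (high LD).
default_r2_edges <- c(0.2, 0.4, 0.6, 0.8)
default_r2_colors <- c("#2C7BB6", "#ABD9E9", "#76C76F", "#FDAE61", "#D7191C")
no_r2_color <- "#555555"

r2_bin <- function(r2, edges = default_r2_edges) {
  # bin index 1..length(edges)+1; NA r2 -> NA
  findInterval(r2, edges, left.open = TRUE) + 1L
}

default_heat_ramp <- c("#FFFFFF", "#FEE0D2", "#FB6A4A", "#A50F15", "#67000D")
default_arc_ramp <- c("#C6DBEF", "#4292C6", "#08306B")
default_intensity_ramp <- c("#F7FBFF", "#6BAED6", "#08306B")

# Fallback state colours cycled by state-name sort order when the supplied
# table does not cover a state.
fallback_state_cycle <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3",
                          "#FF7F00", "#A65628", "#F781BF", "#999999")

default_state_colors <- c(
  "Promoter"    = "#D7191C",
  "Enhancer"    = "#FDAE61",
  "Transcribed" = "#1A9641",
  "Repressed"   = "#7B3294",
  "Quiescent"   = "#E0E0E0")

#' Render an association track (regional SNAP-style plot)
#'
#' One point per record inside a plotted region, at height
#' `-log10(pvalue)` scaled into `[0, 1]` by the track's y-maximum.  Typed
#' and imputed SNPs get different marker symbols; point colour encodes the
#' r2 bin against the index SNP; the index SNP (r2 == 1, or `id` matching
#' `spec$index_id`) is drawn last with a distinct marker and a text label.
#' Recombination rate, when present, is drawn as a line against a secondary
#' axis.
#'
#' @param recs `association_records` from [read_association()].
#' @param map A [build_canvas_map()] result.
#' @param spec Optional list of parameters: `y_max` (-log10 p axis
#'   maximum), `r2_edges`, `r2_colors`, `index_id`, `label`.
#' @return A `rendered_track` with legend entries and axis descriptors.
#' @export
render_association <- function(recs, map, spec = list()) {
  edges <- spec$r2_edges %||% default_r2_edges
  cols <- spec$r2_colors %||% default_r2_colors
  stopifnot(length(cols) == length(edges) + 1L)
  glyphs <- list()
  mlp <- -log10(recs$pvalue)
  x <- genome_to_canvas(map, recs$chrom, recs$pos)
  keep <- which(!is.na(x))
  dropped <- nrow(recs) - length(keep)
  y_max <- spec$y_max %||% max(4, ceiling(max(mlp[keep], 0)))
  is_index <- (!is.na(recs$r2) & recs$r2 == 1) |
    (!is.na(recs$id) & !is.null(spec$index_id) &
       recs$id %in% (spec$index_id %||% character(0)))
  # recombination overlay first (beneath the points)
  rec_max <- NULL
  kr <- keep[!is.na(recs$recomb[keep])]
  if (length(kr) > 1) {
    rec_max <- max(recs$recomb[kr])
    if (rec_max == 0) rec_max <- NULL
    if (!is.null(rec_max)) {
      # one polyline per region so the line never bridges a gap
      for (i in seq_len(n_regions(map$regions))) {
        r <- map$regions$regions[[i]]
        ir <- kr[recs$chrom[kr] == r$chrom &
                   recs$pos[kr] >= r$start & recs$pos[kr] <= r$end]
        ir <- ir[order(recs$pos[ir])]
        if (length(ir) > 1) {
          glyphs[[length(glyphs) + 1L]] <- glyph(
            "line", x[ir], recs$recomb[ir] / rec_max,
            col = "#6BAED6", lwd = 1, layer = 1L)
        }
      }
    }
  }
  ord <- keep[order(is_index[keep])]  # index SNP(s) drawn last
  for (k in ord) {
    bin <- if (is.na(recs$r2[k])) NA_integer_ else r2_bin(recs$r2[k], edges)
    col <- if (is.na(bin)) no_r2_color else cols[bin]
    typed <- if (is.na(recs$typed[k])) TRUE else recs$typed[k]
    pch <- if (is_index[k]) 23 else if (typed) 21 else 24
    glyphs[[length(glyphs) + 1L]] <- glyph(
      "point", x[k], min(mlp[k], y_max) / y_max,
      col = "#000000", fill = if (is_index[k]) "#9632B8" else col,
      pch = pch, cex = if (is_index[k]) 1.3 else 0.8, layer = 2L)
    if (is_index[k] && !is.na(recs$id[k])) {
      glyphs[[length(glyphs) + 1L]] <- glyph(
        "text", x[k], min(min(mlp[k], y_max) / y_max + 0.08, 1),
        text = recs$id[k], cex = 0.8, col = "#000000", layer = 3L)
    }
  }
  legend <- list()
  have_r2 <- any(!is.na(recs$r2[keep]))
  if (have_r2) {
    lo <- c(0, edges); hi <- c(edges, 1)
    for (b in seq_along(cols)) {
      legend[[length(legend) + 1L]] <- legend_entry(
        sprintf("r² %.1f-%.1f", lo[b], hi[b]), col = "#000000",
        pch = 21, fill = cols[b])
    }
  }
  if (any(!is.na(recs$typed[keep]))) {
    legend[[length(legend) + 1L]] <- legend_entry("typed SNP",
      col = "#000000", pch = 21, fill = "#FFFFFF")
    legend[[length(legend) + 1L]] <- legend_entry("imputed SNP",
      col = "#000000", pch = 24, fill = "#FFFFFF")
  }
  if (!is.null(rec_max)) {
    legend[[length(legend) + 1L]] <- legend_entry("recombination rate",
      col = "#6BAED6", lty = 1)
  }
  rendered_track("association", glyphs, legend = legend,
    y_axis = list(label = "-log10 p", range = c(0, y_max)),
    y2_axis = if (!is.null(rec_max))
      list(label = "recomb (cM/Mb)", range = c(0, rec_max)) else NULL,
    dropped = dropped, label = spec$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render an interval intensity track
#'
#' One full-height rectangle per clipped interval, filled by a colour ramp
#' over the min-max-normalised value.  When all values are equal the ramp
#' midpoint is used.
#'
#' @param recs `intensity_records` from [read_bed_like()].
#' @param map A [build_canvas_map()] result.
#' @param spec Optional list: `vmin`, `vmax` (fixed normalisation range),
#'   `palette` (vector of ramp anchor colours), `label`.
#' @return A `rendered_track`.
#' @export
render_intensity <- function(recs, map, spec = list()) {
  stopifnot(all(is.finite(recs$value)))
  ramp <- make_ramp(spec$palette %||% default_intensity_ramp)
  vmin <- spec$vmin %||% if (nrow(recs)) min(recs$value) else 0
  vmax <- spec$vmax %||% if (nrow(recs)) max(recs$value) else 1
  glyphs <- list()
  rs <- map$regions
  for (k in seq_len(nrow(recs))) {
    t <- if (vmax == vmin) 0.5 else (recs$value[k] - vmin) / (vmax - vmin)
    pieces <- clip_to_regions(rs, genomic_interval(recs$chrom[k],
                                                   recs$start[k],
                                                   recs$end[k]))
    for (p in pieces) {
      x0 <- genome_to_canvas(map, p$chrom, p$start)
      x1 <- genome_to_canvas(map, p$chrom, p$end)
      glyphs[[length(glyphs) + 1L]] <- glyph(
        "rect", c(x0, x1), c(0, 1), fill = ramp(t), col = NA, layer = 1L)
    }
  }
  lab <- spec$label %||% "intensity"
  legend <- list(
    legend_entry(sprintf("%s %s", lab, fmt_sig(vmin)), col = NA,
                 fill = ramp(0)),
    legend_entry(sprintf("%s %s", lab, fmt_sig(vmax)), col = NA,
                 fill = ramp(1)))
  rendered_track("intensity", glyphs, legend = legend, label = spec$label)
}

fmt_sig <- function(x) format(signif(x, 3), trim = TRUE)

#' Render a chromatin-state segmentation track
#'
#' One rectangle per clipped segment, coloured by state; abutting segments
#' with the same state are merged.  States missing from the colour table
#' get deterministic fallback colours assigned in state-name sort order.
#'
#' @param recs `segmentation_records` from [read_bed_like()].
#' @param map A [build_canvas_map()] result.
#' @param spec Optional list: `state_colors` (named colour vector),
#'   `label`.
#' @return A `rendered_track` with one legend entry per state present.
#' @export
render_segmentation <- function(recs, map, spec = list()) {
  table <- spec$state_colors %||% default_state_colors
  rs <- map$regions
  # clip each record, keeping plot order, then merge abutting same-state runs
  piece <- list()
  for (k in seq_len(nrow(recs))) {
    for (p in clip_to_regions(rs, genomic_interval(recs$chrom[k],
                                                   recs$start[k],
                                                   recs$end[k]))) {
      piece[[length(piece) + 1L]] <- list(chrom = p$chrom, start = p$start,
                                          end = p$end, state = recs$state[k])
    }
  }
  states_present <- unique(vapply(piece, `[[`, character(1), "state"))
  missing <- sort(setdiff(states_present, names(table)))
  if (length(missing)) {
    extra <- fallback_state_cycle[((seq_along(missing) - 1L) %%
                                     length(fallback_state_cycle)) + 1L]
    names(extra) <- missing
    table <- c(table, extra)
  }
  # merge abutting same-chrom same-state pieces
  merged <- list()
  for (p in piece) {
    m <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(m) && m$chrom == p$chrom && m$state == p$state &&
        m$end == p$start) {
      merged[[length(merged)]]$end <- p$end
    } else {
      merged[[length(merged) + 1L]] <- p
    }
  }
  glyphs <- lapply(merged, function(p) {
    glyph("rect",
          c(genome_to_canvas(map, p$chrom, p$start),
            genome_to_canvas(map, p$chrom, p$end)),
          c(0.05, 0.95), fill = unname(table[p$state]), col = NA, layer = 1L)
  })
  legend <- lapply(states_present, function(s) {
    legend_entry(s, col = NA, fill = unname(table[s]))
  })
  rendered_track("segmentation", glyphs, legend = legend,
                 label = spec$label)
}

#' Render interactions as arches
#'
#' Each interaction whose two anchor midpoints both map onto the canvas is
#' drawn as a semi-elliptical arch between the midpoints; the interaction
#' score (-log10 p) determines both the apex height (linear in score) and
#' the colour intensity.  Arches between regions span the inter-region gap.
#' Interactions with an unmappable anchor are dropped and counted.
#'
#' @param recs `interaction_records` from [read_interactions()].
#' @param map A [build_canvas_map()] result.
#' @param spec Optional list: `h_max` (apex of the highest-scoring arch, in
#'   track units, default 1), `score_max` (fixed normalisation), `palette`,
#'   `min_height` (apex used when all scores are zero, default 0.05),
#'   `label`.
#' @return A `rendered_track`.
#' @export
render_arcs <- function(recs, map, spec = list()) {
  h_max <- spec$h_max %||% 1
  stopifnot(h_max > 0, h_max <= 1)
  ramp <- make_ramp(spec$palette %||% default_arc_ramp)
  min_height <- spec$min_height %||% 0.05
  mid1 <- (recs$start1 + recs$end1) / 2
  mid2 <- (recs$start2 + recs$end2) / 2
  x1 <- genome_to_canvas(map, recs$chrom1, mid1)
  x2 <- genome_to_canvas(map, recs$chrom2, mid2)
  keep <- which(!is.na(x1) & !is.na(x2))
  dropped <- nrow(recs) - length(keep)
  if (dropped > 0) {
    message(sprintf("arcs: dropped %d interaction(s) with an unmappable anchor",
                    dropped))
  }
  score_max <- spec$score_max %||%
    if (length(keep)) max(recs$score[keep]) else 0
  glyphs <- lapply(keep, function(k) {
    s <- if (score_max > 0) recs$score[k] / score_max else NA
    apex <- if (is.na(s)) min_height else h_max * s
    glyph("arc", c(x1[k], x2[k]), c(0, apex),
          col = if (is.na(s)) ramp(0.5) else ramp(s), lwd = 1.2, layer = 2L)
  })
  legend <- list(legend_entry("interaction (-log10 p)",
                              col = ramp(0.9), lty = 1))
  rendered_track("arcs", glyphs, legend = legend, dropped = dropped,
                 y_axis = list(label = "-log10 p", range = c(0, score_max)),
                 label = spec$label)
}

# Greedy first-free-lane assignment over x-extents sorted by (start, input
# order).  Returns 1-based lane numbers in input order.
assign_lanes <- function(x0, x1, pad = 0) {
  n <- length(x0)
  lane <- integer(n)
  ord <- order(x0, seq_len(n))
  lane_end <- numeric(0)
  for (k in ord) {
    free <- which(lane_end <= x0[k] - pad)
    if (length(free)) {
      l <- free[1L]
    } else {
      l <- length(lane_end) + 1L
      lane_end <- c(lane_end, -Inf)
    }
    lane[k] <- l
    lane_end[l] <- x1[k]
  }
  lane
}

#' Render interactions as anchor blocks with connecting links
#'
#' Each interaction is drawn as two anchor rectangles joined by a
#' horizontal segment.  Overlapping links are stacked into lanes by greedy
#' first-fit on their x-extent (ties broken by start, then input order).
#'
#' @param recs `interaction_records` from [read_interactions()].
#' @param map A [build_canvas_map()] result.
#' @param spec Optional list: `color`, `label`.
#' @return A `rendered_track`; `n_rows` holds the lane count.
#' @export
render_links <- function(recs, map, spec = list()) {
  col <- spec$color %||% "#08519C"
  a1_0 <- genome_to_canvas(map, recs$chrom1, recs$start1)
  a1_1 <- genome_to_canvas(map, recs$chrom1, recs$end1)
  a2_0 <- genome_to_canvas(map, recs$chrom2, recs$start2)
  a2_1 <- genome_to_canvas(map, recs$chrom2, recs$end2)
  keep <- which(!is.na(a1_0) & !is.na(a1_1) & !is.na(a2_0) & !is.na(a2_1))
  dropped <- nrow(recs) - length(keep)
  if (dropped > 0) {
    message(sprintf("links: dropped %d interaction(s) with an unmappable anchor",
                    dropped))
  }
  ext0 <- pmin(a1_0, a2_0)[keep]
  ext1 <- pmax(a1_1, a2_1)[keep]
  lane <- assign_lanes(ext0, ext1)
  n_lanes <- max(lane, 0L)
  glyphs <- list()
  for (j in seq_along(keep)) {
    k <- keep[j]
    yc <- if (n_lanes == 0L) 0.5 else 1 - (lane[j] - 0.5) / n_lanes
    hh <- if (n_lanes == 0L) 0.3 else 0.35 / n_lanes
    glyphs[[length(glyphs) + 1L]] <- glyph("rect", c(a1_0[k], a1_1[k]),
                                           c(yc - hh, yc + hh),
                                           fill = col, col = NA, layer = 2L)
    glyphs[[length(glyphs) + 1L]] <- glyph("rect", c(a2_0[k], a2_1[k]),
                                           c(yc - hh, yc + hh),
                                           fill = col, col = NA, layer = 2L)
    glyphs[[length(glyphs) + 1L]] <- glyph("segment", c(ext0[j], ext1[j]),
                                           c(yc, yc), col = col, lwd = 0.8,
                                           layer = 1L)
  }
  legend <- list(legend_entry("interaction anchors", col = NA, fill = col))
  rendered_track("links", glyphs, legend = legend, n_rows = n_lanes,
                 dropped = dropped, label = spec$label)
}

#' Render binned contacts as a rotated-triangle heat map
#'
#' The contact matrix, restricted to bins whose midpoints fall inside the
#' plotted regions, is drawn in the rotated-triangle convention: each bin
#' pair (i, j) becomes a diamond centred at the x midpoint of the two bins,
#' raised in proportion to the bin separation `|i - j|`, coloured by a ramp
#' over `count / count_max`.  Zero counts are drawn in the background
#' colour; if all counts are zero the field is uniform background.
#'
#' @param recs `contact_records` from [read_contacts()].
#' @param map A [build_canvas_map()] result.
#' @param spec Optional list: `count_max` (fixed normalisation), `palette`,
#'   `background` colour, `label`.
#' @return A `rendered_track` with a colour-scale legend.
#' @export
render_heatmap <- function(recs, map, spec = list()) {
  bin_size <- attr(recs, "bin_size")
  stopifnot(!is.null(bin_size))
  ramp <- make_ramp(spec$palette %||% default_heat_ramp)
  bg <- spec$background %||% "#F0F0F0"
  m1 <- recs$bin1_start + bin_size / 2
  m2 <- recs$bin2_start + bin_size / 2
  xm1 <- genome_to_canvas(map, recs$chrom1, m1)
  xm2 <- genome_to_canvas(map, recs$chrom2, m2)
  keep <- which(!is.na(xm1) & !is.na(xm2))
  count_max <- spec$count_max %||%
    if (length(keep)) max(recs$count[keep]) else 0
  if (length(keep) == 0L) {
    return(rendered_track("heatmap", list(), label = spec$label))
  }
  d <- abs(recs$bin1_start[keep] - recs$bin2_start[keep]) / bin_size
  # same-chromosome separations set the vertical unit; inter-chromosomal
  # pairs (if any) are pinned to the top row
  intra <- recs$chrom1[keep] == recs$chrom2[keep]
  d_max <- max(d[intra], 1)
  d[!intra] <- d_max
  half_h <- 0.5 / (d_max + 1)
  half_w <- bin_size / map$bp_per_unit / 2
  glyphs <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    k <- keep[j]
    xc <- (xm1[k] + xm2[k]) / 2
    yc <- (d[j] + 0.5) * 2 * half_h
    t <- if (count_max > 0) recs$count[k] / count_max else 0
    fill <- if (recs$count[k] == 0 || count_max == 0) bg else ramp(t)
    glyphs[[j]] <- glyph("polygon",
                         c(xc - half_w, xc, xc + half_w, xc),
                         c(yc, yc + half_h, yc, yc - half_h),
                         fill = fill, col = NA, layer = 1L)
  }
  legend <- list(
    legend_entry("contacts 0", col = NA, fill = bg),
    legend_entry(sprintf("contacts %s", fmt_sig(count_max)), col = NA,
                 fill = ramp(1)))
  rendered_track("heatmap", glyphs, legend = legend,
                 y_axis = list(label = "bin separation",
                               range = c(0, d_max + 1)),
                 label = spec$label)
}

# Approximate text width in canvas units (backend-neutral, deterministic).
label_width <- function(text, cex = 1) 0.0062 * nchar(text) * cex

#' Render gene models
#'
#' Each gene is drawn as a thin transcript line, tall exon rectangles,
#' strand chevrons along the introns and its name to the left of the body
#' (or to the right when the left edge is clipped).  Genes are packed into
#' horizontal rows by greedy first-fit on the x-extent of label plus body,
#' so no two genes in a row overlap; the row count is reported so the
#' assembler can scale the track height.
#'
#' @param models `gene_models` from [read_genes()].
#' @param map A [build_canvas_map()] result.
#' @param spec Optional list: `color`, `label`, `name_cex`.
#' @return A `rendered_track` with `n_rows` set.
#' @export
render_genes <- function(models, map, spec = list()) {
  col <- spec$color %||% "#333333"
  name_cex <- spec$name_cex %||% 0.7
  rs <- map$regions
  n <- nrow(models)
  body0 <- numeric(n); body1 <- numeric(n); drawn <- logical(n)
  piece_list <- vector("list", n)
  for (k in seq_len(n)) {
    pieces <- clip_to_regions(rs, genomic_interval(models$chrom[k],
                                                   models$tx_start[k],
                                                   models$tx_end[k]))
    piece_list[[k]] <- pieces
    if (length(pieces)) {
      xs <- unlist(lapply(pieces, function(p)
        genome_to_canvas(map, p$chrom, c(p$start, p$end))))
      body0[k] <- min(xs); body1[k] <- max(xs)
      drawn[k] <- TRUE
    }
  }
  idx <- which(drawn)
  dropped <- n - length(idx)
  # label goes left of the body unless that would leave the panel
  lw <- label_width(models$name, name_cex) + 0.005
  label_left <- (body0 - lw) >= 0
  ext0 <- ifelse(label_left, body0 - lw, body0)
  ext1 <- ifelse(label_left, body1, body1 + lw)
  lane <- assign_lanes(ext0[idx], ext1[idx], pad = 0.002)
  n_rows <- max(lane, 1L)
  glyphs <- list()
  row_h <- 1 / n_rows
  for (j in seq_along(idx)) {
    k <- idx[j]
    yc <- 1 - (lane[j] - 0.5) * row_h
    exon_hh <- 0.28 * row_h
    for (p in piece_list[[k]]) {
      p0 <- genome_to_canvas(map, p$chrom, p$start)
      p1 <- genome_to_canvas(map, p$chrom, p$end)
      glyphs[[length(glyphs) + 1L]] <- glyph("segment", c(p0, p1), c(yc, yc),
                                             col = col, lwd = 0.8, layer = 1L)
      # strand chevrons spaced along the clipped body
      n_ch <- max(1L, floor((p1 - p0) / 0.03))
      ch_x <- p0 + (seq_len(n_ch) - 0.5) / n_ch * (p1 - p0)
      glyphs[[length(glyphs) + 1L]] <- glyph(
        "text", ch_x, rep(yc, n_ch),
        text = if (models$strand[k] == "+") ">" else "<",
        cex = 0.45, col = col, layer = 2L)
      # exons clipped to this piece
      es <- models$exon_starts[[k]]; ee <- models$exon_ends[[k]]
      for (e in seq_along(es)) {
        s <- max(es[e], p$start); t <- min(ee[e], p$end)
        if (s < t) {
          glyphs[[length(glyphs) + 1L]] <- glyph(
            "rect",
            c(genome_to_canvas(map, p$chrom, s),
              genome_to_canvas(map, p$chrom, t)),
            c(yc - exon_hh, yc + exon_hh), fill = col, col = NA, layer = 3L)
        }
      }
    }
    glyphs[[length(glyphs) + 1L]] <- glyph(
      "text",
      if (label_left[k]) body0[k] - 0.003 else body1[k] + 0.003, yc,
      text = models$name[k], cex = name_cex, col = col,
      adj = if (label_left[k]) 1 else 0, layer = 4L)
  }
  rendered_track("genes", glyphs, n_rows = n_rows, dropped = dropped,
                 label = spec$label)
}

#' Render manual feature annotations
#'
#' `highlight-box` becomes a translucent full-height rectangle beneath all
#' data layers; `vertical-marker` a dashed full-height line plus label;
#' `bracket` a bracket over the interval with a centred label; `text` a
#' label at the position.  Annotations wholly outside the plotted regions
#' are skipped with a warning.
#'
#' @param anns `annotation_records` from [read_annotations()].
#' @param map A [build_canvas_map()] result.
#' @param spec Optional list: `box_fill`, `color`, `label`.
#' @return A `rendered_track`.
#' @export
render_annotations <- function(anns, map, spec = list()) {
  box_fill <- spec$box_fill %||% "#FFD70055"
  col <- spec$color %||% "#B22222"
  glyphs <- list()
  skipped <- 0L
  rs <- map$regions
  for (k in seq_len(nrow(anns))) {
    kind <- anns$kind[k]
    if (kind %in% c("vertical-marker", "text")) {
      x <- genome_to_canvas(map, anns$chrom[k], anns$start[k])
      if (is.na(x)) { skipped <- skipped + 1L; next }
      if (kind == "vertical-marker") {
        glyphs[[length(glyphs) + 1L]] <- glyph("segment", c(x, x), c(0, 0.88),
                                               col = col, lty = 2, lwd = 1,
                                               layer = 2L)
        glyphs[[length(glyphs) + 1L]] <- glyph("text", x, 0.94,
                                               text = anns$label[k],
                                               cex = 0.75, col = col,
                                               layer = 3L)
      } else {
        glyphs[[length(glyphs) + 1L]] <- glyph("text", x, 0.5,
                                               text = anns$label[k],
                                               cex = 0.8, col = col,
                                               layer = 3L)
      }
    } else {
      pieces <- clip_to_regions(rs, genomic_interval(anns$chrom[k],
                                                     anns$start[k],
                                                     anns$end[k]))
      if (length(pieces) == 0L) { skipped <- skipped + 1L; next }
      for (p in pieces) {
        x0 <- genome_to_canvas(map, p$chrom, p$start)
        x1 <- genome_to_canvas(map, p$chrom, p$end)
        if (kind == "highlight-box") {
          glyphs[[length(glyphs) + 1L]] <- glyph("rect", c(x0, x1), c(0, 1),
                                                 fill = box_fill, col = NA,
                                                 layer = 0L)
          if (nzchar(anns$label[k])) {
            glyphs[[length(glyphs) + 1L]] <- glyph("text", (x0 + x1) / 2, 0.96,
                                                   text = anns$label[k],
                                                   cex = 0.7, col = col,
                                                   layer = 3L)
          }
        } else {  # bracket
          yb <- 0.35
          glyphs[[length(glyphs) + 1L]] <- glyph("line",
                                                 c(x0, x0, x1, x1),
                                                 c(yb - 0.12, yb, yb,
                                                   yb - 0.12),
                                                 col = col, lwd = 1,
                                                 layer = 2L)
          glyphs[[length(glyphs) + 1L]] <- glyph("text", (x0 + x1) / 2,
                                                 yb + 0.25,
                                                 text = anns$label[k],
                                                 cex = 0.75, col = col,
                                                 layer = 3L)
        }
      }
    }
  }
  if (skipped > 0L) {
    warning(sprintf("annotations: %d feature(s) outside all plotted regions skipped",
                    skipped), call. = FALSE)
  }
  rendered_track("annotations", glyphs, dropped = skipped,
                 label = spec$label)
}
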