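# Genome <-> canvas coordinate machinery.
#
# All horizontal placement in a figure goes through a canvas_map: an exact,
# shared-scale mapping of one or more genomic regions onto the abstract
# horizontal interval [0, 1].  Every region is drawn at the same number of
# base pairs per canvas unit, so two loci that are megabases apart -- or on
# different chromosomes -- can be compared visually at identical scale.
# Intervals follow the BED convention: 0-based, half-open [start, end).

#' Create a genomic interval
#'
#' Intervals are 0-based, half-open `[start, end)`, the BED convention.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start Start position in bp (0-based, inclusive).
#' @param end End position in bp (exclusive); must exceed `start`.
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr8", 128e6, 128.5e6)
#' @export
genomic_interval <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) ||
      !nzchar(chrom)) {
    stop("chrom must be a non-empty string", call. = FALSE)
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    stop("start and end must be single numbers", call. = FALSE)
  }
  if (start >= end) {
    stop(sprintf("start >= end (%s:%s-%s)", chrom,
                 format(start, scientific = FALSE),
                 format(end, scientific = FALSE)), call. = FALSE)
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%s-%s (%s bp)>\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              format(x$end - x$start, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

iv_width <- function(iv) iv$end - iv$start

#' Create an ordered set of plotted regions
#'
#' The list order is the left-to-right plot order; regions are deliberately
#' not sorted by chromosome so that the user controls the narrative order.
#' Regions on the same chromosome must not overlap.
#'
#' @param regions List of [genomic_interval()] objects (at least one).
#' @param labels Optional character vector of display names, one per region
#'   (e.g. cytoband names such as `"8q24.21"`).
#' @return An object of class `region_set`.
#' @export
region_set <- function(regions, labels = NULL) {
  if (inherits(regions, "genomic_interval")) regions <- list(regions)
  if (!is.list(regions) || length(regions) == 0L ||
      !all(vapply(regions, inherits, logical(1), "genomic_interval"))) {
    stop("regions must be a non-empty list of genomic_interval objects",
         call. = FALSE)
  }
  n <- length(regions)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) {
      stop("labels must have one entry per region", call. = FALSE)
    }
  }
  # same-chromosome regions must not overlap (half-open: abutting is fine)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        a <- regions[[i]]; b <- regions[[j]]
        if (a$chrom == b$chrom && a$start < b$end && b$start < a$end) {
          stop(sprintf("regions %d and %d overlap on %s", i, j, a$chrom),
               call. = FALSE)
        }
      }
    }
  }
  structure(list(regions = regions, labels = labels), class = "region_set")
}

n_regions <- function(rs) length(rs$regions)

region_labels <- function(rs) {
  if (!is.null(rs$labels)) return(rs$labels)
  vapply(rs$regions, function(r) {
    sprintf("%s:%s-%s", r$chrom,
            format(r$start, big.mark = ",", scientific = FALSE),
            format(r$end, big.mark = ",", scientific = FALSE))
  }, character(1))
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set with %d region(s):\n", n_regions(x)))
  lab <- region_labels(x)
  for (i in seq_len(n_regions(x))) {
    r <- x$regions[[i]]
    cat(sprintf("  [%d] %s  %s:%s-%s\n", i, lab[i], r$chrom,
                format(r$start, scientific = FALSE),
                format(r$end, scientific = FALSE)))
  }
  invisible(x)
}

strip_eol <- function(lines) sub("\r$", "", lines)

#' Parse a region file
#'
#' The region file is tab-delimited with columns `chrom`, `start`, `end` and
#' an optional fourth `label` column.  Lines starting with `#` and blank
#' lines are skipped.  Coordinates are 0-based half-open.
#'
#' @param path Path to the region file.
#' @return A [region_set()].
#' @export
parse_region_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("region file '%s' not found", path), call. = FALSE)
  }
  parse_region_lines(strip_eol(readLines(path, warn = FALSE)))
}

parse_region_lines <- function(lines) {
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("region file contains no regions", call. = FALSE)
  regions <- vector("list", length(keep))
  labels <- character(length(keep))
  has_label <- FALSE
  for (k in seq_along(keep)) {
    ln <- keep[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("region file line %d: expected >= 3 tab-separated columns",
                   ln), call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start != floor(start) ||
        end != floor(end)) {
      stop(sprintf("region file line %d: malformed integer coordinate", ln),
           call. = FALSE)
    }
    if (start >= end) {
      stop(sprintf("region file line %d: start >= end", ln), call. = FALSE)
    }
    regions[[k]] <- genomic_interval(f[1], start, end)
    if (length(f) >= 4L && nzchar(f[4])) {
      labels[k] <- f[4]
      has_label <- TRUE
    }
  }
  # overlap check with line-number diagnostics
  for (i in seq_along(regions)) {
    for (j in seq_along(regions)) {
      if (i < j) {
        a <- regions[[i]]; b <- regions[[j]]
        if (a$chrom == b$chrom && a$start < b$end && b$start < a$end) {
          stop(sprintf(
            "region file lines %d and %d: same-chromosome regions overlap",
            keep[i], keep[j]), call. = FALSE)
        }
      }
    }
  }
  region_set(regions, labels = if (has_label) labels else NULL)
}

#' Build the shared-scale canvas map for a region set
#'
#' The horizontal canvas is the abstract interval `[0, 1]`.  A fixed gap is
#' placed between consecutive regions and the remaining width is divided
#' among the regions in exact proportion to their genomic widths, so every
#' region is drawn at the same number of base pairs per canvas unit.
#'
#' @param rs A [region_set()].
#' @param gap Inter-region gap in canvas units (default 0.05).
#' @return An object of class `canvas_map` with elements `regions` (the
#'   region set), `segments` (n x 2 matrix of canvas extents), `gap` and
#'   `bp_per_unit`.
#' @export
build_canvas_map <- function(rs, gap = 0.05) {
  stopifnot(inherits(rs, "region_set"))
  n <- n_regions(rs)
  if (n == 1L) gap <- 0
  if (gap < 0 || gap * (n - 1L) >= 1) {
    stop(sprintf("gap %g too large for %d region(s)", gap, n), call. = FALSE)
  }
  widths <- vapply(rs$regions, iv_width, numeric(1))
  total_bp <- sum(widths)
  avail <- 1 - gap * (n - 1L)
  bp_per_unit <- total_bp / avail
  seg_w <- widths / bp_per_unit
  x0 <- cumsum(c(0, head(seg_w, -1L) + gap))
  segments <- cbind(x0 = x0, x1 = x0 + seg_w)
  # pin the last edge against accumulated floating-point drift
  segments[n, 2L] <- 1
  structure(list(regions = rs, segments = segments, gap = gap,
                 bp_per_unit = bp_per_unit),
            class = "canvas_map")
}

#' @export
print.canvas_map <- function(x, ...) {
  cat(sprintf("canvas_map: %d region(s), gap %g, %s bp per canvas unit\n",
              n_regions(x$regions), x$gap,
              format(x$bp_per_unit, digits = 6)))
  invisible(x)
}

#' Map genomic positions to canvas x coordinates
#'
#' Positions falling inside a plotted region (including both ends, so that
#' point data sitting exactly on a region edge is never dropped) map
#' linearly into that region's canvas segment; all other positions map to
#' `NA`.
#'
#' @param map A [build_canvas_map()] result.
#' @param chrom Chromosome name(s); recycled against `pos`.
#' @param pos Base positions (0-based bp).
#' @return Numeric vector of canvas x in `[0, 1]`, `NA` where unmappable.
#' @export
genome_to_canvas <- function(map, chrom, pos) {
  stopifnot(inherits(map, "canvas_map"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  out <- rep(NA_real_, n)
  rs <- map$regions
  for (i in seq_len(n_regions(rs))) {
    r <- rs$regions[[i]]
    hit <- which(is.na(out) & chrom == r$chrom & pos >= r$start & pos <= r$end)
    if (length(hit)) {
      x0 <- map$segments[i, 1L]; x1 <- map$segments[i, 2L]
      out[hit] <- x0 + (pos[hit] - r$start) * (x1 - x0) / (r$end - r$start)
    }
  }
  out
}

#' Map canvas x coordinates back to genomic positions
#'
#' The inverse of [genome_to_canvas()] on region segment interiors; canvas
#' positions inside an inter-region gap return `NA`.
#'
#' @param map A [build_canvas_map()] result.
#' @param x Canvas coordinates in `[0, 1]`.
#' @return A data.frame with columns `chrom` (character, `NA` in gaps) and
#'   `pos` (numeric bp, possibly fractional).
#' @export
canvas_to_genome <- function(map, x) {
  stopifnot(inherits(map, "canvas_map"))
  x <- as.numeric(x)
  if (any(is.na(x)) || any(x < 0 | x > 1)) {
    stop("canvas coordinates must lie in [0, 1]", call. = FALSE)
  }
  chrom <- rep(NA_character_, length(x))
  pos <- rep(NA_real_, length(x))
  rs <- map$regions
  for (i in seq_len(n_regions(rs))) {
    r <- rs$regions[[i]]
    x0 <- map$segments[i, 1L]; x1 <- map$segments[i, 2L]
    hit <- which(is.na(chrom) & x >= x0 & x <= x1)
    if (length(hit)) {
      chrom[hit] <- r$chrom
      pos[hit] <- r$start + (x[hit] - x0) * (r$end - r$start) / (x1 - x0)
    }
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Clip an interval to the plotted regions
#'
#' Features straddling a region edge are truncated at the edge rather than
#' dropped, preserving base-pair alignment of what remains visible.
#'
#' @param rs A [region_set()].
#' @param iv A [genomic_interval()].
#' @return List of `genomic_interval` pieces in plot order (possibly empty).
#' @export
clip_to_regions <- function(rs, iv) {
  stopifnot(inherits(rs, "region_set"), inherits(iv, "genomic_interval"))
  out <- list()
  for (i in seq_len(n_regions(rs))) {
    r <- rs$regions[[i]]
    if (r$chrom == iv$chrom) {
      s <- max(r$start, iv$start)
      e <- min(r$end, iv$end)
      if (s < e) out[[length(out) + 1L]] <- genomic_interval(iv$chrom, s, e)
    }
  }
  out
}

#' Specify a zoom sub-region
#'
#' @param target A [genomic_interval()], the sub-region to magnify.
#' @param rs The [region_set()] of the main panel (used to locate the
#'   parent region).
#' @param parent_index Optional index of the containing main-panel region;
#'   found automatically when omitted.
#' @return An object of class `zoom_spec`.
#' @export
zoom_spec <- function(target, rs, parent_index = NULL) {
  stopifnot(inherits(target, "genomic_interval"), inherits(rs, "region_set"))
  contains <- function(r) {
    r$chrom == target$chrom && r$start <= target$start && target$end <= r$end
  }
  if (is.null(parent_index)) {
    idx <- which(vapply(rs$regions, contains, logical(1)))
    if (length(idx) == 0L) {
      stop("zoom target is not contained in any plotted region", call. = FALSE)
    }
    parent_index <- idx[1L]
  } else {
    if (!contains(rs$regions[[parent_index]])) {
      stop("zoom target is not contained in regions[[parent_index]]",
           call. = FALSE)
    }
  }
  parent <- rs$regions[[parent_index]]
  if (iv_width(target) >= iv_width(parent)) {
    stop("zoom target must be strictly smaller than its parent region",
         call. = FALSE)
  }
  structure(list(target = target, parent_index = parent_index),
            class = "zoom_spec")
}

#' Build the zoom panel's canvas map and connector geometry
#'
#' The zoom panel is a single-region canvas spanning `[0, 1]` for the zoom
#' target, so its bp-per-unit is strictly smaller (i.e. magnified).  The
#' connector records where the target sits on the main panel -- the exact
#' `genome_to_canvas` images of its endpoints -- and the zoom panel's full
#' width, defining the trapezoid drawn between the panels.
#'
#' @param map Main-panel [build_canvas_map()] result.
#' @param zoom A [zoom_spec()] valid against `map`'s regions.
#' @return A list with `map` (the zoom panel's `canvas_map`) and `connector`
#'   (list with `main = c(x_left, x_right)` on the main canvas and
#'   `zoom = c(0, 1)`).
#' @export
build_zoom_map <- function(map, zoom) {
  stopifnot(inherits(map, "canvas_map"), inherits(zoom, "zoom_spec"))
  tgt <- zoom$target
  x_left <- genome_to_canvas(map, tgt$chrom, tgt$start)
  x_right <- genome_to_canvas(map, tgt$chrom, tgt$end)
  if (is.na(x_left) || is.na(x_right)) {
    stop("zoom target does not map onto the main canvas", call. = FALSE)
  }
  zmap <- build_canvas_map(region_set(list(tgt)), gap = 0)
  list(map = zmap,
       connector = list(main = c(x_left, x_right), zoom = c(0, 1)))
}
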