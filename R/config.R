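# Configuration file and pipeline driver.
#
# The YAML configuration file is the offline twin of a menu-based
# interface: every figure-level and track-level parameter has a key, the
# schema is closed (unknown keys are an error naming the key path, not
# silently ignored) and all defaults are resolved up front and echoed to
# the log so a run is fully reproducible from its log alone.

config_schema <- list(
  top = c("region_file", "tracks", "zoom", "figure", "log_level", "seed"),
  track = c("type", "path", "height", "letter", "label", "params"),
  zoom = c("chrom", "start", "end", "tracks"),
  figure = c("title", "width_mm", "height_mm", "formats", "dpi", "gap"))

track_param_names <- list(
  association = c("y_max", "r2_edges", "r2_colors", "index_id"),
  intensity = c("vmin", "vmax", "palette"),
  segmentation = c("state_colors"),
  arcs = c("h_max", "score_max", "palette", "min_height"),
  links = c("color"),
  heatmap = c("bin_size", "count_max", "palette", "background"),
  genes = c("color", "name_cex"),
  annotations = c("box_fill", "color"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown configuration key '%s%s'", where, bad[1]),
         call. = FALSE)
  }
}

need_key <- function(x, key, where) {
  if (is.null(x[[key]])) {
    stop(sprintf("missing mandatory configuration key '%s%s'", where, key),
         call. = FALSE)
  }
  x[[key]]
}

validate_track_entry <- function(tr, where) {
  check_keys(tr, config_schema$track, where)
  type <- need_key(tr, "type", where)
  if (!type %in% track_types) {
    stop(sprintf("%stype: unknown track type '%s' (must be one of %s)",
                 where, type, paste(track_types, collapse = ", ")),
         call. = FALSE)
  }
  need_key(tr, "path", where)
  params <- tr$params %||% list()
  check_keys(params, track_param_names[[type]], paste0(where, "params."))
  if (type == "heatmap" && is.null(params$bin_size)) {
    stop(sprintf("missing mandatory configuration key '%sparams.bin_size'",
                 where), call. = FALSE)
  }
  track_spec(type, path = tr$path, height = tr$height %||% 1,
             letter = tr$letter, label = tr$label %||% type,
             params = params)
}

#' Parse and validate a figure configuration file
#'
#' @param path Path to the YAML configuration.
#' @return An object of class `run_config`: fully validated, with every
#'   default resolved.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file '%s' not found", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  check_keys(raw, config_schema$top, "")
  region_file <- need_key(raw, "region_file", "")
  tracks_raw <- need_key(raw, "tracks", "")
  if (length(tracks_raw) == 0L) {
    stop("configuration must define at least one track", call. = FALSE)
  }
  tracks <- lapply(seq_along(tracks_raw), function(i) {
    validate_track_entry(tracks_raw[[i]], sprintf("tracks[%d].", i))
  })
  zoom <- NULL; zoom_tracks <- list()
  if (!is.null(raw$zoom)) {
    check_keys(raw$zoom, config_schema$zoom, "zoom.")
    zoom <- list(chrom = need_key(raw$zoom, "chrom", "zoom."),
                 start = need_key(raw$zoom, "start", "zoom."),
                 end = need_key(raw$zoom, "end", "zoom."))
    zt <- raw$zoom$tracks
    zoom_tracks <- if (is.null(zt)) tracks else {
      lapply(seq_along(zt), function(i) {
        validate_track_entry(zt[[i]], sprintf("zoom.tracks[%d].", i))
      })
    }
  }
  fig_raw <- raw$figure %||% list()
  check_keys(fig_raw, config_schema$figure, "figure.")
  formats <- unlist(fig_raw$formats %||% list("pdf", "png"))
  bad_fmt <- setdiff(tolower(formats), c("pdf", "png"))
  if (length(bad_fmt)) {
    stop(sprintf("figure.formats: unknown format '%s'", bad_fmt[1]),
         call. = FALSE)
  }
  log_level <- raw$log_level %||% "info"
  if (!log_level %in% names(log_levels)) {
    stop(sprintf("log_level: unknown level '%s'", log_level), call. = FALSE)
  }
  structure(list(
    region_file = region_file,
    tracks = tracks,
    zoom = zoom,
    zoom_tracks = zoom_tracks,
    figure = list(title = fig_raw$title,
                  width_mm = fig_raw$width_mm %||% 180,
                  height_mm = fig_raw$height_mm %||% 240,
                  formats = tolower(formats),
                  dpi = fig_raw$dpi %||% 300,
                  gap = fig_raw$gap %||% 0.05),
    log_level = log_level,
    seed = raw$seed %||% NA,
    base_dir = dirname(normalizePath(path, mustWork = TRUE))),
    class = "run_config")
}

log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

log_msg <- function(level, fmt, ..., threshold = "info") {
  if (log_levels[[level]] >= log_levels[[threshold]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

resolve_path <- function(path, base_dir) {
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(base_dir, path)
}

read_track_data <- function(spec, base_dir, permissive = FALSE) {
  path <- resolve_path(spec$path, base_dir)
  if (!file.exists(path)) {
    stop(sprintf("track file '%s' not found", path), call. = FALSE)
  }
  reader <- switch(spec$type,
    association = read_association,
    intensity = function(p) read_bed_like(p, "intensity"),
    segmentation = function(p) read_bed_like(p, "segmentation"),
    arcs = read_interactions,
    links = read_interactions,
    heatmap = function(p) read_contacts(p, spec$params$bin_size),
    genes = read_genes,
    annotations = read_annotations)
  if (!permissive) return(reader(path))
  read_permissive(reader, path)
}

# Permissive mode: repeatedly drop the line named in the parse error until
# the file parses, warning once per dropped line.
read_permissive <- function(reader, path) {
  lines <- strip_eol(readLines(path, warn = FALSE))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  dropped <- 0L
  repeat {
    writeLines(lines, tmp)
    res <- tryCatch(reader(tmp), error = function(e) e)
    if (!inherits(res, "error")) {
      if (dropped > 0L) {
        warning(sprintf("%s: dropped %d unparseable line(s)", path, dropped),
                call. = FALSE)
      }
      return(res)
    }
    m <- regmatches(conditionMessage(res),
                    regexpr("line [0-9]+", conditionMessage(res)))
    if (length(m) == 0L) stop(res)
    ln <- as.integer(sub("line ", "", m))
    lines[ln] <- "# dropped"
    dropped <- dropped + 1L
    if (dropped > length(lines)) stop(res)  # safety
  }
}

render_track <- function(spec, data, map) {
  spec$params$label <- spec$params$label %||% spec$label
  switch(spec$type,
    association = render_association(data, map, spec$params),
    intensity = render_intensity(data, map, spec$params),
    segmentation = render_segmentation(data, map, spec$params),
    arcs = render_arcs(data, map, spec$params),
    links = render_links(data, map, spec$params),
    heatmap = render_heatmap(data, map, spec$params),
    genes = render_genes(data, map, spec$params),
    annotations = render_annotations(data, map, spec$params))
}

#' Build a figure from a validated configuration
#'
#' Runs parse -> map -> render -> assemble without touching any output
#' device; [run()] adds file output around this.
#'
#' @param config A [parse_config()] result.
#' @param permissive Drop unparseable data lines with a warning instead of
#'   failing.
#' @return A list with the `figure_layout`, the canvas maps and per-track
#'   record counts.
#' @export
build_figure <- function(config, permissive = FALSE) {
  stopifnot(inherits(config, "run_config"))
  thr <- config$log_level
  rs <- parse_region_file(resolve_path(config$region_file, config$base_dir))
  map <- build_canvas_map(rs, gap = config$figure$gap)
  log_msg("info", "mapped %d region(s) at %.1f bp per canvas unit",
          n_regions(rs), map$bp_per_unit, threshold = thr)
  counts <- list()
  rendered_main <- lapply(config$tracks, function(sp) {
    data <- read_track_data(sp, config$base_dir, permissive)
    r <- render_track(sp, data, map)
    counts[[sp$label]] <<- c(records = nrow(data), dropped = r$dropped)
    log_msg("info", "track '%s' (%s): %d record(s), %d dropped",
            sp$label, sp$type, nrow(data), r$dropped, threshold = thr)
    r
  })
  zoom <- NULL
  if (!is.null(config$zoom)) {
    zs <- zoom_spec(genomic_interval(config$zoom$chrom, config$zoom$start,
                                     config$zoom$end), rs)
    zm <- build_zoom_map(map, zs)
    log_msg("info", "zoom %s:%d-%d magnified %.1fx",
            config$zoom$chrom, config$zoom$start, config$zoom$end,
            map$bp_per_unit / zm$map$bp_per_unit, threshold = thr)
    rendered_zoom <- lapply(config$zoom_tracks, function(sp) {
      data <- read_track_data(sp, config$base_dir, permissive)
      render_track(sp, data, zm$map)
    })
    zoom <- list(map = zm$map, connector = zm$connector,
                 rendered = rendered_zoom,
                 heights = vapply(config$zoom_tracks, `[[`, numeric(1),
                                  "height"))
  }
  letters <- assign_letters(lapply(config$tracks, `[[`, "letter"),
                            lapply(config$zoom_tracks, `[[`, "letter"))
  layout <- compose_figure(map, rendered_main,
                           heights_main = vapply(config$tracks, `[[`,
                                                 numeric(1), "height"),
                           title = config$figure$title, zoom = zoom,
                           letters = letters)
  list(layout = layout, map = map, zoom = zoom, counts = counts)
}

#' Run a figure build end to end
#'
#' Parses every input named in the configuration, renders and assembles
#' the figure and writes one output file per requested format.  On any
#' error, partial outputs are removed before the error propagates.
#'
#' @param config A [parse_config()] result or the path of a configuration
#'   file.
#' @param out_dir Output directory.
#' @param name Base name of the output files.
#' @param permissive Drop unparseable data lines with a warning.
#' @return Character vector of written file paths (invisibly).
#' @export
run <- function(config, out_dir = ".", name = "figure",
                permissive = FALSE) {
  if (is.character(config)) config <- parse_config(config)
  thr <- config$log_level
  log_msg("info", "effective config: %s", effective_config_string(config),
          threshold = thr)
  targets <- file.path(out_dir, paste0(name, ".", config$figure$formats))
  ok <- FALSE
  on.exit(if (!ok) unlink(targets[file.exists(targets)]))
  built <- build_figure(config, permissive = permissive)
  paths <- render_figure(built$layout, out_dir = out_dir, name = name,
                         formats = config$figure$formats,
                         page_mm = c(config$figure$width_mm,
                                     config$figure$height_mm),
                         dpi = config$figure$dpi)
  ok <- TRUE
  for (p in paths) log_msg("info", "wrote %s", p, threshold = thr)
  invisible(paths)
}

effective_config_string <- function(config) {
  f <- config$figure
  sprintf(paste0("region_file=%s tracks=%d zoom=%s width_mm=%g height_mm=%g ",
                 "formats=%s dpi=%g gap=%g log_level=%s"),
          config$region_file, length(config$tracks),
          if (is.null(config$zoom)) "none" else
            sprintf("%s:%d-%d", config$zoom$chrom, config$zoom$start,
                    config$zoom$end),
          f$width_mm, f$height_mm, paste(f$formats, collapse = ","), f$dpi,
          f$gap, config$log_level)
}
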