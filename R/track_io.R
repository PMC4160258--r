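# Readers and writers for the tab-delimited track dialects.
#
# All dialects share the house rules: tab-delimited UTF-8, '#' comment lines
# and blank lines skipped, LF or CRLF endings accepted, records kept in file
# order, and every diagnostic carries the 1-based line number of the
# offending line.  Interval dialects are 0-based half-open; single-position
# association records carry 1-based positions in the file and are converted
# to 0-based internally.

# Split a file into data lines while remembering original line numbers.
read_data_lines <- function(path) {
  lines <- strip_eol(readLines(path, warn = FALSE))
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  list(lines = lines[keep], lineno = keep)
}

split_tabs <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

num_or_stop <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    stop(sprintf("line %d: non-numeric %s '%s'", lineno, what,
                 x[which(is.na(v))[1]]), call. = FALSE)
  }
  v
}

int_or_stop <- function(x, what, lineno) {
  v <- num_or_stop(x, what, lineno)
  if (any(v != floor(v))) {
    stop(sprintf("line %d: %s must be an integer", lineno, what),
         call. = FALSE)
  }
  v
}

looks_numeric <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read an association (regional GWAS) file
#'
#' Tab-delimited columns: `chrom`, `pos` (1-based bp), `pvalue`, then
#' optionally `typed` (T/F or typed/imputed), `r2` (LD with the index SNP,
#' in `[0, 1]`), `recomb` (recombination rate, cM/Mb) and `id` (SNP name).
#' A first line whose position column is non-numeric is treated as a header
#' and skipped.  Positions are converted to 0-based internally.
#'
#' @param path Path to the file.
#' @return A data.frame of class `association_records` with columns `chrom`,
#'   `pos` (0-based), `pvalue`, `typed` (logical, `NA` when absent), `r2`,
#'   `recomb`, `id`.
#' @export
read_association <- function(path) {
  d <- read_data_lines(path)
  if (length(d$lines) == 0L) return(empty_association())
  first <- split_tabs(d$lines[1])
  if (length(first) >= 2L && !looks_numeric(first[2])) {
    d$lines <- d$lines[-1L]
    d$lineno <- d$lineno[-1L]
  }
  n <- length(d$lines)
  chrom <- character(n); pos <- numeric(n); pvalue <- numeric(n)
  typed <- rep(NA, n); r2 <- rep(NA_real_, n); recomb <- rep(NA_real_, n)
  id <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    f <- split_tabs(d$lines[k]); ln <- d$lineno[k]
    if (length(f) < 3L) {
      stop(sprintf("line %d: association records need >= 3 columns", ln),
           call. = FALSE)
    }
    chrom[k] <- f[1]
    pos[k] <- int_or_stop(f[2], "position", ln) - 1  # file is 1-based
    pvalue[k] <- num_or_stop(f[3], "p-value", ln)
    if (pvalue[k] <= 0 || pvalue[k] > 1) {
      stop(sprintf("line %d: p-value %g outside (0, 1]", ln, pvalue[k]),
           call. = FALSE)
    }
    if (length(f) >= 4L && nzchar(f[4])) typed[k] <- parse_typed(f[4], ln)
    if (length(f) >= 5L && nzchar(f[5])) {
      r2[k] <- num_or_stop(f[5], "r2", ln)
      if (r2[k] < 0 || r2[k] > 1) {
        stop(sprintf("line %d: r2 %g outside [0, 1]", ln, r2[k]),
             call. = FALSE)
      }
    }
    if (length(f) >= 6L && nzchar(f[6])) {
      recomb[k] <- num_or_stop(f[6], "recombination rate", ln)
      if (recomb[k] < 0) {
        stop(sprintf("line %d: negative recombination rate", ln),
             call. = FALSE)
      }
    }
    if (length(f) >= 7L && nzchar(f[7])) id[k] <- f[7]
  }
  structure(data.frame(chrom = chrom, pos = pos, pvalue = pvalue,
                       typed = typed, r2 = r2, recomb = recomb, id = id,
                       stringsAsFactors = FALSE),
            class = c("association_records", "data.frame"))
}

empty_association <- function() {
  structure(data.frame(chrom = character(), pos = numeric(),
                       pvalue = numeric(), typed = logical(), r2 = numeric(),
                       recomb = numeric(), id = character(),
                       stringsAsFactors = FALSE),
            class = c("association_records", "data.frame"))
}

parse_typed <- function(x, lineno) {
  up <- toupper(x)
  if (up %in% c("T", "TRUE", "TYPED", "1")) return(TRUE)
  if (up %in% c("F", "FALSE", "IMPUTED", "0")) return(FALSE)
  stop(sprintf("line %d: cannot interpret typed/imputed flag '%s'", lineno, x),
       call. = FALSE)
}

#' Write association records back to their dialect
#'
#' Inverse of [read_association()]; positions are emitted 1-based.
#'
#' @param recs An `association_records` data.frame.
#' @param path Output path.
#' @export
write_association <- function(recs, path) {
  fmt_opt <- function(v, f) ifelse(is.na(v), "", f(v))
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s",
    recs$chrom,
    format(recs$pos + 1, scientific = FALSE, trim = TRUE),
    fmt_num(recs$pvalue),
    fmt_opt(recs$typed, function(v) ifelse(v, "T", "F")),
    fmt_opt(recs$r2, fmt_num),
    fmt_opt(recs$recomb, fmt_num),
    ifelse(is.na(recs$id), "", recs$id))
  writeLines(lines, path)
}

# Deterministic numeric formatting used by all writers.
fmt_num <- function(v) {
  vapply(v, function(x) {
    if (is.na(x)) return("")
    if (x == floor(x) && abs(x) < 1e15) {
      format(x, scientific = FALSE, trim = TRUE)
    } else {
      format(x, digits = 10, scientific = TRUE, trim = TRUE)
    }
  }, character(1))
}

#' Read a BED-like interval file (intensity or segmentation)
#'
#' Tab-delimited columns `chrom`, `start`, `end`, `value`; coordinates are
#' 0-based half-open.  In `"intensity"` mode the fourth column must be
#' numeric; in `"segmentation"` mode it is a non-empty state label.
#'
#' @param path Path to the file.
#' @param mode `"intensity"` or `"segmentation"`.
#' @return A data.frame: columns `chrom`, `start`, `end` and `value`
#'   (numeric) or `state` (character) depending on mode.
#' @export
read_bed_like <- function(path, mode = c("intensity", "segmentation")) {
  mode <- match.arg(mode)
  d <- read_data_lines(path)
  n <- length(d$lines)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  val <- if (mode == "intensity") numeric(n) else character(n)
  for (k in seq_len(n)) {
    f <- split_tabs(d$lines[k]); ln <- d$lineno[k]
    if (length(f) < 4L) {
      stop(sprintf("line %d: expected 4 columns (chrom, start, end, %s)",
                   ln, if (mode == "intensity") "value" else "state"),
           call. = FALSE)
    }
    chrom[k] <- f[1]
    start[k] <- int_or_stop(f[2], "start", ln)
    end[k] <- int_or_stop(f[3], "end", ln)
    if (start[k] >= end[k]) {
      stop(sprintf("line %d: zero- or negative-length interval", ln),
           call. = FALSE)
    }
    if (mode == "intensity") {
      val[k] <- num_or_stop(f[4], "value", ln)
    } else {
      if (!nzchar(f[4])) {
        stop(sprintf("line %d: empty state label", ln), call. = FALSE)
      }
      val[k] <- f[4]
    }
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (mode == "intensity") out$value <- val else out$state <- val
  cls <- if (mode == "intensity") "intensity_records" else
    "segmentation_records"
  structure(out, class = c(cls, "data.frame"))
}

#' @rdname read_bed_like
#' @param recs Records as returned by [read_bed_like()].
#' @export
write_bed_like <- function(recs, path) {
  col4 <- if (!is.null(recs$value)) fmt_num(recs$value) else recs$state
  writeLines(sprintf("%s\t%s\t%s\t%s", recs$chrom,
                     format(recs$start, scientific = FALSE, trim = TRUE),
                     format(recs$end, scientific = FALSE, trim = TRUE),
                     col4), path)
}

#' Read a paired-anchor interaction file (BEDPE plus score)
#'
#' Seven tab-delimited columns: `chrom1`, `start1`, `end1`, `chrom2`,
#' `start2`, `end2`, `score` where the score is the -log10 p-value of the
#' interaction (must be non-negative).  Anchors may lie on different
#' chromosomes; a self-loop (anchor1 == anchor2) is accepted.
#'
#' @param path Path to the file.
#' @return A data.frame of class `interaction_records`.
#' @export
read_interactions <- function(path) {
  d <- read_data_lines(path)
  n <- length(d$lines)
  out <- data.frame(chrom1 = character(n), start1 = numeric(n),
                    end1 = numeric(n), chrom2 = character(n),
                    start2 = numeric(n), end2 = numeric(n),
                    score = numeric(n), stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    f <- split_tabs(d$lines[k]); ln <- d$lineno[k]
    if (length(f) < 7L) {
      stop(sprintf("line %d: interaction records need 7 columns", ln),
           call. = FALSE)
    }
    out$chrom1[k] <- f[1]
    out$start1[k] <- int_or_stop(f[2], "start1", ln)
    out$end1[k] <- int_or_stop(f[3], "end1", ln)
    out$chrom2[k] <- f[4]
    out$start2[k] <- int_or_stop(f[5], "start2", ln)
    out$end2[k] <- int_or_stop(f[6], "end2", ln)
    out$score[k] <- num_or_stop(f[7], "score", ln)
    if (out$start1[k] >= out$end1[k] || out$start2[k] >= out$end2[k]) {
      stop(sprintf("line %d: invalid anchor interval", ln), call. = FALSE)
    }
    if (out$score[k] < 0) {
      stop(sprintf("line %d: negative interaction score", ln), call. = FALSE)
    }
  }
  structure(out, class = c("interaction_records", "data.frame"))
}

#' @rdname read_interactions
#' @param recs Records as returned by [read_interactions()].
#' @export
write_interactions <- function(recs, path) {
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s",
    recs$chrom1,
    format(recs$start1, scientific = FALSE, trim = TRUE),
    format(recs$end1, scientific = FALSE, trim = TRUE),
    recs$chrom2,
    format(recs$start2, scientific = FALSE, trim = TRUE),
    format(recs$end2, scientific = FALSE, trim = TRUE),
    fmt_num(recs$score)), path)
}

#' Read a binned contact-count file
#'
#' Five tab-delimited columns: `chrom1`, `bin1_start`, `chrom2`,
#' `bin2_start`, `count`.  Bin starts must be aligned to the `bin_size`
#' grid.  Symmetric completion is not applied; duplicates of a symmetric
#' pair are summed with a warning.
#'
#' @param path Path to the file.
#' @param bin_size Bin width in bp (file-level constant, e.g. 3000).
#' @return A data.frame of class `contact_records` with attribute
#'   `bin_size`.
#' @export
read_contacts <- function(path, bin_size) {
  stopifnot(is.numeric(bin_size), length(bin_size) == 1L, bin_size > 0)
  d <- read_data_lines(path)
  n <- length(d$lines)
  out <- data.frame(chrom1 = character(n), bin1_start = numeric(n),
                    chrom2 = character(n), bin2_start = numeric(n),
                    count = numeric(n), stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    f <- split_tabs(d$lines[k]); ln <- d$lineno[k]
    if (length(f) < 5L) {
      stop(sprintf("line %d: contact records need 5 columns", ln),
           call. = FALSE)
    }
    out$chrom1[k] <- f[1]
    out$bin1_start[k] <- int_or_stop(f[2], "bin1_start", ln)
    out$chrom2[k] <- f[3]
    out$bin2_start[k] <- int_or_stop(f[4], "bin2_start", ln)
    out$count[k] <- num_or_stop(f[5], "count", ln)
    if (out$bin1_start[k] %% bin_size != 0 ||
        out$bin2_start[k] %% bin_size != 0) {
      stop(sprintf("line %d: bin start not aligned to %d bp grid", ln,
                   as.integer(bin_size)), call. = FALSE)
    }
    if (out$count[k] < 0) {
      stop(sprintf("line %d: negative contact count", ln), call. = FALSE)
    }
  }
  # collapse duplicates of a symmetric pair (unordered anchor key)
  key_a <- paste(out$chrom1, out$bin1_start)
  key_b <- paste(out$chrom2, out$bin2_start)
  key <- ifelse(key_a <= key_b, paste(key_a, key_b, sep = "|"),
                paste(key_b, key_a, sep = "|"))
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate symmetric contact pair(s) summed",
                    sum(duplicated(key))), call. = FALSE)
    first <- !duplicated(key)
    sums <- tapply(out$count, key, sum)
    out <- out[first, , drop = FALSE]
    out$count <- as.numeric(sums[ifelse(key_a <= key_b,
                                        paste(key_a, key_b, sep = "|"),
                                        paste(key_b, key_a, sep = "|"))[first]])
    rownames(out) <- NULL
  }
  attr(out, "bin_size") <- bin_size
  structure(out, class = c("contact_records", "data.frame"))
}

#' @rdname read_contacts
#' @param recs Records as returned by [read_contacts()].
#' @export
write_contacts <- function(recs, path) {
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s",
    recs$chrom1,
    format(recs$bin1_start, scientific = FALSE, trim = TRUE),
    recs$chrom2,
    format(recs$bin2_start, scientific = FALSE, trim = TRUE),
    fmt_num(recs$count)), path)
}

#' Read gene models from a BED12 file
#'
#' Standard 12-column BED: chrom, start, end, name, score, strand,
#' thickStart, thickEnd, itemRgb, blockCount, blockSizes, blockStarts.
#' Exons are reconstructed as absolute half-open intervals from the block
#' lists and validated to be sorted, non-overlapping and inside the
#' transcript span.
#'
#' @param path Path to the BED12 file.
#' @return A data.frame of class `gene_models` with list columns
#'   `exon_starts` and `exon_ends`.
#' @export
read_genes <- function(path) {
  d <- read_data_lines(path)
  n <- length(d$lines)
  name <- character(n); chrom <- character(n); tx_start <- numeric(n)
  tx_end <- numeric(n); strand <- character(n)
  exon_starts <- vector("list", n); exon_ends <- vector("list", n)
  for (k in seq_len(n)) {
    f <- split_tabs(d$lines[k]); ln <- d$lineno[k]
    if (length(f) < 12L) {
      stop(sprintf("line %d: BED12 records need 12 columns", ln),
           call. = FALSE)
    }
    chrom[k] <- f[1]
    tx_start[k] <- int_or_stop(f[2], "txStart", ln)
    tx_end[k] <- int_or_stop(f[3], "txEnd", ln)
    if (tx_start[k] >= tx_end[k]) {
      stop(sprintf("line %d: txStart >= txEnd", ln), call. = FALSE)
    }
    name[k] <- f[4]
    if (!f[6] %in% c("+", "-")) {
      stop(sprintf("line %d: strand must be '+' or '-'", ln), call. = FALSE)
    }
    strand[k] <- f[6]
    nblk <- int_or_stop(f[10], "blockCount", ln)
    sizes <- parse_int_list(f[11], "blockSizes", ln)
    starts <- parse_int_list(f[12], "blockStarts", ln)
    if (length(sizes) != nblk || length(starts) != nblk) {
      stop(sprintf("line %d: blockCount %d does not match list lengths", ln,
                   as.integer(nblk)), call. = FALSE)
    }
    es <- tx_start[k] + starts
    ee <- es + sizes
    if (any(ee > tx_end[k]) || any(es < tx_start[k])) {
      stop(sprintf("line %d: exon outside transcript span", ln),
           call. = FALSE)
    }
    if (is.unsorted(es, strictly = TRUE) ||
        any(head(ee, -1L) > es[-1L])) {
      stop(sprintf("line %d: exons must be sorted and non-overlapping", ln),
           call. = FALSE)
    }
    exon_starts[[k]] <- es
    exon_ends[[k]] <- ee
  }
  out <- data.frame(name = name, chrom = chrom, tx_start = tx_start,
                    tx_end = tx_end, strand = strand,
                    stringsAsFactors = FALSE)
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  structure(out, class = c("gene_models", "data.frame"))
}

parse_int_list <- function(x, what, lineno) {
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) return(numeric(0))
  int_or_stop(parts, what, lineno)
}

#' @rdname read_genes
#' @param models Gene models as returned by [read_genes()].
#' @export
write_genes <- function(models, path) {
  lines <- vapply(seq_len(nrow(models)), function(k) {
    es <- models$exon_starts[[k]]; ee <- models$exon_ends[[k]]
    sizes <- paste0(paste(format(ee - es, scientific = FALSE, trim = TRUE),
                          collapse = ","), ",")
    starts <- paste0(paste(format(es - models$tx_start[k],
                                  scientific = FALSE, trim = TRUE),
                           collapse = ","), ",")
    sprintf("%s\t%s\t%s\t%s\t0\t%s\t%s\t%s\t0\t%d\t%s\t%s",
            models$chrom[k],
            format(models$tx_start[k], scientific = FALSE, trim = TRUE),
            format(models$tx_end[k], scientific = FALSE, trim = TRUE),
            models$name[k], models$strand[k],
            format(models$tx_start[k], scientific = FALSE, trim = TRUE),
            format(models$tx_end[k], scientific = FALSE, trim = TRUE),
            length(es), sizes, starts)
  }, character(1))
  writeLines(lines, path)
}

annotation_kinds <- c("highlight-box", "vertical-marker", "bracket", "text")

#' Read a manual feature-annotation file
#'
#' Five tab-delimited columns: `chrom`, `start`, `end`, `kind`, `label`.
#' `kind` is one of `highlight-box`, `vertical-marker`, `bracket`, `text`.
#' Single-position kinds (`vertical-marker`, `text`) require
#' `end == start + 1`; the label may be empty only for `highlight-box`.
#'
#' @param path Path to the file.
#' @return A data.frame of class `annotation_records`.
#' @export
read_annotations <- function(path) {
  d <- read_data_lines(path)
  n <- length(d$lines)
  out <- data.frame(chrom = character(n), start = numeric(n),
                    end = numeric(n), kind = character(n),
                    label = character(n), stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    f <- split_tabs(d$lines[k]); ln <- d$lineno[k]
    if (length(f) < 4L) {
      stop(sprintf("line %d: annotation records need >= 4 columns", ln),
           call. = FALSE)
    }
    out$chrom[k] <- f[1]
    out$start[k] <- int_or_stop(f[2], "start", ln)
    out$end[k] <- int_or_stop(f[3], "end", ln)
    if (out$start[k] >= out$end[k]) {
      stop(sprintf("line %d: start >= end", ln), call. = FALSE)
    }
    if (!f[4] %in% annotation_kinds) {
      stop(sprintf("line %d: unknown annotation kind '%s' (must be one of %s)",
                   ln, f[4], paste(annotation_kinds, collapse = ", ")),
           call. = FALSE)
    }
    out$kind[k] <- f[4]
    out$label[k] <- if (length(f) >= 5L) f[5] else ""
    if (out$kind[k] %in% c("vertical-marker", "text") &&
        out$end[k] != out$start[k] + 1) {
      stop(sprintf("line %d: kind '%s' requires end == start + 1", ln,
                   out$kind[k]), call. = FALSE)
    }
    if (!nzchar(out$label[k]) && out$kind[k] != "highlight-box") {
      stop(sprintf("line %d: empty label only allowed for highlight-box", ln),
           call. = FALSE)
    }
  }
  structure(out, class = c("annotation_records", "data.frame"))
}

#' @rdname read_annotations
#' @param recs Records as returned by [read_annotations()].
#' @export
write_annotations <- function(recs, path) {
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s", recs$chrom,
                     format(recs$start, scientific = FALSE, trim = TRUE),
                     format(recs$end, scientific = FALSE, trim = TRUE),
                     recs$kind, recs$label), path)
}
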