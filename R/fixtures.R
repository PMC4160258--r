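# Seeded fixture generator.
#
# Produces a complete synthetic input set with the structure of a
# two-locus figure: two regions on different chromosomes, an association
# signal with an index SNP and LD r-squared decaying with distance, a
# recombination-rate overlay, a chromatin-state segmentation tiling each
# region, a binned contact matrix with planted enriched pairs emitted as
# the significant-interaction set, gene models (some overlapping, to
# exercise row packing) and manual annotations around the index SNP.
# Everything is driven by a single integer seed through R's default
# Mersenne-Twister RNG; a given seed always yields byte-identical files.

#' Parameters of the synthetic fixture set
#'
#' Defaults emulate two Mb-scale loci on different chromosomes drawn at a
#' common scale, with a 3 kb contact-bin resolution.
#'
#' @param seed Integer seed driving all randomness.
#' @param regions List of two [genomic_interval()] (different chromosomes).
#' @param region_labels Display names for the two regions.
#' @param n_snps SNPs simulated per region.
#' @param index_pos Index SNP position (bp, inside region 2).
#' @param index_id Index SNP identifier.
#' @param peak_mlp Peak -log10 p at the index SNP.
#' @param r2_decay LD decay length in bp.
#' @param n_states Number of segmentation states.
#' @param seg_mean_len Mean segmentation segment length in bp.
#' @param bin_size Contact bin width in bp (must divide region widths).
#' @param contact_decay Exponent of the contact distance decay.
#' @param n_interactions Planted significant interactions (region 2).
#' @param n_genes Genes per region.
#' @return A list of class `fixture_params`.
#' @export
fixture_params <- function(seed = 1,
                           regions = list(
                             genomic_interval("chr3", 9999000, 10599000),
                             genomic_interval("chr8", 24999000, 25899000)),
                           region_labels = c("3q26.2", "8q24.21"),
                           n_snps = c(350, 450),
                           index_pos = 25451500,
                           index_id = "rs6983267",
                           peak_mlp = 8,
                           r2_decay = 20000,
                           n_states = 5,
                           seg_mean_len = 8000,
                           bin_size = 3000,
                           contact_decay = 1,
                           n_interactions = 10,
                           n_genes = c(5, 4)) {
  stopifnot(length(regions) == 2L, seed == floor(seed),
            all(n_snps > 0), peak_mlp > 0, r2_decay > 0, n_states > 0,
            bin_size > 0, n_interactions > 0, all(n_genes > 0))
  for (r in regions) {
    if (iv_width(r) %% bin_size != 0 || r$start %% bin_size != 0) {
      stop("region start and width must be multiples of bin_size",
           call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "fixture_params")
}

# Offsets keep each generator on its own deterministic RNG stream so the
# files are reproducible individually as well as in a set.
fixture_seed <- function(params, k) as.integer(params$seed * 131L + k)

ld_block <- function(params) {
  c(params$index_pos - 20000, params$index_pos + 20000)
}

#' Generate the synthetic association file
#'
#' SNP positions are uniform over the regions; -log10 p is baseline noise
#' plus a peak at the index SNP decaying with distance; r2 to the index SNP
#' decays exponentially with distance (noise added, clipped to \[0, 1\]);
#' the index SNP gets r2 = 1, the configured identifier and the maximum
#' -log10 p of its region.  About 20 percent of SNPs are flagged imputed.
#' A recombination-rate overlay with hotspots flanking the LD block is
#' included.
#'
#' @param params A [fixture_params()].
#' @param path Output file path.
#' @return The parsed `association_records` (invisibly); the file is
#'   written as a side effect.
#' @export
make_association <- function(params, path) {
  set.seed(fixture_seed(params, 1L))
  rows <- list()
  for (i in 1:2) {
    r <- params$regions[[i]]
    n <- params$n_snps[i]
    pos <- sort(floor(stats::runif(n, r$start, r$end - 1)))
    base_mlp <- -log10(stats::runif(n))
    if (i == 2L) {
      d <- abs(pos - params$index_pos)
      signal <- params$peak_mlp * exp(-d / (params$r2_decay * 0.75)) *
        stats::runif(n, 0.55, 0.95)
      mlp <- pmax(base_mlp, signal)
      r2 <- pmin(1, pmax(0, exp(-d / params$r2_decay) +
                           stats::rnorm(n, 0, 0.05)))
    } else {
      mlp <- base_mlp
      r2 <- stats::runif(n, 0, 0.05)  # other chromosome: no LD with index
    }
    typed <- stats::runif(n) > 0.2
    # recombination: smooth background plus hotspots, in cM/Mb
    hot <- stats::runif(3, r$start, r$end)
    recomb <- stats::runif(n, 0, 2)
    for (h in hot) {
      recomb <- recomb + 35 * exp(-(pos - h)^2 / (2 * 4000^2))
    }
    rows[[i]] <- data.frame(chrom = r$chrom, pos = pos,
                            mlp = pmin(mlp, params$peak_mlp - 0.2),
                            typed = typed, r2 = round(r2, 4),
                            recomb = round(recomb, 3),
                            id = sprintf("rs%d%04d", i, seq_len(n)),
                            stringsAsFactors = FALSE)
  }
  # the index SNP: strictly the strongest signal in its region
  idx <- data.frame(chrom = params$regions[[2]]$chrom,
                    pos = params$index_pos, mlp = params$peak_mlp,
                    typed = TRUE, r2 = 1, recomb = 0.5,
                    id = params$index_id, stringsAsFactors = FALSE)
  d <- rbind(rows[[1]], rows[[2]], idx)
  d <- d[order(match(d$chrom, c(params$regions[[1]]$chrom,
                                params$regions[[2]]$chrom)), d$pos), ]
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s",
                   d$chrom, d$pos + 1, fmt_num(10^(-d$mlp)),
                   ifelse(d$typed, "T", "F"), fmt_num(d$r2),
                   fmt_num(d$recomb), d$id)
  writeLines(lines, path)
  invisible(read_association(path))
}

#' Generate matched contact and interaction files
#'
#' Contact counts for same-region bin pairs up to 12 bins apart are Poisson
#' with mean proportional to `(1 + |i - j|)^-decay`.  A planted set of
#' enriched pairs -- every one with an anchor in the LD block around the
#' index SNP, plus one pair joining the two regions -- gets a five-fold
#' mean boost and is emitted as the significant-interaction file with
#' -log10 p scores.
#'
#' @param params A [fixture_params()].
#' @param contacts_path Output path of the binned contact file.
#' @param interactions_path Output path of the interaction (BEDPE+score)
#'   file.
#' @return List with the parsed `contact_records` and
#'   `interaction_records` (invisibly).
#' @export
make_contacts_and_interactions <- function(params, contacts_path,
                                           interactions_path) {
  set.seed(fixture_seed(params, 2L))
  bs <- params$bin_size
  base_mu <- function(d) 30 * (1 + d)^(-params$contact_decay)
  max_d <- 12L
  # planted pairs: anchored in the LD block, various separations
  block <- ld_block(params)
  r2 <- params$regions[[2]]
  block_bins <- seq(floor((block[1] - r2$start) / bs),
                    ceiling((block[2] - r2$start) / bs) - 1L)
  anchor_bins <- sample(block_bins, params$n_interactions, replace = TRUE)
  sep <- sample(5:40, params$n_interactions, replace = TRUE)
  n_bins2 <- iv_width(r2) / bs
  partner <- pmin(pmax(anchor_bins + sep * sample(c(-1L, 1L),
                                                  params$n_interactions,
                                                  replace = TRUE), 0L),
                  n_bins2 - 1L)
  planted <- unique(data.frame(
    chrom1 = r2$chrom, bin1 = pmin(anchor_bins, partner) * bs + r2$start,
    chrom2 = r2$chrom, bin2 = pmax(anchor_bins, partner) * bs + r2$start))
  # one inter-region pair: region-1 bin to an LD-block bin
  r1 <- params$regions[[1]]
  cross_bin1 <- sample(seq_len(iv_width(r1) / bs) - 1L, 1L) * bs + r1$start
  cross_bin2 <- sample(block_bins, 1L) * bs + r2$start
  planted <- rbind(planted,
                   data.frame(chrom1 = r1$chrom, bin1 = cross_bin1,
                              chrom2 = r2$chrom, bin2 = cross_bin2))
  planted_key <- paste(planted$chrom1, planted$bin1, planted$chrom2,
                       planted$bin2)
  # background same-region pairs up to max_d bins apart
  recs <- list()
  for (r in params$regions) {
    n_bins <- iv_width(r) / bs
    starts <- r$start + (seq_len(n_bins) - 1L) * bs
    for (d in 0:max_d) {
      i <- seq_len(n_bins - d)
      b1 <- starts[i]; b2 <- starts[i + d]
      key <- paste(r$chrom, b1, r$chrom, b2)
      boost <- ifelse(key %in% planted_key, 5, 1)
      cnt <- stats::rpois(length(i), boost * base_mu(d))
      recs[[length(recs) + 1L]] <- data.frame(
        chrom1 = r$chrom, bin1 = b1, chrom2 = r$chrom, bin2 = b2,
        count = cnt, stringsAsFactors = FALSE)
    }
  }
  bg <- do.call(rbind, recs)
  # planted pairs farther apart than max_d (and the cross-region pair) are
  # appended explicitly so every interaction anchor is a matrix bin
  key_bg <- paste(bg$chrom1, bg$bin1, bg$chrom2, bg$bin2)
  extra <- planted[!(planted_key %in% key_bg), , drop = FALSE]
  if (nrow(extra)) {
    d_extra <- ifelse(extra$chrom1 == extra$chrom2,
                      abs(extra$bin2 - extra$bin1) / bs, 20)
    bg <- rbind(bg, data.frame(chrom1 = extra$chrom1, bin1 = extra$bin1,
                               chrom2 = extra$chrom2, bin2 = extra$bin2,
                               count = stats::rpois(nrow(extra),
                                                    5 * base_mu(d_extra)) + 1,
                               stringsAsFactors = FALSE))
  }
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d", bg$chrom1, bg$bin1, bg$chrom2,
                     bg$bin2, bg$count), contacts_path)
  scores <- round(stats::runif(nrow(planted), 3, 8), 3)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s",
                     planted$chrom1, planted$bin1, planted$bin1 + bs,
                     planted$chrom2, planted$bin2, planted$bin2 + bs,
                     fmt_num(scores)), interactions_path)
  invisible(list(contacts = read_contacts(contacts_path, bs),
                 interactions = read_interactions(interactions_path)))
}

#' Generate segmentation, gene-model and annotation files
#'
#' The segmentation tiles each region exactly (no gaps, no overlaps) with
#' states drawn from a Markov chain.  Gene models have valid exon
#' structures and the first region contains a deliberately overlapping
#' pair to exercise row packing.  Annotations place a highlight box and a
#' bracket over the LD block and a vertical marker at the index SNP.
#'
#' @param params A [fixture_params()].
#' @param seg_path Output path of the segmentation file.
#' @param genes_path Output path of the BED12 gene file.
#' @param ann_path Output path of the annotation file.
#' @return List of the three parsed record sets (invisibly).
#' @export
make_segmentation_genes_annotations <- function(params, seg_path,
                                                genes_path, ann_path) {
  set.seed(fixture_seed(params, 3L))
  states <- names(default_state_colors)[seq_len(min(params$n_states,
                                                    length(default_state_colors)))]
  n_st <- length(states)
  # sticky Markov chain over states
  trans <- matrix(0.6 / (n_st - 1), n_st, n_st)
  diag(trans) <- 0.4
  seg_lines <- character(0)
  for (r in params$regions) {
    pos <- r$start
    st <- sample.int(n_st, 1L)
    while (pos < r$end) {
      len <- 200 * (1 + stats::rgeom(1, 200 / params$seg_mean_len))
      end <- min(pos + len, r$end)
      seg_lines <- c(seg_lines, sprintf("%s\t%d\t%d\t%s", r$chrom, pos, end,
                                        states[st]))
      pos <- end
      st <- sample.int(n_st, 1L, prob = trans[st, ])
    }
  }
  writeLines(seg_lines, seg_path)

  gene_lines <- character(0)
  g_id <- 0L
  for (i in 1:2) {
    r <- params$regions[[i]]
    n <- params$n_genes[i]
    for (j in seq_len(n)) {
      g_id <- g_id + 1L
      len <- floor(stats::runif(1, 30000, 120000))
      if (i == 1L && j == 2L) {
        # force overlap with the previous gene (row-packing exercise)
        f <- strsplit(gene_lines[length(gene_lines)], "\t")[[1]]
        tx_start <- floor(mean(as.numeric(f[2:3])))
      } else {
        tx_start <- floor(stats::runif(1, r$start, r$end - len - 1))
      }
      tx_end <- min(tx_start + len, r$end - 1)
      n_ex <- sample(2:8, 1L)
      cuts <- sort(sample(seq(200, tx_end - tx_start - 200, by = 100),
                          2L * n_ex - 2L))
      bounds <- c(0, cuts, tx_end - tx_start)
      ex_s <- bounds[seq(1, length(bounds) - 1, by = 2)]
      ex_e <- bounds[seq(2, length(bounds), by = 2)]
      strand <- sample(c("+", "-"), 1L)
      gene_lines <- c(gene_lines, sprintf(
        "%s\t%d\t%d\tGENE%d\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
        r$chrom, tx_start, tx_end, g_id, strand, tx_start, tx_end, n_ex,
        paste0(paste(ex_e - ex_s, collapse = ","), ","),
        paste0(paste(ex_s, collapse = ","), ",")))
    }
  }
  writeLines(gene_lines, genes_path)

  block <- ld_block(params)
  ann_lines <- c(
    sprintf("%s\t%d\t%d\thighlight-box\t", params$regions[[2]]$chrom,
            block[1], block[2]),
    sprintf("%s\t%d\t%d\tbracket\tLD block", params$regions[[2]]$chrom,
            block[1], block[2]),
    sprintf("%s\t%d\t%d\tvertical-marker\t%s", params$regions[[2]]$chrom,
            params$index_pos, params$index_pos + 1, params$index_id))
  writeLines(ann_lines, ann_path)
  invisible(list(segmentation = read_bed_like(seg_path, "segmentation"),
                 genes = read_genes(genes_path),
                 annotations = read_annotations(ann_path)))
}

#' Write the complete fixture set plus a ready-to-run configuration
#'
#' Writes the region file, every track dialect and a `config.yaml` wired to
#' them: six main tracks (intensity, links, segmentation, association,
#' arches, genes) and a zoom panel over the LD block with association,
#' segmentation, contact heat map and gene tracks.  The intensity track is
#' derived from the association signal (strongest -log10 p per 20 kb
#' window), mirroring the convention of showing the same association data
#' both as colour intensity and as a scatter.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param params Optional [fixture_params()] (overrides `seed`).
#' @return Named list of the written file paths (invisibly).
#' @export
write_fixtures <- function(dir, seed = 1, params = NULL) {
  params <- params %||% fixture_params(seed = seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    regions = file.path(dir, "regions.tsv"),
    association = file.path(dir, "association.tsv"),
    intensity = file.path(dir, "intensity.tsv"),
    segmentation = file.path(dir, "segmentation.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    contacts = file.path(dir, "contacts.tsv"),
    genes = file.path(dir, "genes.bed"),
    annotations = file.path(dir, "annotations.tsv"),
    config = file.path(dir, "config.yaml"))

  labels <- params$region_labels
  writeLines(sprintf("%s\t%d\t%d\t%s",
                     vapply(params$regions, `[[`, character(1), "chrom"),
                     vapply(params$regions, function(r) as.integer(r$start),
                            integer(1)),
                     vapply(params$regions, function(r) as.integer(r$end),
                            integer(1)),
                     labels), paths$regions)

  assoc <- make_association(params, paths$association)
  make_contacts_and_interactions(params, paths$contacts,
                                 paths$interactions)
  make_segmentation_genes_annotations(params, paths$segmentation,
                                      paths$genes, paths$annotations)

  # intensity = windowed maximum of -log10 p over 20 kb tiles
  win <- 20000
  int_lines <- character(0)
  for (r in params$regions) {
    w0 <- seq(r$start, r$end - win, by = win)
    for (s in w0) {
      in_w <- assoc$chrom == r$chrom & assoc$pos >= s & assoc$pos < s + win
      v <- if (any(in_w)) max(-log10(assoc$pvalue[in_w])) else 0
      int_lines <- c(int_lines, sprintf("%s\t%d\t%d\t%s", r$chrom, s,
                                        s + win, fmt_num(round(v, 4))))
    }
  }
  writeLines(int_lines, paths$intensity)

  block <- ld_block(params)
  zoom0 <- block[1] - 10000
  zoom1 <- block[2] + 10000
  config <- list(
    region_file = "regions.tsv",
    tracks = list(
      list(type = "intensity", path = "intensity.tsv", height = 0.6,
           label = "GWAS -log10 p"),
      list(type = "links", path = "interactions.tsv", height = 0.8,
           label = "significant interactions"),
      list(type = "segmentation", path = "segmentation.tsv", height = 0.5,
           label = "chromatin states"),
      list(type = "association", path = "association.tsv", height = 2,
           label = "association",
           params = list(index_id = params$index_id)),
      list(type = "arcs", path = "interactions.tsv", height = 1.4,
           label = "interaction arches"),
      list(type = "genes", path = "genes.bed", height = 1,
           label = "genes")),
    zoom = list(
      chrom = params$regions[[2]]$chrom, start = zoom0, end = zoom1,
      tracks = list(
        list(type = "association", path = "association.tsv", height = 1.6,
             params = list(index_id = params$index_id)),
        list(type = "segmentation", path = "segmentation.tsv",
             height = 0.5),
        list(type = "heatmap", path = "contacts.tsv", height = 1.4,
             params = list(bin_size = params$bin_size)),
        list(type = "annotations", path = "annotations.tsv", height = 0.6),
        list(type = "genes", path = "genes.bed", height = 0.8))),
    figure = list(title = "Two risk loci at a common scale",
                  formats = list("pdf", "png"), dpi = 150),
    seed = params$seed)
  yaml::write_yaml(config, paths$config)
  invisible(paths)
}
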