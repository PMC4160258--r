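# The seeded synthetic-data generator.

test_that("the same seed writes byte-identical fixture sets", {
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_fixtures(d1, seed = 9)
  p2 <- write_fixtures(d2, seed = 9)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
  d3 <- tempfile()
  p3 <- write_fixtures(d3, seed = 10)
  expect_false(identical(readLines(p1$association),
                         readLines(p3$association)))
})

test_that("generated files pass their strict parsers", {
  d <- fixture_dir()
  expect_silent(rs <- parse_region_file(file.path(d, "regions.tsv")))
  expect_silent(read_association(file.path(d, "association.tsv")))
  expect_silent(read_bed_like(file.path(d, "intensity.tsv"), "intensity"))
  expect_silent(read_bed_like(file.path(d, "segmentation.tsv"),
                              "segmentation"))
  expect_silent(read_interactions(file.path(d, "interactions.tsv")))
  expect_silent(read_contacts(file.path(d, "contacts.tsv"), 3000))
  expect_silent(read_genes(file.path(d, "genes.bed")))
  expect_silent(read_annotations(file.path(d, "annotations.tsv")))
  expect_silent(parse_config(file.path(d, "config.yaml")))
})

test_that("the index SNP dominates its region with r2 = 1 and the marker", {
  d <- fixture_dir()
  a <- read_association(file.path(d, "association.tsv"))
  params <- fixture_params(seed = 42)
  r2reg <- a[a$chrom == params$regions[[2]]$chrom, ]
  idx <- which(r2reg$id == params$index_id)
  expect_equal(length(idx), 1L)
  expect_equal(r2reg$pvalue[idx], min(r2reg$pvalue))
  expect_equal(r2reg$r2[idx], 1)
  expect_true(all(a$r2 >= 0 & a$r2 <= 1))
  # the annotation marker sits exactly at the index SNP position
  an <- read_annotations(file.path(d, "annotations.tsv"))
  marker <- an[an$kind == "vertical-marker", ]
  expect_equal(marker$start, r2reg$pos[idx])
  expect_equal(marker$label, params$index_id)
})

test_that("segmentation tiles each region with zero gap bp", {
  d <- fixture_dir()
  rs <- parse_region_file(file.path(d, "regions.tsv"))
  seg <- read_bed_like(file.path(d, "segmentation.tsv"), "segmentation")
  for (r in rs$regions) {
    s <- seg[seg$chrom == r$chrom, ]
    s <- s[order(s$start), ]
    expect_equal(s$start[1], r$start)
    expect_equal(s$end[nrow(s)], r$end)
    expect_true(all(s$end[-nrow(s)] == s$start[-1]))
  }
})

test_that("interaction anchors are contact-matrix bins; one joins the regions", {
  d <- fixture_dir()
  ia <- read_interactions(file.path(d, "interactions.tsv"))
  ct <- read_contacts(file.path(d, "contacts.tsv"), 3000)
  bins <- unique(paste(c(ct$chrom1, ct$chrom2),
                       c(ct$bin1_start, ct$bin2_start)))
  expect_true(all(paste(ia$chrom1, ia$start1) %in% bins))
  expect_true(all(paste(ia$chrom2, ia$start2) %in% bins))
  expect_true(all(ia$end1 - ia$start1 == 3000))
  expect_true(any(ia$chrom1 != ia$chrom2))
  expect_true(all(ct$count >= 0 & ct$count == floor(ct$count)))
})

test_that("planted pairs are enriched over background at equal separation", {
  # empirical mean over repeated seeded draws: planted pairs carry a
  # five-fold expected count at the same |i - j|
  planted_mean <- c(); bg_mean <- c()
  for (s in 1:15) {
    d <- tempfile()
    dir.create(d)
    params <- fixture_params(seed = s)
    res <- make_contacts_and_interactions(params, file.path(d, "c.tsv"),
                                          file.path(d, "i.tsv"))
    ct <- res$contacts; ia <- res$interactions
    intra <- ia[ia$chrom1 == ia$chrom2, ]
    key <- paste(ct$chrom1, ct$bin1_start, ct$chrom2, ct$bin2_start)
    pkey <- paste(intra$chrom1, intra$start1, intra$chrom2, intra$start2)
    sep <- abs(ct$bin2_start - ct$bin1_start) / 3000
    is_planted <- key %in% pkey
    for (dd in unique(sep[is_planted])) {
      p <- ct$count[is_planted & sep == dd]
      b <- ct$count[!is_planted & sep == dd &
                      ct$chrom1 == ct$chrom2]
      if (length(b)) {
        planted_mean <- c(planted_mean, mean(p))
        bg_mean <- c(bg_mean, mean(b))
      }
    }
  }
  expect_gt(mean(planted_mean), 2 * mean(bg_mean))
})

test_that("default regions hold an overlapping gene pair for row packing", {
  d <- fixture_dir()
  g <- read_genes(file.path(d, "genes.bed"))
  rs <- parse_region_file(file.path(d, "regions.tsv"))
  g1 <- g[g$chrom == rs$regions[[1]]$chrom, ]
  overlaps <- outer(seq_len(nrow(g1)), seq_len(nrow(g1)), Vectorize(
    function(i, j) i < j && g1$tx_start[i] < g1$tx_end[j] &&
      g1$tx_start[j] < g1$tx_end[i]))
  expect_true(any(overlaps))
})
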