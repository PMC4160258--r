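# Parsers for every track dialect: typed fields, diagnostics, round-trips.

test_that("association records parse with all optional columns", {
  f <- write_tmp("chr8\t128413305\t1e-8\tT\t1.0\t0.3\trs6983267")
  r <- read_association(f)
  expect_equal(nrow(r), 1L)
  expect_equal(r$pos, 128413304)  # 1-based file -> 0-based internal
  expect_equal(r$pvalue, 1e-8)
  expect_true(r$typed)
  expect_equal(r$r2, 1.0)
  expect_equal(r$recomb, 0.3)
  expect_equal(r$id, "rs6983267")
})

test_that("association parsing enforces the p-value domain and detects headers", {
  expect_error(read_association(write_tmp("chr1\t100\t0")), "line 1.*\\(0, 1\\]")
  expect_error(read_association(write_tmp("chr1\t100\t1.5")), "line 1")
  expect_error(read_association(write_tmp("chr1\tpos\t0.5\nchr1\tx\t0.5")),
               "line 2.*position")
  # header line skipped, not an error
  f <- write_tmp(c("chrom\tpos\tpvalue", "chr1\t100\t0.5"))
  expect_equal(nrow(read_association(f)), 1L)
  # minimal 3-column file leaves the optional fields unset
  r <- read_association(write_tmp("chr1\t100\t0.5"))
  expect_true(is.na(r$typed) && is.na(r$r2) && is.na(r$recomb) && is.na(r$id))
})

test_that("bed-like intervals parse as intensity or segmentation", {
  seg <- read_bed_like(write_tmp("chr3\t0\t3000\tEnhancer"), "segmentation")
  expect_equal(seg$state, "Enhancer")
  int <- read_bed_like(write_tmp("chr3\t0\t3000\t7.5"), "intensity")
  expect_equal(int$value, 7.5)
  expect_error(read_bed_like(write_tmp("chr3\t5\t5\t1"), "intensity"),
               "line 1.*length")
  expect_error(read_bed_like(write_tmp("chr3\t0\t10\tabc"), "intensity"),
               "non-numeric")
})

test_that("interaction records accept inter-chromosomal pairs and self-loops", {
  r <- read_interactions(write_tmp(
    "chr3\t100\t200\tchr8\t500\t600\t5.2"))
  expect_equal(r$chrom2, "chr8")
  expect_equal(r$score, 5.2)
  self <- read_interactions(write_tmp("chr3\t100\t200\tchr3\t100\t200\t1"))
  expect_equal(nrow(self), 1L)
  expect_error(read_interactions(write_tmp(
    "chr3\t100\t200\tchr8\t500\t600\t-1")), "line 1.*negative")
})

test_that("contact bins must sit on the grid; symmetric duplicates sum", {
  ok <- read_contacts(write_tmp("chr1\t6000\tchr1\t9000\t4"), 3000)
  expect_equal(ok$count, 4)
  expect_equal(attr(ok, "bin_size"), 3000)
  expect_error(read_contacts(write_tmp("chr1\t6001\tchr1\t9000\t4"), 3000),
               "line 1.*grid")
  zero <- read_contacts(write_tmp("chr1\t0\tchr1\t3000\t0"), 3000)
  expect_equal(zero$count, 0)
  expect_warning(
    dup <- read_contacts(write_tmp(c("chr1\t0\tchr1\t3000\t4",
                                     "chr1\t3000\tchr1\t0\t2")), 3000),
    "summed")
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$count, 6)
})

test_that("BED12 exons reconstruct from block lists with validation", {
  g <- read_genes(write_tmp(
    "chr1\t1000\t1500\tGENEX\t0\t+\t1000\t1500\t0\t2\t100,200,\t0,300,"))
  expect_equal(g$exon_starts[[1]], c(1000, 1300))
  expect_equal(g$exon_ends[[1]], c(1100, 1500))
  expect_error(read_genes(write_tmp(
    "chr1\t1000\t1500\tGENEX\t0\t+\t1000\t1500\t0\t2\t100,\t0,300,")),
    "line 1.*blockCount")
  expect_error(read_genes(write_tmp(
    "chr1\t1000\t1500\tGENEX\t0\t+\t1000\t1500\t0\t1\t600,\t0,")),
    "line 1.*span")
  minus <- read_genes(write_tmp(
    "chr1\t1000\t1500\tGENEY\t0\t-\t1000\t1500\t0\t1\t100,\t0,"))
  expect_equal(minus$strand, "-")
})

test_that("annotations use a closed kind vocabulary", {
  m <- read_annotations(write_tmp(
    "chr8\t128413304\t128413305\tvertical-marker\trs6983267"))
  expect_equal(m$kind, "vertical-marker")
  box <- read_annotations(write_tmp(
    "chr8\t128400000\t128450000\thighlight-box\t"))
  expect_equal(box$label, "")
  expect_error(read_annotations(write_tmp("chr8\t1\t2\tstar\tx")),
               "line 1.*unknown annotation kind")
  expect_error(read_annotations(write_tmp(
    "chr8\t100\t200\tvertical-marker\tx")), "start \\+ 1")
  expect_error(read_annotations(write_tmp("chr8\t100\t200\tbracket\t")),
               "empty label")
})

test_that("CRLF endings and comment lines are handled identically", {
  lf <- write_tmp(c("# c", "chr1\t100\t0.5"))
  crlf <- tempfile(fileext = ".tsv")
  writeBin(charToRaw("# c\r\nchr1\t100\t0.5\r\n"), crlf)
  expect_identical(read_association(lf), read_association(crlf))
})

test_that("parse -> write -> parse is the identity for every dialect", {
  d <- fixture_dir()
  a <- read_association(file.path(d, "association.tsv"))
  expect_identical(a, {
    f <- tempfile(); write_association(a, f); read_association(f)
  })
  for (mode in c("intensity", "segmentation")) {
    r <- read_bed_like(file.path(d, paste0(mode, ".tsv")), mode)
    f <- tempfile(); write_bed_like(r, f)
    expect_identical(r, read_bed_like(f, mode))
  }
  i <- read_interactions(file.path(d, "interactions.tsv"))
  f <- tempfile(); write_interactions(i, f)
  expect_identical(i, read_interactions(f))
  ct <- read_contacts(file.path(d, "contacts.tsv"), 3000)
  f <- tempfile(); write_contacts(ct, f)
  expect_identical(ct, read_contacts(f, 3000))
  g <- read_genes(file.path(d, "genes.bed"))
  f <- tempfile(); write_genes(g, f)
  expect_identical(g, read_genes(f))
  an <- read_annotations(file.path(d, "annotations.tsv"))
  f <- tempfile(); write_annotations(an, f)
  expect_identical(an, read_annotations(f))
})
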