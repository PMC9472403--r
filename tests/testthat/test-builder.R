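## Junction extraction, support filtering, bunch grouping, gene assignment.

sam_line <- function(pos, cigar, chrom = "chr1", flag = 0, mapq = 60,
                     tags = "") {
  paste0("r\t", flag, "\t", chrom, "\t", pos, "\t", mapq, "\t", cigar,
         "\t*\t0\t0\tAAAA\tIIII", tags)
}

write_sam <- function(lines, sq = "@SQ\tSN:chr1\tLN:100000") {
  f <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", sq, lines), f)
  f
}

test_that("CIGAR walking places junctions at the skipped reference bases", {
  jx <- extractJunctions(write_sam(sam_line(100, "10M50N10M")))
  expect_equal(GenomicRanges::start(jx), 110)
  expect_equal(GenomicRanges::end(jx), 159)
  expect_equal(jx$count, 1L)

  jx2 <- extractJunctions(write_sam(sam_line(1, "5M10N5M10N5M")))
  expect_equal(GenomicRanges::start(jx2), c(6, 21))
  expect_equal(GenomicRanges::end(jx2), c(15, 30))

  expect_length(extractJunctions(write_sam(sam_line(1, "20M"))), 0)

  ## insertions/clips do not consume reference; deletions do
  jx3 <- extractJunctions(write_sam(sam_line(100, "5S10M3I2D40N10M")))
  oracle <- hand_walk_cigar(100, "5S10M3I2D40N10M")
  expect_equal(GenomicRanges::start(jx3), oracle$start)
  expect_equal(GenomicRanges::end(jx3), oracle$end)
})

test_that("extraction agrees with a hand CIGAR walk on random records", {
  set.seed(42)
  cigars <- replicate(60, {
    n_gap <- sample(0:3, 1)
    parts <- c(paste0(sample(20:80, 1), "M"))
    for (i in seq_len(n_gap))
      parts <- c(parts, paste0(sample(50:4000, 1), "N"),
                 paste0(sample(20:80, 1), "M"))
    paste(parts, collapse = "")
  })
  pos <- sample(1000:50000, 60)
  lines <- mapply(sam_line, pos, cigars)
  jx <- extractJunctions(write_sam(lines))
  oracle <- do.call(rbind, Map(hand_walk_cigar, pos, cigars))
  okey <- paste(oracle$start, oracle$end)
  expected <- table(okey)
  got <- stats::setNames(jx$count,
                         paste(GenomicRanges::start(jx),
                               GenomicRanges::end(jx)))
  expect_setequal(names(got), names(expected))
  expect_equal(as.integer(got[names(expected)]),
               as.integer(expected))
})

test_that("record filters honour flags, MAPQ and malformed CIGARs", {
  lines <- c(
    sam_line(100, "10M50N10M"),                       # counted
    sam_line(100, "10M50N10M", flag = 256),           # secondary: dropped
    sam_line(100, "10M50N10M", flag = 4, chrom = "*"),# unmapped: silent
    sam_line(100, "10M50N10M", mapq = 5),             # low MAPQ w/ filter
    sam_line(100, "10MQ50N10M"))                      # malformed: warned
  f <- write_sam(lines)
  expect_warning(jx <- extractJunctions(f, min_mapq = 10), "malformed")
  expect_equal(jx$count, 1L)
  expect_equal(attr(jx, "skipped"), 1L)
  ## without the MAPQ filter the low-quality record counts too
  expect_warning(jx2 <- extractJunctions(f), "malformed")
  expect_equal(jx2$count, 2L)
  ## secondary records count when primary_only is off
  expect_warning(jx3 <- extractJunctions(f, primary_only = FALSE), "malformed")
  expect_equal(jx3$count, 3L)
})

test_that("splice strand comes from the XS tag, else unstranded", {
  lines <- c(sam_line(100, "10M50N10M", tags = "\tXS:A:-"),
             sam_line(500, "10M50N10M"))
  jx <- extractJunctions(write_sam(lines))
  expect_equal(as.character(GenomicRanges::strand(jx)), c("-", "*"))
})

test_that("intron support filter keeps introns reaching the threshold anywhere", {
  cts <- rbind(c(2L, 2L, 2L), c(0L, 0L, 5L), c(3L, 3L, 3L))
  jx <- make_jx(cts, condition = c("a", "a", "b"))
  kept <- filterIntrons(jx, min_reads = 3)
  expect_equal(unname(counts(kept)), cts[2:3, ])
  ## the strict per-sample-all strategy keeps only the uniformly covered row
  kept_all <- filterIntrons(jx, min_reads = 3, strategy = "all")
  expect_equal(unname(counts(kept_all)), cts[3, , drop = FALSE])
  expect_error(filterIntrons(jx, min_reads = 0), "min_reads")
})

test_that("the support filter is idempotent and monotone in the threshold", {
  set.seed(9)
  cts <- matrix(rpois(300, 3), ncol = 6)
  jx <- make_jx(cts, condition = rep(c("a", "b"), each = 3))
  f3 <- filterIntrons(jx, 3)
  expect_equal(counts(filterIntrons(f3, 3)), counts(f3))
  for (th in c(1, 2, 5, 8)) {
    keys <- function(x) paste(GenomicRanges::start(x), GenomicRanges::end(x))
    expect_true(all(keys(filterIntrons(jx, th + 1)) %in%
                      keys(filterIntrons(jx, th))))
  }
})

test_that("bunches are connected components of shared splice sites", {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100, 100, 400), c(200, 300, 500)), strand = "+")
  b <- groupBunches(gr)
  expect_equal(b[1], b[2])
  expect_false(b[1] == b[3])

  ## transitivity through a chain of shared starts and ends
  gr2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100, 100, 250), c(200, 300, 300)), strand = "+")
  expect_length(unique(groupBunches(gr2)), 1)

  expect_equal(groupBunches(GenomicRanges::GRanges()), character(0))

  ## same coordinates on another chromosome or strand do not link
  gr3 <- GenomicRanges::GRanges(c("chr1", "chr2", "chr1"),
    IRanges::IRanges(c(100, 100, 100), c(200, 200, 300)),
    strand = c("+", "+", "-"))
  expect_length(unique(groupBunches(gr3)), 3)
})

test_that("bunch grouping matches brute-force components and partitions input", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 50
    ## coordinate pool small enough to force shared endpoints
    st <- sample(seq(100, 1500, by = 100), n, replace = TRUE)
    en <- st + sample(seq(100, 800, by = 100), n, replace = TRUE)
    gr <- unique(GenomicRanges::GRanges(
      sample(c("chr1", "chr2"), n, replace = TRUE),
      IRanges::IRanges(st, en),
      strand = sample(c("+", "-"), n, replace = TRUE)))
    got <- groupBunches(gr)
    want <- brute_force_bunches(gr)
    ## same partition: label-invariant comparison
    expect_equal(as.integer(factor(got, levels = unique(got))),
                 as.integer(factor(want, levels = unique(want))))
    expect_false(anyNA(got))
  }
})

test_that("gene assignment uses shared intron boundaries; novelty is exact", {
  gtf <- write_toy_gtf()
  ## (101,160) exact match to G1-T1; (101,999) shares only the start;
  ## (5000,6000) matches nothing
  gr <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1"),
    IRanges::IRanges(c(101, 101, 5000), c(160, 999, 6000)), strand = "+")
  jx <- make_jx(matrix(5L, 3, 2), c("a", "b"), introns = gr)
  jx <- assignGenes(jx, gtf)
  rd <- SummarizedExperiment::rowData(jx)
  expect_equal(rd$gene_ids, c("G1", "G1", "."))
  expect_equal(rd$novel, c(FALSE, TRUE, TRUE))
})

test_that("a bunch inherits the union of member gene assignments", {
  gtf <- write_toy_gtf()
  ## two introns sharing start 101: one matches G1, the other nothing
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 101), c(160, 777)), strand = "+")
  jx <- make_jx(matrix(4L, 2, 2), c("a", "b"), introns = gr)
  jx <- addBunches(jx)
  jx <- assignGenes(jx, gtf)
  expect_equal(SummarizedExperiment::rowData(jx)$gene_ids, c("G1", "G1"))
})

test_that("annotation-derived introns are transcript exon gaps", {
  anno <- annotatedIntrons(write_toy_gtf())
  key <- paste(GenomicRanges::seqnames(anno), GenomicRanges::start(anno),
               GenomicRanges::end(anno), anno$gene_id)
  expect_setequal(key, c("chr1 101 160 G1", "chr1 101 200 G1",
                         "chr2 121 180 G2"))
  expect_error(annotatedIntrons(GenomicRanges::GRanges()), "exon")
})

test_that("novel flags fall back to all-novel under an empty annotation", {
  anno <- annotatedIntrons(write_toy_gtf())
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 160))
  expect_false(novelIntronFlags(gr, anno))
  expect_true(novelIntronFlags(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 165)), anno))
})

test_that("multi-sample building takes the union and merges strand twins", {
  gr1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 700),
                                strand = "+")
  gr2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(500, 900), c(700, 1000)), strand = c("*", "+"))
  d <- tempfile()
  dir.create(d)
  p1 <- writeMiniSam(gr1, matrix(4L, 1, 1, dimnames = list(NULL, "s1")),
                     file.path(d, "a"))
  p2 <- writeMiniSam(gr2, matrix(c(3L, 6L), 2, 1,
                                 dimnames = list(NULL, "s2")),
                     file.path(d, "b"))
  mf <- data.frame(sample_id = c("s1", "s2"), path = c(p1, p2),
                   condition = c("x", "y"))
  jx <- suppressWarnings(buildJunctionExperiment(mf))
  ## the unstranded twin of 500-700 merges into the stranded entry
  expect_equal(nrow(jx), 2)
  key <- paste(GenomicRanges::start(jx), GenomicRanges::end(jx))
  cts <- counts(jx)
  expect_equal(unname(cts[match("500 700", key), ]), c(4L, 3L))
  expect_equal(unname(cts[match("900 1000", key), ]), c(0L, 6L))
})
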