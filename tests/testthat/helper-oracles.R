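## Independent oracles and small fixture builders used across tests.

## Hand CIGAR walk: returns data.frame(start, end) of N gaps for one record.
## Deliberately naive (character-by-character) and independent of the
## package's extraction path.
hand_walk_cigar <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  ref <- pos
  out <- data.frame(start = integer(0), end = integer(0))
  for (op in ops) {
    n <- as.integer(sub("[A-Z=]$", "", op))
    type <- sub("^[0-9]+", "", op)
    if (type %in% c("M", "D", "=", "X")) {
      ref <- ref + n
    } else if (type == "N") {
      out <- rbind(out, data.frame(start = ref, end = ref + n - 1L))
      ref <- ref + n
    } ## I, S, H, P: no reference consumption
  }
  out
}

## Brute-force connected components over shared-endpoint edges (O(n^2) BFS).
brute_force_bunches <- function(gr) {
  n <- length(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  str <- as.character(GenomicRanges::strand(gr))
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  adj <- function(i, j) {
    chrom[i] == chrom[j] && str[i] == str[j] &&
      (s[i] == s[j] || e[i] == e[j])
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in seq_len(n)) {
        if (is.na(comp[v]) && adj(u, v)) {
          comp[v] <- cid
          queue <- c(queue, v)
        }
      }
    }
  }
  comp
}

## Brute-force BH step-up: literal definition, no vectorized shortcuts.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) adj[r] <- p[o[r]] * m / r
  if (m > 1)
    for (r in (m - 1):1) adj[r] <- min(adj[r], adj[r + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## All compositions of N into k parts (for DM pmf normalization checks).
compositions <- function(N, k) {
  if (k == 1) return(matrix(N, nrow = 1))
  out <- NULL
  for (first in 0:N) {
    rest <- compositions(N - first, k - 1)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

## Tiny two-gene GTF written to a temp file. Gene G1 (chr1, +): transcript
## T1 exons 1-100, 161-260 and transcript T2 exons 1-100, 201-300 ->
## annotated introns (101,160) and (101,200). Gene G2 (chr2, -): exons
## 50-120, 181-240 -> intron (121,180).
write_toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  attr1 <- 'gene_id "G1"; transcript_id "%s";'
  attr2 <- 'gene_id "G2"; transcript_id "T3";'
  lines <- c(
    paste("chr1", "toy", "exon", 1, 100, ".", "+", ".",
          sprintf(attr1, "T1"), sep = "\t"),
    paste("chr1", "toy", "exon", 161, 260, ".", "+", ".",
          sprintf(attr1, "T1"), sep = "\t"),
    paste("chr1", "toy", "exon", 1, 100, ".", "+", ".",
          sprintf(attr1, "T2"), sep = "\t"),
    paste("chr1", "toy", "exon", 201, 300, ".", "+", ".",
          sprintf(attr1, "T2"), sep = "\t"),
    paste("chr2", "toy", "exon", 50, 120, ".", "-", ".", attr2, sep = "\t"),
    paste("chr2", "toy", "exon", 181, 240, ".", "-", ".", attr2, sep = "\t"))
  writeLines(lines, path)
  path
}

## Quick JunctionExperiment from a counts matrix (introns get distinct
## non-overlapping coordinates unless a GRanges is supplied).
make_jx <- function(counts, condition, introns = NULL) {
  counts <- as.matrix(counts)
  if (is.null(introns)) {
    st <- 1000L + seq_len(nrow(counts)) * 500L
    introns <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(st, st + 100L), strand = "+")
  }
  ## fixtures legitimately use single-sample conditions
  suppressWarnings(JunctionExperiment(counts, introns, condition))
}

## Junction GRanges + counts for builder fixtures: n junctions across a few
## chromosomes, no shared coordinates unless asked for.
random_junctions <- function(n, n_chrom = 3, seed = 1) {
  set.seed(seed)
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE)
  start <- sample(500:200000, n)
  width <- sample(60:5000, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, start + width),
    strand = sample(c("+", "-", "*"), n, replace = TRUE, prob = c(.45, .45, .1)))
  unique(gr)
}
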