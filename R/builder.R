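## The "builder": splice junctions from alignments, support filtering,
## bunch grouping, gene association.

.CIGAR_RE <- "^([0-9]+[MIDNSHP=X])+$"

## N-gap ranges on the reference for parallel vectors of POS and CIGAR.
## Returns a data.frame chrom/start/end/strand, one row per N operation.
.junctions_from_fields <- function(chrom, pos, cigar, strand) {
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = "N")
  nj <- lengths(rl)
  flat <- unlist(rl, use.names = FALSE)
  data.frame(chrom = rep(chrom, nj),
             start = BiocGenerics::start(flat),
             end = BiocGenerics::end(flat),
             strand = rep(strand, nj),
             stringsAsFactors = FALSE)
}

.aggregate_junctions <- function(df) {
  if (nrow(df) == 0L)
    return(GRanges(strand = character(0), count = integer(0)))
  key <- paste(df$chrom, df$start, df$end, df$strand, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.integer(vapply(parts, `[[`, "", 2L))
  end <- as.integer(vapply(parts, `[[`, "", 3L))
  strand <- vapply(parts, `[[`, "", 4L)
  o <- order(chrom, start, end, strand)
  gr <- GRanges(chrom[o], IRanges(start[o], end[o]), strand = strand[o])
  gr$count <- as.integer(tab)[o]
  gr
}

.extract_junctions_sam <- function(file, min_mapq, primary_only) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "@")]
  skipped <- 0L
  if (length(lines) == 0L)
    return(structure(.aggregate_junctions(
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), strand = character(0))),
      skipped = 0L))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 11L
  if (any(bad)) {
    skipped <- skipped + sum(bad)
    warning(sum(bad), " truncated SAM record(s) skipped")
    fields <- fields[!bad]
    lines <- lines[!bad]
  }
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  chrom <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  mapq <- as.integer(vapply(fields, `[[`, "", 5L))
  cigar <- vapply(fields, `[[`, "", 6L)
  ## unmapped records are ignored silently
  keep <- !bitwAnd(flag, 4L)
  if (primary_only)
    keep <- keep & !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  keep <- keep & mapq >= min_mapq & cigar != "*"
  malformed <- keep & !grepl(.CIGAR_RE, cigar)
  if (any(malformed)) {
    skipped <- skipped + sum(malformed)
    warning(sum(malformed), " record(s) with malformed CIGAR skipped")
    keep <- keep & !malformed
  }
  ## splice strand from the XS:A tag when present, else '*'
  xs <- regmatches(lines, regexpr("\tXS:A:[+-]", lines))
  strand <- rep("*", length(lines))
  strand[grepl("\tXS:A:", lines)] <- substring(xs, 7L, 7L)
  df <- .junctions_from_fields(chrom[keep], pos[keep], cigar[keep],
                               strand[keep])
  structure(.aggregate_junctions(df), skipped = skipped)
}

.extract_junctions_bam <- function(file, min_mapq, primary_only) {
  fl <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (primary_only) FALSE else NA,
    isSupplementaryAlignment = if (primary_only) FALSE else NA)
  param <- Rsamtools::ScanBamParam(
    flag = fl, mapqFilter = min_mapq,
    what = c("rname", "pos", "cigar"), tag = "XS")
  res <- Rsamtools::scanBam(file, param = param)[[1L]]
  cigar <- res$cigar
  ok <- !is.na(cigar) & cigar != "*"
  skipped <- 0L
  malformed <- ok & !grepl(.CIGAR_RE, cigar)
  if (any(malformed)) {
    skipped <- sum(malformed)
    warning(skipped, " record(s) with malformed CIGAR skipped")
    ok <- ok & !malformed
  }
  xs <- res$tag$XS
  strand <- if (is.null(xs)) rep("*", length(cigar)) else {
    s <- as.character(xs); s[is.na(s)] <- "*"; s
  }
  df <- .junctions_from_fields(as.character(res$rname)[ok], res$pos[ok],
                               cigar[ok], strand[ok])
  structure(.aggregate_junctions(df), skipped = skipped)
}

#' Extract splice junctions from a spliced alignment file
#'
#' Walks each primary, mapped alignment's CIGAR from its 1-based start:
#' `M`, `D`, `=` and `X` consume reference, `I`, `S`, `H` and `P` do not, and
#' every `N` operation defines one intron (first to last skipped reference
#' base, 1-based closed) contributing one supporting read. The splice strand
#' is taken from the `XS:A` tag when present, otherwise `*`.
#'
#' @param file path to a SAM (text) or BAM alignment file; coordinate
#'   sorting is not required.
#' @param min_mapq minimum mapping quality; records below it are ignored.
#' @param primary_only drop secondary and supplementary alignments
#'   (default `TRUE`).
#' @return `GRanges` of distinct junctions, sorted by chromosome, strand and
#'   coordinates, with a metadata column `count` (supporting reads). The
#'   number of records skipped for malformed CIGAR strings is attached as
#'   attribute `"skipped"` and reported via warnings; unmapped records are
#'   ignored silently.
#' @examples
#' sam <- tempfile(fileext = ".sam")
#' writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
#'   "r1\t0\tchr1\t100\t60\t10M50N10M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAA\t*"),
#'   sam)
#' extractJunctions(sam)  # one junction chr1:110-159
#' @export
extractJunctions <- function(file, min_mapq = 0L, primary_only = TRUE) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  ext <- tolower(tools::file_ext(file))
  if (ext == "bam")
    .extract_junctions_bam(file, min_mapq, primary_only)
  else
    .extract_junctions_sam(file, min_mapq, primary_only)
}

#' Read a sample manifest
#'
#' A tab-separated file with columns `sample_id`, `path`, `condition`
#' describing one alignment (SAM/BAM) or junction-count table per sample.
#'
#' @param path manifest file path.
#' @return data.frame with the three columns, in file order.
#' @export
readSampleManifest <- function(path) {
  mf <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "path", "condition")
  if (!all(need %in% colnames(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (nrow(mf) == 0L) stop("manifest is empty")
  mf
}

#' Build a JunctionExperiment from per-sample alignments or count tables
#'
#' Extracts junctions from every sample listed in the manifest (or reads
#' precomputed per-sample junction-count TSVs with columns
#' `chrom,start,end,strand,count`), takes the union of junctions across
#' samples, and assembles the counts matrix. Junctions differing only by
#' strand are kept distinct only when both strands are observed: if a
#' junction is seen both stranded and unstranded (`*`), the unstranded
#' counts are merged into the stranded entry.
#'
#' @param manifest data.frame as returned by [readSampleManifest()], or a
#'   path to the manifest file.
#' @param min_mapq,primary_only passed to [extractJunctions()].
#' @return A [JunctionExperiment-class] with one row per junction observed in
#'   any sample (zero where unobserved).
#' @export
buildJunctionExperiment <- function(manifest, min_mapq = 0L,
                                    primary_only = TRUE) {
  if (is.character(manifest)) manifest <- readSampleManifest(manifest)
  if (nrow(manifest) == 0L) stop("manifest is empty")
  per_sample <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (tolower(tools::file_ext(p)) %in% c("sam", "bam"))
      extractJunctions(p, min_mapq = min_mapq, primary_only = primary_only)
    else
      .read_count_table(p)
  })
  .merge_junction_counts(per_sample, manifest$sample_id, manifest$condition)
}

.read_count_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("chrom", "start", "end", "strand", "count")
  if (!all(need %in% colnames(tb)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  gr <- GRanges(tb$chrom, IRanges(tb$start, tb$end),
                strand = ifelse(tb$strand %in% c("+", "-"), tb$strand, "*"))
  gr$count <- as.integer(tb$count)
  o <- order(tb$chrom, tb$start, tb$end, as.character(strand(gr)))
  gr[o]
}

.jx_key <- function(gr, with_strand = TRUE) {
  if (with_strand)
    paste(as.character(seqnames(gr)), start(gr), end(gr),
          as.character(strand(gr)), sep = ":")
  else
    paste(as.character(seqnames(gr)), start(gr), end(gr), sep = ":")
}

.merge_junction_counts <- function(per_sample, sample_ids, condition) {
  all_gr <- do.call(c, lapply(per_sample, granges))
  if (length(all_gr) == 0L)
    stop("no junctions found in any sample")
  uni <- unique(all_gr)
  ## a coordinate seen stranded anywhere collapses its '*' twin
  stranded_keys <- .jx_key(uni, FALSE)[as.character(strand(uni)) != "*"]
  drop <- as.character(strand(uni)) == "*" &
    .jx_key(uni, FALSE) %in% stranded_keys
  uni <- BiocGenerics::sort(uni[!drop])
  ukey <- .jx_key(uni)
  ukey_nostrand <- .jx_key(uni, FALSE)
  counts <- matrix(0L, nrow = length(uni), ncol = length(per_sample))
  for (j in seq_along(per_sample)) {
    g <- per_sample[[j]]
    idx <- match(.jx_key(g), ukey)
    miss <- is.na(idx)
    if (any(miss)) {
      ## unstranded observation of a junction known stranded: merge counts
      idx2 <- match(.jx_key(g, FALSE)[miss], ukey_nostrand)
      idx[miss] <- idx2
    }
    ok <- !is.na(idx)
    cc <- counts[, j]
    cc[idx[ok]] <- cc[idx[ok]] + g$count[ok]
    counts[, j] <- cc
  }
  JunctionExperiment(counts, uni, condition, sample_names = sample_ids)
}

#' Filter weakly supported introns
#'
#' Removes introns whose read support never reaches `min_reads`: with the
#' default `strategy = "any"`, an intron is retained iff its count is at
#' least `min_reads` in at least one sample (the stricter `"all"` strategy
#' requires the threshold in every sample, at the cost of discarding
#' condition-specific introns).
#'
#' @param jx a [JunctionExperiment-class].
#' @param min_reads minimum supporting reads (default 3).
#' @param strategy `"any"` (default) or `"all"`; see Details.
#' @return the filtered `JunctionExperiment` (samples unchanged).
#' @export
filterIntrons <- function(jx, min_reads = 3L,
                          strategy = c("any", "all")) {
  strategy <- match.arg(strategy)
  if (min_reads < 1L) stop("min_reads must be >= 1")
  cts <- counts(jx)
  keep <- if (strategy == "any")
    rowSums(cts >= min_reads) >= 1L
  else
    rowSums(cts >= min_reads) == ncol(cts)
  jx[keep, ]
}

## union-find over intron endpoint keys
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Group introns sharing a splice site into bunches
#'
#' Two introns on the same chromosome and strand are linked when they share a
#' start or an end coordinate; bunches are the connected components of this
#' graph, so membership is transitive. Bunch identifiers are assigned
#' deterministically in order of chromosome then leftmost member start.
#'
#' @param introns a `GRanges` of deduplicated introns.
#' @return character vector of bunch ids (`"b000001"`, ...), parallel to
#'   `introns`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(100, 100, 400), c(200, 300, 500)))
#' groupBunches(gr)  # first two introns share start 100
#' @export
groupBunches <- function(introns) {
  n <- length(introns)
  if (n == 0L) return(character(0))
  chrom <- as.character(seqnames(introns))
  str <- as.character(strand(introns))
  skey <- paste(chrom, str, start(introns), "s")
  ekey <- paste(chrom, str, end(introns), "e")
  parent <- seq_len(n)
  for (key in list(skey, ekey)) {
    grp <- split(seq_len(n), key)
    for (g in grp) {
      if (length(g) > 1L) {
        r <- .uf_find(parent, g[1L])
        for (i in g[-1L]) {
          ri <- .uf_find(parent, i)
          if (ri != r) parent[ri] <- r
        }
      }
    }
  }
  root <- vapply(seq_len(n), function(i) .uf_find(parent, i), 1L)
  ## deterministic ids: order components by chrom, then min start
  comp_min_start <- tapply(start(introns), root, min)
  comp_chrom <- tapply(chrom, root, `[`, 1L)
  ord <- order(comp_chrom, comp_min_start)
  ids <- stats::setNames(sprintf("b%06d", order(ord)), names(comp_min_start))
  unname(ids[as.character(root)])
}

#' Assign bunch ids to a JunctionExperiment
#'
#' @param jx a [JunctionExperiment-class].
#' @return `jx` with a `bunch_id` column added to `rowData`.
#' @export
addBunches <- function(jx) {
  rowData(jx)$bunch_id <- groupBunches(rowRanges(jx))
  jx
}

#' Annotated introns from a GTF gene annotation
#'
#' Derives introns as the gaps between consecutive exons of each transcript
#' in the annotation.
#'
#' @param gtf path to a GTF file with `exon` features carrying `gene_id`
#'   attributes, or a `GRanges` as returned by `rtracklayer::import`.
#' @return `GRanges` of unique annotated introns with a `gene_id` metadata
#'   column (an intron shared by several genes appears once per gene).
#' @export
annotatedIntrons <- function(gtf) {
  anno <- if (is.character(gtf))
    rtracklayer::import(gtf, format = "gtf")
  else gtf
  ex <- anno[anno$type == "exon"]
  if (length(ex) == 0L) stop("annotation contains no exon features")
  if (is.null(ex$transcript_id) || is.null(ex$gene_id))
    stop("exon features must carry transcript_id and gene_id attributes")
  grl <- GenomicRanges::split(granges(ex), ex$transcript_id)
  tx_range <- unlist(range(grl))
  introns_by_tx <- IRanges::psetdiff(tx_range, grl)
  tx2gene <- vapply(GenomicRanges::split(ex$gene_id, ex$transcript_id),
                    `[`, "", 1L)
  flat <- unlist(introns_by_tx, use.names = TRUE)
  flat$gene_id <- tx2gene[names(flat)]
  names(flat) <- NULL
  unique(flat)
}

## gene sets at annotated intron boundaries, keyed by chrom:pos
.boundary_gene_map <- function(anno_introns) {
  key <- c(paste(as.character(seqnames(anno_introns)), start(anno_introns)),
           paste(as.character(seqnames(anno_introns)), end(anno_introns)))
  gene <- rep(anno_introns$gene_id, 2L)
  split(gene, key)
}

#' Associate introns (and bunches) with annotated genes
#'
#' An intron is assigned every gene having an annotated intron that shares
#' its start or end coordinate on the same chromosome; a bunch receives the
#' union of its members' genes. Introns matching no annotated boundary get an
#' empty assignment (candidate novel junctions).
#'
#' @param jx a [JunctionExperiment-class] (bunches optional).
#' @param annotation GTF path or `GRanges`, see [annotatedIntrons()].
#' @return `jx` with `rowData` columns `gene_ids` (comma-joined, `"."` when
#'   none) and `novel` (no exact coordinate match among annotated introns).
#' @export
assignGenes <- function(jx, annotation) {
  anno <- annotatedIntrons(annotation)
  bmap <- .boundary_gene_map(anno)
  chrom <- as.character(seqnames(jx))
  g_start <- bmap[paste(chrom, start(jx))]
  g_end <- bmap[paste(chrom, end(jx))]
  genes <- mapply(function(a, b) sort(unique(c(a, b))),
                  g_start, g_end, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  if (!is.null(bunchIds(jx))) {
    by_bunch <- split(genes, bunchIds(jx))
    bunch_genes <- lapply(by_bunch, function(gs) sort(unique(unlist(gs))))
    genes <- bunch_genes[bunchIds(jx)]
  }
  rowData(jx)$gene_ids <- unname(vapply(genes, function(g)
    if (length(g)) paste(g, collapse = ",") else ".", ""))
  rowData(jx)$novel <- novelIntronFlags(rowRanges(jx), anno)
  jx
}

#' Flag introns absent from the annotation
#'
#' @param introns `GRanges` of observed introns.
#' @param annotation GTF path or `GRanges` ([annotatedIntrons()] output is
#'   accepted directly).
#' @param ignore_strand match on (chrom, start, end) only (default `TRUE`).
#' @return logical vector: `TRUE` when the intron's coordinates are not
#'   among the annotation-derived introns.
#' @export
novelIntronFlags <- function(introns, annotation, ignore_strand = TRUE) {
  anno <- if (is(annotation, "GRanges") && !is.null(annotation$gene_id))
    annotation
  else annotatedIntrons(annotation)
  !(.jx_key(introns, !ignore_strand) %in% .jx_key(anno, !ignore_strand))
}

#' Write the intron count table
#'
#' One row per intron: coordinates, bunch, gene association, novelty flag,
#' then one integer count column per sample.
#'
#' @param jx a processed [JunctionExperiment-class].
#' @param path output TSV path.
#' @export
writeIntronTable <- function(jx, path) {
  rd <- rowData(jx)
  df <- data.frame(
    chrom = as.character(seqnames(jx)),
    start = start(jx), end = end(jx),
    strand = sub("\\*", ".", as.character(strand(jx))),
    bunch_id = if (is.null(rd$bunch_id)) "." else rd$bunch_id,
    gene_ids = if (is.null(rd$gene_ids)) "." else rd$gene_ids,
    novel = if (is.null(rd$novel)) NA else rd$novel,
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(counts(jx)))
  .write_tsv(df, path, "intron count table v1")
  invisible(path)
}

.write_tsv <- function(df, path, version_tag) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# IntronDiff ", version_tag), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
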