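## Synthetic junction-count experiments with known ground truth, mini SAM
## fixtures for the builder, and benchmarking metrics.

#' Simulate ground-truth splicing parameters for a gene panel
#'
#' Each gene is one bunch of `k` introns sharing a splice site. Baseline
#' parameters: total gene output drawn log-normally, intron proportions from
#' a flat Dirichlet (sorted decreasing), NB dispersion uniform on
#' `phi_range`. Genes are assigned to perturbation classes: `NONE`
#' (unchanged), `DE` (total mean halved or doubled in each perturbed
#' condition, ratios unchanged), `DS` (proportions of the top two introns
#' swapped, total unchanged), `DE-DS` (both).
#'
#' @param n_genes number of genes (default 500).
#' @param class_props named proportions over `NONE`, `DE`, `DS`, `DE-DS`
#'   (default 1/4 each).
#' @param m number of conditions (default 2).
#' @param perturbed_conditions which conditions receive the perturbation
#'   (default all but the first); each perturbed condition draws its own DE
#'   factor.
#' @param k_choices,k_probs bunch sizes and their sampling probabilities.
#' @param mean_log,mean_sdlog log-normal parameters of the total gene mean
#'   (defaults `log(50)`, 0.7).
#' @param phi_range NB dispersion range (default `c(0.1, 0.5)`).
#' @param concentration Dirichlet-multinomial total concentration governing
#'   sample-to-sample ratio variability (default 10).
#' @param seed integer seed; the truth is reproducible given it.
#' @return object of class `sim_truth`: a list with per-gene `genes`
#'   data.frame (`gene_id`, `class`, `k`, `phi`), `props` (list of `m x k`
#'   per-condition proportion matrices), `total_mean` (`n_genes x m`),
#'   and the generator settings.
#' @export
simulateTruth <- function(n_genes = 500,
                          class_props = c(NONE = 0.25, DE = 0.25,
                                          DS = 0.25, `DE-DS` = 0.25),
                          m = 2, perturbed_conditions = NULL,
                          k_choices = 2:3, k_probs = c(0.6, 0.4),
                          mean_log = log(50), mean_sdlog = 0.7,
                          phi_range = c(0.1, 0.5), concentration = 10,
                          seed = 1L) {
  stopifnot(abs(sum(class_props) - 1) < 1e-8, m >= 2)
  if (is.null(perturbed_conditions))
    perturbed_conditions <- setdiff(seq_len(m), 1L)
  set.seed(seed)
  n_per_class <- diff(c(0L, round(cumsum(class_props) * n_genes)))
  cls <- sample(rep(names(class_props), times = n_per_class))
  k <- sample(k_choices, n_genes, replace = TRUE, prob = k_probs)
  phi <- stats::runif(n_genes, phi_range[1L], phi_range[2L])
  base_mean <- stats::rlnorm(n_genes, mean_log, mean_sdlog)
  props <- vector("list", n_genes)
  total_mean <- matrix(rep(base_mean, m), ncol = m)
  for (g in seq_len(n_genes)) {
    p0 <- stats::rgamma(k[g], 1)
    p0 <- sort(p0 / sum(p0), decreasing = TRUE)
    P <- matrix(rep(p0, each = m), nrow = m)
    for (i in perturbed_conditions) {
      if (cls[g] %in% c("DE", "DE-DS"))
        total_mean[g, i] <- base_mean[g] * sample(c(0.5, 2), 1L)
      if (cls[g] %in% c("DS", "DE-DS"))
        P[i, c(1L, 2L)] <- P[i, c(2L, 1L)]
    }
    props[[g]] <- P
  }
  structure(list(
    genes = data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                       class = cls, k = k, phi = phi,
                       stringsAsFactors = FALSE),
    props = props, total_mean = total_mean, m = m,
    concentration = concentration, seed = seed), class = "sim_truth")
}

#' Simulate a junction-count experiment from a ground truth
#'
#' For every gene and sample, a total read count is drawn
#' `NB(total_mean * L_j, phi)` with a per-sample log-normal library-size
#' factor `L_j` (sdlog `libsize_sdlog`), then split across the bunch's
#' introns by a Dirichlet-multinomial with concentrations
#' `concentration * proportions`. Intron coordinates place each gene's
#' introns on a shared 5' splice site so the builder's bunch grouping
#' recovers the planted bunches. Byte-reproducible given `truth` and
#' `seed`.
#'
#' @param truth a [simulateTruth()] object.
#' @param n_per_condition samples per condition (scalar or length-`m`).
#' @param libsize_sdlog log-normal sdlog of library-size factors
#'   (default 0.2).
#' @param seed integer seed.
#' @return a [JunctionExperiment-class] with `rowData` columns `gene_ids`
#'   (the true gene), `bunch_id` and `true_class`; the truth object and the
#'   library factors are stored in `metadata()`.
#' @export
simulateJunctionExperiment <- function(truth, n_per_condition = 25,
                                       libsize_sdlog = 0.2, seed = 2L) {
  stopifnot(inherits(truth, "sim_truth"))
  m <- truth$m
  npc <- rep_len(n_per_condition, m)
  n <- sum(npc)
  cond <- factor(rep(paste0("cond", seq_len(m)), times = npc))
  set.seed(seed)
  lib <- stats::rlnorm(n, 0, libsize_sdlog)
  ng <- nrow(truth$genes)
  k <- truth$genes$k
  rows <- sum(k)
  counts <- matrix(0L, nrow = rows, ncol = n)
  row_gene <- rep(seq_len(ng), k)
  offset <- c(0L, cumsum(k))
  for (g in seq_len(ng)) {
    kg <- k[g]
    alpha_by_cond <- lapply(seq_len(m), function(i)
      pmax(truth$concentration * truth$props[[g]][i, ], 1e-6))
    for (j in seq_len(n)) {
      i <- as.integer(cond[j])
      tot <- stats::rnbinom(1L, size = 1 / truth$genes$phi[g],
                            mu = truth$total_mean[g, i] * lib[j])
      counts[(offset[g] + 1L):offset[g + 1L], j] <-
        if (tot > 0) rdirmult(1L, tot, alpha_by_cond[[i]])[, 1L]
        else integer(kg)
    }
  }
  ## coordinates: one bunch per gene, members share the donor site
  gene_anchor <- 1000L + (seq_len(ng) - 1L) * 10000L
  member <- unlist(lapply(k, seq_len))
  gr <- GRanges("chrS",
                IRanges(start = gene_anchor[row_gene] + 1L,
                        end = gene_anchor[row_gene] + 200L + member * 150L),
                strand = "+")
  jx <- JunctionExperiment(counts, gr, cond,
                           sample_names = sprintf("s%03d", seq_len(n)))
  rowData(jx)$gene_ids <- truth$genes$gene_id[row_gene]
  rowData(jx)$true_class <- truth$genes$class[row_gene]
  jx <- addBunches(jx)
  metadata(jx)$truth <- truth
  metadata(jx)$lib_factors <- lib
  jx
}

#' Write mini SAM files realizing a junction-count truth table
#'
#' Emits one syntactically valid SAM file per sample in which every
#' supporting read is a spliced record (`aM nN bM`) spanning its junction,
#' so that [extractJunctions()] recovers the truth table exactly. A few
#' unspliced and unmapped decoy records are interleaved to exercise the
#' extractor's filters.
#'
#' @param introns `GRanges` of junctions (starts must exceed `read_len` so
#'   reads fit on the reference).
#' @param count_matrix integer matrix, junctions x samples.
#' @param dir output directory (created).
#' @param read_len total aligned read length (default 100).
#' @param n_decoys unspliced decoy records per sample (default 5).
#' @param seed integer seed for flank placement.
#' @return character vector of SAM paths, named by sample; the truth table
#'   TSV is written alongside as `truth.tsv`.
#' @export
writeMiniSam <- function(introns, count_matrix, dir, read_len = 100L,
                         n_decoys = 5L, seed = 3L) {
  count_matrix <- as.matrix(count_matrix)
  stopifnot(length(introns) == nrow(count_matrix))
  if (any(start(introns) <= read_len))
    stop("junction start(s) within read_len of the reference origin")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  chrom <- as.character(seqnames(introns))
  chr_len <- tapply(end(introns) + read_len + 10L, chrom, max)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chr_len),
                      as.integer(chr_len)))
  sam_names <- colnames(count_matrix)
  if (is.null(sam_names))
    sam_names <- sprintf("s%03d", seq_len(ncol(count_matrix)))
  seq_str <- strrep("A", read_len)
  qual_str <- strrep("I", read_len)
  paths <- character(ncol(count_matrix))
  for (j in seq_len(ncol(count_matrix))) {
    cnt <- count_matrix[, j]
    idx <- rep(seq_along(introns), cnt)
    recs <- character(0)
    if (length(idx)) {
      a <- sample(5:(read_len - 5L), length(idx), replace = TRUE)
      b <- read_len - a
      st <- start(introns)[idx]
      en <- end(introns)[idx]
      nlen <- en - st + 1L
      strd <- as.character(strand(introns))[idx]
      tag <- ifelse(strd %in% c("+", "-"), paste0("\tXS:A:", strd), "")
      recs <- sprintf(
        "r%06d\t0\t%s\t%d\t60\t%dM%dN%dM\t*\t0\t0\t%s\t%s%s",
        seq_along(idx), chrom[idx], st - a, a, nlen, b,
        seq_str, qual_str, tag)
    }
    if (n_decoys > 0L) {
      dc <- sprintf("d%03d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                    seq_len(n_decoys),
                    sample(names(chr_len), n_decoys, replace = TRUE),
                    sample(seq_len(200L), n_decoys, replace = TRUE),
                    read_len, seq_str, qual_str)
      un <- sprintf("u001\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                    seq_str, qual_str)
      recs <- c(recs, dc, un)
    }
    p <- file.path(dir, paste0(sam_names[j], ".sam"))
    writeLines(c(header, recs), p)
    paths[j] <- p
  }
  names(paths) <- sam_names
  truth <- data.frame(chrom = chrom, start = start(introns),
                      end = end(introns),
                      strand = as.character(strand(introns)),
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(count_matrix))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Benchmark differential-splicing calls against a simulated truth
#'
#' Gold standards follow the simulation design: genes with ratio changes
#' (`DS`, `DE-DS`) for the ratio test, genes with any splicing-abundance
#' change (`DE`, `DS`, `DE-DS`) for the abundance test. Any called gene
#' outside the simulated panel counts as a false positive.
#'
#' @param called_genes character vector of called gene ids.
#' @param truth a [simulateTruth()] object.
#' @param mode `"DSR"` or `"DSA"`.
#' @return list with `sensitivity`, `precision`, `f1`, `tp`, `fp`, `fn`;
#'   with no calls, precision is reported as 0 with
#'   `precision_defined = FALSE`.
#' @export
evaluateCalls <- function(called_genes, truth, mode = c("DSR", "DSA")) {
  mode <- match.arg(mode)
  gold_classes <- if (mode == "DSR") c("DS", "DE-DS")
  else c("DE", "DS", "DE-DS")
  gold <- truth$genes$gene_id[truth$genes$class %in% gold_classes]
  called <- unique(called_genes)
  tp <- sum(called %in% gold)
  fp <- length(called) - tp
  fn <- length(gold) - tp
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  pr_defined <- (tp + fp) > 0
  pr <- if (pr_defined) tp / (tp + fp) else 0
  f1 <- if (sn + pr > 0) 2 * sn * pr / (sn + pr) else 0
  list(sensitivity = sn, precision = pr, f1 = f1,
       tp = tp, fp = fp, fn = fn, precision_defined = pr_defined)
}
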