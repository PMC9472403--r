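## End-to-end pipeline: builder -> DSA/DSR -> post-stats -> TSV writers,
## plus the multi-way versus pairwise comparison wrapper.

#' Run the full differential-splicing pipeline
#'
#' Builds the junction experiment from a sample manifest (SAM/BAM
#' alignments or precomputed count tables), filters weakly supported
#' introns, groups bunches, optionally associates genes from a GTF, runs the
#' requested tests, and writes the output tables plus a run log. Per-feature
#' model failures are recorded as status rows and never abort the run.
#'
#' @param manifest path to, or data.frame of, the sample manifest
#'   (`sample_id`, `path`, `condition`).
#' @param out_dir output directory (created if needed).
#' @param annotation optional GTF path for gene association and novelty
#'   flags.
#' @param min_reads,filter_strategy intron support filter, see
#'   [filterIntrons()].
#' @param mean_cutoff DSA low-mean filter threshold, see [runDSA()].
#' @param p_cut,dpsi_cut,use_q significance thresholds, see
#'   [significantFeatures()].
#' @param tests `"both"` (default), `"dsa"` or `"dsr"`.
#' @param min_mapq,primary_only alignment filters, see [extractJunctions()].
#' @return (invisibly) a list with the `JunctionExperiment`, the result
#'   tables, the significant-gene vectors and the written file paths.
#' @export
runPipeline <- function(manifest, out_dir, annotation = NULL,
                        min_reads = 3L, filter_strategy = "any",
                        mean_cutoff = 1, p_cut = 0.05, dpsi_cut = 0.05,
                        use_q = FALSE, tests = c("both", "dsa", "dsr"),
                        min_mapq = 0L, primary_only = TRUE) {
  tests <- match.arg(tests)
  if (is.character(manifest)) manifest <- readSampleManifest(manifest)
  missing_files <- !file.exists(manifest$path)
  if (any(missing_files))
    stop("input file(s) not found: ",
         paste(manifest$path[missing_files], collapse = ", "))
  t0 <- Sys.time()
  jx <- buildJunctionExperiment(manifest, min_mapq = min_mapq,
                                primary_only = primary_only)
  n_raw <- nrow(jx)
  jx <- filterIntrons(jx, min_reads = min_reads,
                      strategy = filter_strategy)
  jx <- addBunches(jx)
  if (!is.null(annotation)) jx <- assignGenes(jx, annotation)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(introns = file.path(out_dir, "intron_table.tsv"))
  writeIntronTable(jx, paths$introns)
  out <- list(jx = jx, paths = paths)
  genes <- character(0)
  if (tests %in% c("both", "dsa")) {
    dsa <- runDSA(jx, mean_cutoff = mean_cutoff)
    paths$dsa <- file.path(out_dir, "dsa_results.tsv")
    .write_tsv(dsa, paths$dsa, "DSA results v1")
    sig <- significantFeatures(dsa, "dsa", p_cut = p_cut, use_q = use_q)
    out$dsa <- dsa
    out$dsa_genes <- genesWithDS(sig)
    genes <- union(genes, out$dsa_genes)
  }
  if (tests %in% c("both", "dsr")) {
    dsr <- runDSR(jx)
    paths$dsr_bunches <- file.path(out_dir, "dsr_bunches.tsv")
    paths$dsr_introns <- file.path(out_dir, "dsr_introns.tsv")
    .write_tsv(dsr$bunches, paths$dsr_bunches, "DSR bunch results v1")
    .write_tsv(dsr$introns, paths$dsr_introns, "DSR intron results v1")
    sig <- significantFeatures(dsr, "dsr", p_cut = p_cut,
                               dpsi_cut = dpsi_cut, use_q = use_q)
    out$dsr <- dsr
    out$dsr_genes <- genesWithDS(sig)
    genes <- union(genes, out$dsr_genes)
  }
  gene_df <- data.frame(gene_id = sort(genes), stringsAsFactors = FALSE)
  if (length(genes)) {
    gene_df$dsa <- if (!is.null(out$dsa_genes))
      gene_df$gene_id %in% out$dsa_genes else NA
    gene_df$dsr <- if (!is.null(out$dsr_genes))
      gene_df$gene_id %in% out$dsr_genes else NA
  }
  paths$genes <- file.path(out_dir, "gene_summary.tsv")
  .write_tsv(gene_df, paths$genes, "gene summary v1")
  paths$log <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste0("IntronDiff ",
           as.character(utils::packageVersion("IntronDiff"))),
    paste0("date: ", format(t0)),
    paste0("samples: ", nrow(manifest),
           "  conditions: ", length(unique(manifest$condition))),
    paste0("introns raw/filtered: ", n_raw, "/", nrow(jx)),
    paste0("params: min_reads=", min_reads,
           " filter_strategy=", filter_strategy,
           " mean_cutoff=", mean_cutoff,
           " p_cut=", p_cut, " dpsi_cut=", dpsi_cut,
           " use_q=", use_q, " tests=", tests,
           " min_mapq=", min_mapq, " primary_only=", primary_only),
    paste0("elapsed_sec: ",
           round(as.numeric(Sys.time() - t0, units = "secs"), 2))),
    paths$log)
  out$paths <- paths
  out$genes <- gene_df
  invisible(out)
}

#' Multi-way versus pairwise differential-splicing comparison
#'
#' Runs one joint test per feature across all `m` conditions of the
#' experiment, and optionally every pairwise two-condition comparison for
#' cross-validation of the joint calls. With `m = 2` the multi-way path is
#' the pairwise path.
#'
#' @param jx a [JunctionExperiment-class] with `m >= 2` conditions.
#' @param test `"dsr"` (default) or `"dsa"`.
#' @param pairwise also run all condition pairs (default `TRUE`).
#' @param p_cut,dpsi_cut,use_q significance thresholds, see
#'   [significantFeatures()].
#' @param mean_cutoff DSA low-mean threshold.
#' @return list with `multiway` (result table(s)), `multiway_genes`,
#'   and when `pairwise` is set, `pairwise` (named list of result tables)
#'   and `pairwise_genes` (named list of gene vectors).
#' @export
compareMultiway <- function(jx, test = c("dsr", "dsa"), pairwise = TRUE,
                            p_cut = 0.05, dpsi_cut = 0.05, use_q = FALSE,
                            mean_cutoff = 1) {
  test <- match.arg(test)
  run_one <- function(x) {
    if (test == "dsa") {
      res <- runDSA(x, mean_cutoff = mean_cutoff)
      sig <- significantFeatures(res, "dsa", p_cut = p_cut, use_q = use_q)
    } else {
      res <- runDSR(x)
      sig <- significantFeatures(res, "dsr", p_cut = p_cut,
                                 dpsi_cut = dpsi_cut, use_q = use_q)
    }
    list(res = res, genes = genesWithDS(sig))
  }
  mw <- run_one(jx)
  out <- list(multiway = mw$res, multiway_genes = mw$genes)
  if (pairwise) {
    lv <- levels(sampleConditions(jx))
    prs <- utils::combn(lv, 2L)
    pw <- lapply(seq_len(ncol(prs)), function(j) {
      keep <- sampleConditions(jx) %in% prs[, j]
      sub <- jx[, keep]
      sub$condition <- droplevels(sub$condition)
      run_one(sub)
    })
    names(pw) <- paste0(prs[1L, ], ".vs.", prs[2L, ])
    out$pairwise <- lapply(pw, `[[`, "res")
    out$pairwise_genes <- lapply(pw, `[[`, "genes")
  }
  out
}
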