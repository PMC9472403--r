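## Multiple-testing correction, significance filters, gene-level
## aggregation, event-effect classes, tissue-specificity screen.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the family is all tested features of one test type in one run.
#'
#' @param p vector of raw p-values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @return adjusted p-values (q-values).
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select significant differential-splicing features
#'
#' DSR features are reported when the bunch p-value passes `p_cut` and the
#' intron-level effect reaches `dpsi_cut`; DSA features when the p-value
#' passes `p_cut` (the low-mean filter has already restricted the family).
#' Filtering on raw p-values follows the usual reporting convention here;
#' `use_q = TRUE` switches the same cutoff to BH-adjusted values.
#'
#' @param results for `type = "dsr"` the list from [runDSR()]; for
#'   `type = "dsa"` the data.frame from [runDSA()].
#' @param type `"dsr"` or `"dsa"`.
#' @param p_cut p-value threshold (default 0.05).
#' @param dpsi_cut minimum absolute splicing-ratio change, DSR only
#'   (default 0.05).
#' @param use_q filter on q-values instead of raw p-values.
#' @return the significant rows: for DSR, the intron table (rows of
#'   significant bunches whose intron passes `dpsi_cut`); for DSA, rows of
#'   the result table with status `TEST`.
#' @export
significantFeatures <- function(results, type = c("dsr", "dsa"),
                                p_cut = 0.05, dpsi_cut = 0.05,
                                use_q = FALSE) {
  type <- match.arg(type)
  if (type == "dsa") {
    p <- if (use_q) results$q_value else results$p_value
    keep <- results$status == "TEST" & !is.na(p) & p < p_cut
    return(results[keep, , drop = FALSE])
  }
  b <- results$bunches
  p <- if (use_q) b$q_value else b$p_value
  sig_b <- b$bunch_id[b$status == "TEST" & !is.na(p) & p < p_cut]
  ii <- results$introns
  ii[ii$bunch_id %in% sig_b & !is.na(ii$dpsi) & ii$dpsi >= dpsi_cut, ,
     drop = FALSE]
}

#' Genes with differential splicing
#'
#' A gene is called differentially spliced when at least one of its
#' associated significant features exists; features with no gene assignment
#' are reported under a synthetic locus id built from their coordinates.
#'
#' @param features data.frame of significant features with columns
#'   `gene_ids` (comma-joined, `"."` for none) and coordinates.
#' @return sorted character vector of unique gene (or synthetic locus) ids.
#' @export
genesWithDS <- function(features) {
  if (nrow(features) == 0L) return(character(0))
  genes <- strsplit(features$gene_ids, ",", fixed = TRUE)
  none <- features$gene_ids == "." | is.na(features$gene_ids)
  genes[none] <- paste0("novel:", features$chrom[none], ":",
                        features$start[none], "-", features$end[none])
  sort(unique(unlist(genes)))
}

#' Classify the effect size of a splicing event
#'
#' Events are binned by the absolute splicing-ratio change: `stable`
#' (`dpsi < 0.05`), `variable` (`0.05 <= dpsi < 0.5`), `switch`
#' (`dpsi >= 0.5`); an event absent from either compared group is
#' `not_present` regardless of dpsi.
#'
#' @param dpsi absolute splicing-ratio difference (vectorized).
#' @param present_a,present_b logical presence flags in the two groups.
#' @return character vector of class labels.
#' @export
classifyEvent <- function(dpsi, present_a = TRUE, present_b = TRUE) {
  n <- max(length(dpsi), length(present_a), length(present_b))
  dpsi <- rep_len(dpsi, n)
  present <- rep_len(present_a, n) & rep_len(present_b, n)
  out <- rep("not_present", n)
  out[present & dpsi < 0.05] <- "stable"
  out[present & dpsi >= 0.05 & dpsi < 0.5] <- "variable"
  out[present & dpsi >= 0.5] <- "switch"
  out
}

#' Cross-group event-class matrix
#'
#' Counts events per class for every ordered pair of groups, given
#' per-group dpsi and presence tables.
#'
#' @param dpsi matrix of dpsi values, events x group pairs (column names
#'   `"a.vs.b"`), or a function taking two group names.
#' @param presence logical matrix events x groups.
#' @return data.frame with columns `group_a`, `group_b`, `stable`,
#'   `variable`, `switch`, `not_present`.
#' @export
eventClassMatrix <- function(dpsi, presence) {
  groups <- colnames(presence)
  pairs <- utils::combn(groups, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    d <- if (is.function(dpsi)) dpsi(a, b) else dpsi[, paste0(a, ".vs.", b)]
    cls <- classifyEvent(d, presence[, a], presence[, b])
    tab <- table(factor(cls, levels = c("stable", "variable", "switch",
                                        "not_present")))
    data.frame(group_a = a, group_b = b, as.list(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tissue-specificity screen for introns
#'
#' An intron is "present" in a tissue when it has more than `read_cut` reads
#' in at least `present_frac` of that tissue's samples. For each tissue
#' where the intron is absent, the expected number of absent samples is
#' `E = present_frac_complement * n_samples` (with the default 15% presence
#' rule, `E = 0.85 n`), compared to the observed absent count `O` by a
#' chi-square goodness-of-fit statistic summed over the absent tissues; the
#' statistic is only applied to introns with `O >= E` in every absent tissue
#' (those "absent" at the margin are screened out). An intron is specific to
#' a tissue when it is present in exactly one tissue and the chi-square
#' p-value is at most `p_cut`.
#'
#' @param n_present integer matrix, introns x tissues: samples with more
#'   than `read_cut` reads (the `read_cut` argument documents the intended
#'   counting; the matrix is taken as given).
#' @param n_samples integer vector of per-tissue sample totals.
#' @param present_frac presence fraction threshold (default 0.15).
#' @param p_cut chi-square p-value cutoff (default 0.001).
#' @param read_cut read threshold used to build `n_present` (default 10,
#'   informational).
#' @return data.frame per intron: `present_in` (comma-joined tissues),
#'   `n_present_tissues`, `chi2`, `chi2_p` (`NA` when the O >= E condition
#'   fails or no tissue is absent), `specific_to` (`NA` when not specific).
#' @export
tissueSpecificity <- function(n_present, n_samples, present_frac = 0.15,
                              p_cut = 0.001, read_cut = 10) {
  tissues <- colnames(n_present)
  if (is.null(tissues)) tissues <- paste0("t", seq_along(n_samples))
  if (any(n_samples <= 0)) {
    warning("tissue(s) with 0 samples excluded: ",
            paste(tissues[n_samples <= 0], collapse = ", "))
    keep <- n_samples > 0
    n_present <- n_present[, keep, drop = FALSE]
    n_samples <- n_samples[keep]
    tissues <- tissues[keep]
  }
  present <- sweep(n_present, 2L, present_frac * n_samples, ">=")
  E <- (1 - present_frac) * n_samples
  res <- lapply(seq_len(nrow(n_present)), function(i) {
    pr <- present[i, ]
    absent <- which(!pr)
    chi2 <- chi2_p <- NA_real_
    if (length(absent)) {
      O <- n_samples[absent] - n_present[i, absent]
      Ei <- E[absent]
      if (all(O >= Ei)) {
        chi2 <- sum((O - Ei)^2 / Ei)
        chi2_p <- stats::pchisq(chi2, df = length(absent),
                                lower.tail = FALSE)
      }
    }
    spec <- if (sum(pr) == 1L && !is.na(chi2_p) && chi2_p <= p_cut)
      tissues[pr] else NA_character_
    data.frame(present_in = paste(tissues[pr], collapse = ","),
               n_present_tissues = sum(pr),
               chi2 = chi2, chi2_p = chi2_p, specific_to = spec,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- rownames(n_present)
  out
}
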