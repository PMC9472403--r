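## Differential splicing ratio (DSR): per-bunch Dirichlet-multinomial
## mixture across conditions, likelihood-ratio test, PSI and dPSI.

#' Likelihood-ratio test for differential splicing ratio in one bunch
#'
#' The null model fits one Dirichlet-multinomial over all samples; the
#' alternative fits one per condition (the 0/1 condition indicators
#' factorize the mixture likelihood), each seeded from the null
#' concentrations. `LR = -2 (L0 - L1)` clamped at zero is referred to a
#' chi-square with `k (m_eff - 1)` degrees of freedom, where `m_eff` counts
#' conditions with any observed reads; a condition with all-zero columns
#' gets `NA` splicing ratios and the test still runs when at least two
#' conditions have data.
#'
#' @param Y `k x n` count matrix for the bunch (`k >= 2` introns).
#' @param labels condition label per sample (column).
#' @return list with `lr`, `df`, `p_value`, `psi` (`m x k` matrix of
#'   per-condition splicing ratios, rows summing to 1 where estimable),
#'   `dpsi` (per intron, the maximum absolute pairwise ratio difference
#'   across conditions), `status` (`TEST` or `NO-DATA`), and the fitted
#'   `null`/`alts` [DmFit-class] objects.
#' @examples
#' Y <- cbind(rdirmult(5, 50, c(8, 2)), rdirmult(5, 50, c(2, 8)))
#' lrtDsr(Y, rep(c("a", "b"), each = 5))
#' @export
lrtDsr <- function(Y, labels) {
  Y <- as.matrix(Y)
  k <- nrow(Y)
  if (k < 2L) stop("k >= 2 introns required")
  labels <- factor(labels)
  m <- nlevels(labels)
  if (m < 2L) stop("at least 2 conditions required")
  if (ncol(Y) != length(labels))
    stop("ncol(Y) must equal length(labels)")
  has_data <- vapply(levels(labels),
                     function(lv) sum(Y[, labels == lv]) > 0, TRUE)
  psi <- matrix(NA_real_, nrow = m, ncol = k,
                dimnames = list(levels(labels), rownames(Y)))
  if (sum(has_data) < 2L) {
    return(list(lr = NA_real_, df = NA_integer_, p_value = NA_real_,
                psi = psi, dpsi = rep(NA_real_, k), status = "NO-DATA",
                null = NULL, alts = NULL))
  }
  use <- labels %in% levels(labels)[has_data]
  null <- fitDm(Y[, use, drop = FALSE])
  alts <- lapply(levels(labels)[has_data], function(lv)
    fitDm(Y[, labels == lv, drop = FALSE], init = null))
  names(alts) <- levels(labels)[has_data]
  l1 <- sum(vapply(alts, function(f) f@loglik, 0))
  lr <- max(0, -2 * (null@loglik - l1))
  df <- k * (sum(has_data) - 1L)
  for (lv in names(alts))
    psi[lv, ] <- psiFromAlpha(alts[[lv]]@alpha)
  est <- psi[has_data, , drop = FALSE]
  dpsi <- if (nrow(est) >= 2L) {
    pairs <- utils::combn(nrow(est), 2L)
    apply(abs(est[pairs[1L, ], , drop = FALSE] -
                est[pairs[2L, ], , drop = FALSE]), 2L, max)
  } else rep(NA_real_, k)
  list(lr = lr, df = df,
       p_value = stats::pchisq(lr, df, lower.tail = FALSE),
       psi = psi, dpsi = dpsi, status = "TEST",
       null = null, alts = alts)
}

#' Differential splicing ratio over a JunctionExperiment
#'
#' Groups introns by bunch (assigning bunches first when absent), runs
#' [lrtDsr()] on every bunch with at least two member introns, and adjusts
#' bunch p-values with Benjamini-Hochberg. Single-intron bunches carry no
#' ratio information and are skipped (they remain eligible for [runDSA()]).
#'
#' @param jx a [JunctionExperiment-class] with >= 2 conditions.
#' @return list of two data.frames: `bunches` (one row per tested bunch:
#'   `bunch_id`, `k`, `lr`, `df`, `p_value`, `q_value`, `status`) and
#'   `introns` (one row per member intron: coordinates, `bunch_id`,
#'   `gene_ids`, per-condition `psi_<cond>`, `dpsi`).
#' @export
runDSR <- function(jx) {
  cond <- sampleConditions(jx)
  if (nlevels(cond) < 2L) stop("at least 2 conditions required")
  if (is.null(bunchIds(jx))) jx <- addBunches(jx)
  bid <- bunchIds(jx)
  cts <- counts(jx)
  rd <- rowData(jx)
  idx_by_bunch <- split(seq_len(nrow(cts)), bid)
  idx_by_bunch <- idx_by_bunch[vapply(idx_by_bunch, length, 0L) >= 2L]
  idx_by_bunch <- idx_by_bunch[order(names(idx_by_bunch))]
  if (length(idx_by_bunch) == 0L) {
    empty_b <- data.frame(bunch_id = character(0), k = integer(0),
                          lr = numeric(0), df = integer(0),
                          p_value = numeric(0), status = character(0),
                          q_value = numeric(0), stringsAsFactors = FALSE)
    empty_i <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          bunch_id = character(0), gene_ids = character(0),
                          dpsi = numeric(0), stringsAsFactors = FALSE)
    return(list(bunches = empty_b, introns = empty_i))
  }
  bres <- lapply(idx_by_bunch, function(ii)
    lrtDsr(cts[ii, , drop = FALSE], cond))
  bunches <- data.frame(
    bunch_id = names(idx_by_bunch),
    k = vapply(idx_by_bunch, length, 0L),
    lr = vapply(bres, `[[`, 0, "lr"),
    df = vapply(bres, function(r) as.integer(r$df), 0L),
    p_value = vapply(bres, `[[`, 0, "p_value"),
    status = vapply(bres, `[[`, "", "status"),
    row.names = NULL, stringsAsFactors = FALSE)
  fam <- bunches$status == "TEST"
  bunches$q_value <- NA_real_
  bunches$q_value[fam] <- bhAdjust(bunches$p_value[fam])
  introns <- do.call(rbind, lapply(names(idx_by_bunch), function(b) {
    ii <- idx_by_bunch[[b]]
    r <- bres[[b]]
    psi <- t(r$psi)
    colnames(psi) <- paste0("psi_", rownames(r$psi))
    data.frame(
      chrom = as.character(seqnames(jx))[ii],
      start = start(jx)[ii], end = end(jx)[ii],
      strand = sub("\\*", ".", as.character(strand(jx))[ii]),
      bunch_id = b,
      gene_ids = if (is.null(rd$gene_ids)) "." else rd$gene_ids[ii],
      psi, dpsi = r$dpsi,
      row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(bunches = bunches, introns = introns)
}
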