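## Differential splicing abundance (DSA): per-intron mixture ZINB across m
## conditions, likelihood-ratio test, low-mean noise filter, log fold change.

#' Null (single-condition) ZINB fit for an intron
#'
#' Pools all samples into one ZINB fit; the prior anchor is the pooled
#' sample mean.
#'
#' @param y counts over all samples (length >= 2).
#' @return a [ZinbFit-class].
#' @export
fitDsaNull <- function(y) {
  if (length(y) < 2L) stop("at least 2 samples required")
  fitZinb(y, prior = zinbPrior(mean(y)))
}

#' Per-condition ZINB fits for an intron
#'
#' The mixture likelihood with 0/1 condition indicators factorizes into
#' independent per-condition terms, so the alternative model is one ZINB fit
#' per condition, each anchored at its own condition mean and seeded from the
#' null solution (guaranteeing the LRT statistic is non-negative up to
#' optimizer tolerance).
#'
#' @param y counts over all samples.
#' @param labels condition label per sample (>= 1 sample per condition).
#' @param null optional [ZinbFit-class] used to seed each per-condition fit.
#' @return named list of [ZinbFit-class], one per condition level.
#' @export
fitDsaAlt <- function(y, labels, null = NULL) {
  labels <- factor(labels)
  if (any(table(labels) < 1L)) stop("every condition needs >= 1 sample")
  fits <- lapply(levels(labels), function(lv) {
    yi <- y[labels == lv]
    fitZinb(yi, prior = zinbPrior(mean(yi)), init = null)
  })
  stats::setNames(fits, levels(labels))
}

#' Likelihood-ratio test for differential splicing abundance
#'
#' `LR = -2 (L0 - L1)` with `L1` the sum of per-condition log-likelihoods,
#' clamped at zero, referred to a chi-square with `3 (m - 1)` degrees of
#' freedom (mean, dispersion and zero-inflation free per condition). By
#' default the data log-likelihoods evaluated at the MAP estimates are
#' compared; `penalized = TRUE` compares the penalized objectives instead
#' (strongly conservative, because the alternative carries `m` prior terms
#' against the null's one; see the methods vignette).
#'
#' @param null a [ZinbFit-class] from [fitDsaNull()].
#' @param alts list of per-condition fits from [fitDsaAlt()].
#' @param penalized compare penalized objectives instead of data
#'   log-likelihoods (default `FALSE`).
#' @return list with `lr`, `df`, `p_value`, `loglik_null`, `loglik_alt`.
#' @export
lrtDsa <- function(null, alts, penalized = FALSE) {
  m <- length(alts)
  if (m < 2L) stop("at least 2 conditions required")
  pick <- function(f) if (penalized) f@loglikPenalized else f@loglikData
  l0 <- pick(null)
  l1 <- sum(vapply(alts, pick, 0))
  lr <- max(0, -2 * (l0 - l1))
  df <- 3L * (m - 1L)
  list(lr = lr, df = df,
       p_value = stats::pchisq(lr, df, lower.tail = FALSE),
       loglik_null = l0, loglik_alt = l1)
}

#' Low-mean noise filter
#'
#' An intron passes when its fitted mean reaches `cutoff` in at least one
#' condition (`rule = "max"`, the default: an intron genuinely expressed in
#' one condition remains testable) or in every condition (`rule = "all"`).
#'
#' @param alts list of per-condition [ZinbFit-class] objects.
#' @param cutoff minimum fitted mean (default 1 read).
#' @param rule `"max"` or `"all"`.
#' @return logical flag.
#' @export
meanFilter <- function(alts, cutoff = 1, rule = c("max", "all")) {
  rule <- match.arg(rule)
  mus <- vapply(alts, function(f) f@mu, 0)
  if (rule == "max") max(mus) >= cutoff else all(mus >= cutoff)
}

#' Log2 fold changes between condition means
#'
#' For two conditions, `log2((mu_2 + eps) / (mu_1 + eps))`; for more, all
#' pairwise contrasts, named `"b.vs.a"`. The pseudocount keeps
#' condition-absent introns finite.
#'
#' @param mu named vector of per-condition fitted means (length >= 2).
#' @param eps pseudocount (default 0.01).
#' @return named numeric vector of log2 fold changes.
#' @export
log2FoldChanges <- function(mu, eps = 0.01) {
  m <- length(mu)
  if (m < 2L) stop("at least 2 conditions required")
  if (is.null(names(mu))) names(mu) <- paste0("c", seq_len(m))
  pairs <- utils::combn(m, 2L)
  lfc <- log2((mu[pairs[2L, ]] + eps) / (mu[pairs[1L, ]] + eps))
  stats::setNames(as.numeric(lfc),
                  paste0(names(mu)[pairs[2L, ]], ".vs.",
                         names(mu)[pairs[1L, ]]))
}

#' Differential splicing abundance over a JunctionExperiment
#'
#' Runs the pooled-null versus per-condition ZINB likelihood-ratio test for
#' every intron, applies the low-mean filter, and adjusts p-values with
#' Benjamini-Hochberg within the family of tested introns.
#'
#' @param jx a [JunctionExperiment-class] with >= 2 conditions.
#' @param mean_cutoff low-mean filter threshold (default 1); introns failing
#'   it get status `LOW-MEAN` and are excluded from the BH family (set
#'   `bh_before_filter = TRUE` to adjust over all introns instead).
#' @param mean_rule passed to [meanFilter()].
#' @param penalized passed to [lrtDsa()].
#' @param bh_before_filter include low-mean introns in the BH family.
#' @return data.frame, one row per intron: coordinates, `gene_ids`, `status`
#'   (`TEST`/`LOW-MEAN`/`FAIL`), per-condition fitted means `mu_<cond>`,
#'   `log2fc` (two conditions: the single contrast; more: the contrast of
#'   largest magnitude), `lr`, `df`, `p_value`, `q_value`.
#' @export
runDSA <- function(jx, mean_cutoff = 1, mean_rule = "max",
                   penalized = FALSE, bh_before_filter = FALSE) {
  cond <- sampleConditions(jx)
  if (nlevels(cond) < 2L) stop("at least 2 conditions required")
  cts <- counts(jx)
  rd <- rowData(jx)
  res <- lapply(seq_len(nrow(cts)), function(i) {
    y <- cts[i, ]
    out <- tryCatch({
      null <- fitDsaNull(y)
      alts <- fitDsaAlt(y, cond, null = null)
      tst <- lrtDsa(null, alts, penalized = penalized)
      mus <- vapply(alts, function(f) f@mu, 0)
      lfc <- log2FoldChanges(mus)
      list(status = if (meanFilter(alts, mean_cutoff, mean_rule))
        "TEST" else "LOW-MEAN",
        mu = mus, lr = tst$lr, df = tst$df, p = tst$p_value,
        lfc = lfc[which.max(abs(lfc))])
    }, error = function(e)
      list(status = "FAIL", mu = rep(NA_real_, nlevels(cond)),
           lr = NA_real_, df = NA_integer_, p = NA_real_,
           lfc = NA_real_))
    out
  })
  mus <- do.call(rbind, lapply(res, `[[`, "mu"))
  colnames(mus) <- paste0("mu_", levels(cond))
  df <- data.frame(
    chrom = as.character(seqnames(jx)),
    start = start(jx), end = end(jx),
    strand = sub("\\*", ".", as.character(strand(jx))),
    gene_ids = if (is.null(rd$gene_ids)) "." else rd$gene_ids,
    bunch_id = if (is.null(rd$bunch_id)) "." else rd$bunch_id,
    status = vapply(res, `[[`, "", "status"),
    stringsAsFactors = FALSE)
  df <- cbind(df, mus)
  df$log2fc <- vapply(res, function(r) unname(r$lfc), 0)
  df$lr <- vapply(res, `[[`, 0, "lr")
  df$df <- vapply(res, function(r) as.integer(r$df), 0L)
  df$p_value <- vapply(res, `[[`, 0, "p")
  fam <- if (bh_before_filter) df$status %in% c("TEST", "LOW-MEAN")
  else df$status == "TEST"
  df$q_value <- NA_real_
  df$q_value[fam] <- bhAdjust(df$p_value[fam])
  df
}
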