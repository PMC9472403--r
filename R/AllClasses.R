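#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges rowData
#'   rowData<- colData assay assays
#' @importFrom GenomicRanges GRanges seqnames strand start end granges
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics counts
NULL

#' JunctionExperiment: splice-junction counts across samples
#'
#' The central container of the package: a
#' [SummarizedExperiment::RangedSummarizedExperiment] whose rows are introns
#' (splice junctions, 1-based fully-closed coordinates of the first and last
#' intronic base) and whose single `"counts"` assay holds the number of
#' spliced reads supporting each junction in each sample. `colData` carries a
#' mandatory `condition` factor; `rowData` optionally carries `bunch_id`
#' (assigned by [addBunches()]), `gene_ids` and `novel` annotations.
#'
#' @slot . inherits all slots from `RangedSummarizedExperiment`.
#' @seealso [JunctionExperiment()], [filterIntrons()], [addBunches()],
#'   [runDSA()], [runDSR()]
#' @export
setClass("JunctionExperiment",
         contains = "RangedSummarizedExperiment")

.validJunctionExperiment <- function(object) {
  msg <- NULL
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (!is.numeric(cts))
      msg <- c(msg, "'counts' must be numeric")
    else if (any(!is.finite(cts)) || any(cts < 0) ||
             any(cts != round(cts)))
      msg <- c(msg, "'counts' must be finite, non-negative integers")
  }
  if (!"condition" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'condition' column")
  else {
    cond <- object$condition
    if (anyNA(cond))
      msg <- c(msg, "'condition' must not contain NA")
    if (length(unique(cond)) < 1L)
      msg <- c(msg, "at least one condition is required")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("JunctionExperiment", .validJunctionExperiment)

#' Construct a JunctionExperiment
#'
#' @param counts integer matrix, introns x samples.
#' @param introns `GRanges` of intron coordinates (first to last intronic
#'   base, 1-based closed), one range per row of `counts`.
#' @param condition vector or factor of per-sample condition labels, one per
#'   column of `counts`. Conditions with a single sample trigger a warning
#'   (dispersion is poorly identified from one observation).
#' @param sample_names optional sample identifiers; defaults to
#'   `colnames(counts)`.
#' @return A [JunctionExperiment-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(110, 210), c(159, 300)))
#' cts <- matrix(c(5L, 0L, 7L, 3L), nrow = 2,
#'               dimnames = list(NULL, c("s1", "s2")))
#' jx <- JunctionExperiment(cts, gr, condition = c("ctrl", "case"))
#' @export
JunctionExperiment <- function(counts, introns, condition,
                               sample_names = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (length(introns) != nrow(counts))
    stop("length(introns) must equal nrow(counts)")
  if (length(condition) != ncol(counts))
    stop("length(condition) must equal ncol(counts)")
  if (is.null(sample_names))
    sample_names <- paste0("sample", seq_len(ncol(counts)))
  colnames(counts) <- sample_names
  condition <- factor(condition)
  tab <- table(condition)
  if (any(tab < 2L))
    warning("condition(s) with fewer than 2 samples: ",
            paste(names(tab)[tab < 2L], collapse = ", "))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = introns,
    colData = DataFrame(condition = condition, row.names = sample_names))
  new("JunctionExperiment", se)
}

#' @describeIn JunctionExperiment-class junction read counts (introns x
#'   samples integer matrix).
#' @param object,x a `JunctionExperiment`.
#' @export
setMethod("counts", "JunctionExperiment",
          function(object) assay(object, "counts"))

#' Per-sample condition labels
#'
#' @param x a [JunctionExperiment-class].
#' @return factor of length `ncol(x)`.
#' @export
sampleConditions <- function(x) x$condition

#' Bunch membership of each intron
#'
#' @param x a [JunctionExperiment-class] processed by [addBunches()].
#' @return character vector of bunch identifiers, or `NULL` when bunches have
#'   not been assigned.
#' @export
bunchIds <- function(x) rowData(x)$bunch_id

setMethod("show", "JunctionExperiment", function(object) {
  cat("class: JunctionExperiment\n")
  cat("introns:", nrow(object), " samples:", ncol(object), "\n")
  cond <- table(sampleConditions(object))
  cat("conditions:",
      paste(sprintf("%s (%d)", names(cond), cond), collapse = ", "), "\n")
  if (!is.null(bunchIds(object)))
    cat("bunches:", length(unique(bunchIds(object))), "\n")
  invisible(NULL)
})

#' ZinbFit: MAP fit of the zero-inflated negative-binomial count model
#'
#' Point estimates for one count vector: NB mean `mu`, dispersion `phi`
#' (variance `mu + phi * mu^2`) and structural-zero probability `pi`, with
#' the maximized penalized objective (`loglikPenalized`, data log-likelihood
#' plus log-prior) and the data log-likelihood at the MAP (`loglikData`).
#'
#' @slot mu,phi,pi numeric parameter estimates.
#' @slot loglikPenalized,loglikData numeric objective values at the optimum.
#' @slot converged logical, optimizer convergence flag.
#' @slot nObs integer, number of observations fitted.
#' @export
setClass("ZinbFit",
         representation(mu = "numeric", phi = "numeric", pi = "numeric",
                        loglikPenalized = "numeric", loglikData = "numeric",
                        converged = "logical", nObs = "integer"))

setValidity("ZinbFit", function(object) {
  msg <- NULL
  if (object@mu <= 0) msg <- c(msg, "mu must be > 0")
  if (object@phi <= 0) msg <- c(msg, "phi must be > 0")
  if (object@pi < 0 || object@pi > 1) msg <- c(msg, "pi must lie in [0,1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ZinbFit", function(object) {
  cat(sprintf(
    "ZinbFit: mu=%.4g phi=%.4g pi=%.4g  loglik=%.4f (penalized %.4f)%s\n",
    object@mu, object@phi, object@pi, object@loglikData,
    object@loglikPenalized,
    if (object@converged) "" else "  [not converged]"))
  invisible(NULL)
})

#' DmFit: maximum-likelihood fit of the Dirichlet-multinomial bunch model
#'
#' Concentration estimates `alpha` (one per intron of the bunch) and the
#' maximized log-likelihood for a bunch count matrix.
#'
#' @slot alpha numeric vector of concentrations (all > 0).
#' @slot loglik numeric maximized log-likelihood.
#' @slot converged logical.
#' @slot nObs integer, number of samples fitted.
#' @export
setClass("DmFit",
         representation(alpha = "numeric", loglik = "numeric",
                        converged = "logical", nObs = "integer"))

setValidity("DmFit", function(object) {
  if (length(object@alpha) && any(object@alpha <= 0))
    "alpha must be strictly positive" else TRUE
})

setMethod("show", "DmFit", function(object) {
  cat(sprintf("DmFit (k=%d): alpha=(%s)  loglik=%.4f%s\n",
              length(object@alpha),
              paste(sprintf("%.3g", object@alpha), collapse = ", "),
              object@loglik,
              if (object@converged) "" else "  [not converged]"))
  invisible(NULL)
})
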