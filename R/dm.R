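## Dirichlet-multinomial distribution: log-pmf, maximum-likelihood fit,
## splicing-ratio (PSI) helpers.

#' Dirichlet-multinomial log-probability
#'
#' Log-pmf of counts `y` over `k` categories with concentrations `alpha`,
#' including the multinomial coefficient (constant in `alpha`, so it cancels
#' in likelihood ratios but keeps the pmf normalized). An empty draw
#' (`sum(y) = 0`) has probability 1.
#'
#' @param y non-negative integer vector of length `k >= 2`, or a `k x n`
#'   matrix of per-sample counts (columns are samples).
#' @param alpha strictly positive concentration vector of length `k`.
#' @return scalar log-probability (summed over columns when `y` is a
#'   matrix).
#' @examples
#' dmLogpmf(c(1, 0), c(1, 1))  # log(0.5)
#' @export
dmLogpmf <- function(y, alpha) {
  if (any(alpha <= 0) || any(!is.finite(alpha)))
    stop("alpha must be strictly positive and finite")
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
  if (nrow(Y) != length(alpha)) stop("length(alpha) must match nrow(y)")
  if (nrow(Y) < 2L) stop("k >= 2 categories required")
  if (any(Y < 0) || any(Y != round(Y)))
    stop("y must contain non-negative integers")
  N <- colSums(Y)
  A <- sum(alpha)
  sum(lgamma(N + 1)) - sum(lgamma(Y + 1)) +
    length(N) * lgamma(A) - sum(lgamma(N + A)) +
    sum(lgamma(Y + alpha) - lgamma(alpha))
}

.dm_init <- function(Y, floor = 1e-3) {
  p <- rowSums(Y) + 0.5
  p <- p / sum(p)
  pmax(10 * p, floor)
}

#' Maximum-likelihood Dirichlet-multinomial fit for a bunch
#'
#' Maximizes the summed log-pmf over `log(alpha)` with L-BFGS-B, the
#' concentrations floored at `1e-3` to keep the objective finite. The
#' default start moment-matches the pooled count proportions at total
#' concentration 10. Deterministic given the counts and start.
#'
#' @param Y `k x n` matrix of intron counts (columns are samples, `n >= 1`).
#' @param init optional start: positive `alpha` vector or a [DmFit-class].
#' @return a [DmFit-class]; an all-zero matrix yields `converged = FALSE`
#'   with the start returned (callers report such bunches as `NO-DATA`).
#' @export
fitDm <- function(Y, init = NULL) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 1L) stop("at least one sample required")
  a0 <- if (is.null(init)) .dm_init(Y)
  else if (is(init, "DmFit")) init@alpha
  else init
  if (all(Y == 0))
    return(new("DmFit", alpha = a0, loglik = 0, converged = FALSE,
               nObs = ncol(Y)))
  negobj <- function(lp) {
    v <- -dmLogpmf(Y, exp(lp))
    if (!is.finite(v)) 1e12 else v
  }
  par0 <- log(pmax(a0, 1e-3))
  opt <- tryCatch(
    stats::optim(par0, negobj, method = "L-BFGS-B",
                 lower = log(1e-3), upper = 15,
                 control = list(maxit = 500L, factr = 1e7)),
    error = function(e) list(par = par0, value = negobj(par0),
                             convergence = 99L))
  if (opt$value > negobj(par0) + 1e-9)
    opt <- list(par = par0, value = negobj(par0), convergence = 99L)
  new("DmFit", alpha = exp(opt$par), loglik = -opt$value,
      converged = opt$convergence == 0L, nObs = ncol(Y))
}

#' Splicing ratios (PSI) from concentrations
#'
#' `Psi_l = alpha_l / sum(alpha)`: each intron's share of its bunch, on the
#' scale of percent-spliced-in. Invariant to rescaling `alpha`.
#'
#' @param alpha positive concentration vector.
#' @return numeric vector summing to 1.
#' @export
psiFromAlpha <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be strictly positive")
  alpha / sum(alpha)
}

#' Per-sample empirical splicing ratios
#'
#' Column-wise count proportions `y_lj / sum_l y_lj`; samples expressing no
#' member intron (zero column sum) yield `NA`.
#'
#' @param Y `k x n` count matrix.
#' @return `k x n` matrix of proportions.
#' @export
perSamplePsi <- function(Y) {
  Y <- as.matrix(Y)
  tot <- colSums(Y)
  out <- sweep(Y, 2L, tot, "/")
  out[, tot == 0] <- NA_real_
  out
}

#' Draw Dirichlet-multinomial samples
#'
#' @param n number of samples (columns).
#' @param size total count per sample (scalar or length-`n`).
#' @param alpha concentration vector (length `k`).
#' @return `k x n` integer matrix.
#' @export
rdirmult <- function(n, size, alpha) {
  k <- length(alpha)
  size <- rep_len(size, n)
  out <- vapply(seq_len(n), function(j) {
    g <- stats::rgamma(k, shape = alpha)
    p <- g / sum(g)
    stats::rmultinom(1L, size[j], p)[, 1L]
  }, integer(k))
  matrix(as.integer(out), nrow = k)
}
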