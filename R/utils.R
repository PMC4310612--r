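#' @importFrom stats median pt sd setNames complete.cases rnorm rbinom runif
#'   dbinom qnorm plogis qlogis fisher.test wilcox.test t.test p.adjust
#'   smooth.spline predict quantile rhyper
NULL

#' Centre and scale a vector to unit sample standard deviation
#'
#' Effect sizes are expressed in phenotype standard deviations; this is the
#' scaling they rely on (subtract the mean, divide by the sample SD).
#' Idempotent up to floating point.
#'
#' @param x numeric vector (NAs tolerated and preserved).
#' @return scaled vector, mean 0 and sample SD 1.
#' @export
scaleValues <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("cannot scale a constant vector")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Lower weighted median with midpoint interpolation
#'
#' Sorts values, accumulates normalised weights and returns the first value
#' whose cumulative weight reaches one half; when the cumulative weight hits
#' exactly one half the midpoint of the straddling values is returned. This
#' is the convention used by the allelic-ratio distance.
#'
#' @param x numeric values.
#' @param w positive weights, same length.
#' @return the weighted median.
#' @examples
#' weightedMedian(c(0.1, 0.5), c(10, 10))  # 0.3
#' @export
weightedMedian <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), any(w > 0))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5 - 1e-12)[1L]
  if (abs(cw[i] - 0.5) <= 1e-12 && i < length(x))
    (x[i] + x[i + 1L]) / 2
  else
    x[i]
}

## Spearman rho between one x and the columns of a matrix of pre-ranked,
## standardised phenotypes. Internal building block of the scan engines.
## Ranks use average ties; rho is the Pearson correlation of ranks.
rankStandardize <- function(m) {
  r <- apply(m, 2L, rank)
  r <- scale(r)                        # centre, unit sample SD
  r / sqrt(nrow(m) - 1)                # crossprod now yields rho directly
}

## t-approximation p-value for Spearman rho at sample size n
spearmanPApprox <- function(rho, n) {
  rho <- pmin(1, pmax(-1, rho))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Spearman rank correlation with permutation-exact small-sample p
#'
#' Rho is the Pearson correlation of average-tie ranks. For `n >=
#' exactBelow` the p-value uses the usual t approximation; for smaller n the
#' exact permutation distribution of rho is enumerated over all n!
#' orderings. Zero variance in either vector is an error (callers skip such
#' pairs and count them).
#'
#' @param x,y paired numeric vectors; pairs with missing values are dropped.
#' @param exactBelow sample size below which the exact enumeration is used.
#' @return list with `rho`, `p`, `n`.
#' @export
spearmanTest <- function(x, y, exactBelow = 10L) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired non-missing observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: Spearman correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < exactBelow) {
    perms <- permuteAll(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    null <- apply(perms, 1L, function(ix) sum(rxc * ryc[ix])) / denom
    p <- mean(abs(null) >= abs(rho) - 1e-12)
  } else {
    p <- spearmanPApprox(rho, n)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

## all permutations of seq_len(n) as rows (n <= 9 in practice)
permuteAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permuteAll(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  k <- 1L
  for (i in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep.int(i, rows),
                   matrix(setdiff(seq_len(n), i)[sub], rows))
    out[k:(k + rows - 1L), ] <- block
    k <- k + rows
  }
  out
}

#' Storey estimate of the null proportion pi0
#'
#' pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)) is evaluated on the grid
#' lambda = 0.05, 0.10, ..., 0.95, smoothed with a cubic spline (df = 3) and
#' read off at the largest lambda, then clipped to (0, 1].
#'
#' @param p p-values in (0, 1].
#' @return pi0 estimate.
#' @export
storeyPi0 <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  lambda <- seq(0.05, 0.95, by = 0.05)
  m <- length(p)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' Storey q-values and the significant set at an FDR level
#'
#' q-values are `pi0 * m * p / rank(p)` made monotone by a step-up pass from
#' the largest p-value. With pi0 forced to 1 this reduces exactly to
#' Benjamini-Hochberg adjusted p-values. Fewer than 100 tests fall back to
#' pi0 = 1 (with a message), as the smoother is unreliable there.
#'
#' @param p p-values in (0, 1].
#' @param fdr FDR level for the significance flag.
#' @param pi0 optional override of the null proportion.
#' @return list with `qvalues`, `pi0`, `significant` (logical).
#' @export
storeyQvalues <- function(p, fdr = 0.10, pi0 = NULL) {
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100L) {
      message("fewer than 100 tests: falling back to pi0 = 1 (BH)")
      pi0 <- 1
    } else pi0 <- storeyPi0(p)
  }
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(pi0 * m * p[o] / (m - seq_len(m) + 1L)))
  qv <- numeric(m)
  qv[o] <- q
  list(qvalues = qv, pi0 = pi0, significant = qv <= fdr)
}

#' Proportion of true positives in a p-value set (pi1)
#'
#' `1 - pi0` with pi0 from [storeyPi0()], clipped to \[0, 1\]. Used as the
#' cross-tissue sharing estimate: p-values of one tissue's significant pairs
#' evaluated in a second tissue.
#'
#' @param p p-values.
#' @return pi1 estimate in \[0, 1\].
#' @export
pi1 <- function(p) {
  if (length(unique(p)) == 1L)
    warning("degenerate p-value set (all identical); pi1 unreliable")
  min(max(1 - storeyPi0(p), 0), 1)
}

#' Expected-over-observed FDR estimate for threshold-based ASE calls
#'
#' With `nTests` sites tested at nominal level `alpha`, `alpha * nTests`
#' significant sites are expected under the null; the FDR at that threshold
#' is estimated as expected over observed.
#'
#' @param nTests number of tests performed.
#' @param nObserved number of tests significant at `alpha`.
#' @param alpha nominal p-value threshold.
#' @return estimated FDR (NA with a warning when `nObserved` is 0).
#' @examples
#' aseFdrEstimate(1748, 41, 0.005)  # ~0.21
#' @export
aseFdrEstimate <- function(nTests, nObserved, alpha = 0.005) {
  if (nObserved == 0) {
    warning("no observed significant tests: FDR undefined")
    return(NA_real_)
  }
  (alpha * nTests) / nObserved
}
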