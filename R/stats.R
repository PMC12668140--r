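# Exact contingency, binomial and classification statistics: Pearson
# chi-square, Fisher exact with Bonferroni, binomial pmf/tail/CI,
# fold-change of medians, 2-component GMM positivity, soma-candidate
# filtering, ROI colocalization.

#' Pearson chi-square test of independence
#'
#' Pearson statistic \eqn{\sum (O - E)^2 / E} without continuity
#' correction, df = (r-1)(c-1), p from the chi-square distribution.
#' Errors if any expected count is zero.
#'
#' @param table r x c matrix of non-negative integer counts (>= 2 rows
#'   and columns).
#' @return list with \code{statistic}, \code{df}, \code{p},
#'   \code{expected}.
#' @examples
#' chiSquareTest(matrix(c(23, 14, 3, 23), 2, byrow = TRUE))$statistic
#' @export
chiSquareTest <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("contingency table needs >= 2 rows and columns")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) stop("zero expected count; test undefined")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability convention: the sum
#' of hypergeometric probabilities, over tables with the observed
#' margins, that do not exceed the probability of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisherExactTest <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    stop("fisherExactTest expects a 2x2 table")
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Bonferroni correction
#'
#' @param p p-value(s).
#' @param m number of comparisons (default the number of p-values).
#' @return min(1, m * p), elementwise.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  pmin(1, m * p)
}

#' Exact binomial probability mass
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param p success probability.
#' @return P(X = k) for X ~ Binomial(n, p).
#' @examples
#' binomialPMF(11, 16, 0.35)
#' @export
binomialPMF <- function(k, n, p) {
  stopifnot(all(k >= 0), all(k <= n), all(p >= 0), all(p <= 1))
  stats::dbinom(k, n, p)
}

#' Exact binomial upper tail
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param p success probability.
#' @return P(X >= k).
#' @export
binomialTail <- function(k, n, p) {
  stopifnot(all(k >= 0), all(k <= n), all(p >= 0), all(p <= 1))
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Endpoints from the beta-quantile identities: lower =
#' qbeta(alpha/2; k, n-k+1) (0 when k = 0), upper =
#' qbeta(1-alpha/2; k+1, n-k) (1 when k = n).
#'
#' @param k successes (vectorized).
#' @param n trials.
#' @param conf confidence level.
#' @return list with \code{lower} and \code{upper}.
#' @export
binomialCI <- function(k, n, conf = 0.95) {
  stopifnot(all(k >= 0), all(k <= n))
  a <- 1 - conf
  lower <- ifelse(k == 0, 0, stats::qbeta(a / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, stats::qbeta(1 - a / 2, k + 1, n - k))
  list(lower = lower, upper = upper)
}

#' Pairwise fold change of per-state median rates
#'
#' Median transient rate over cells per state, and the matrix of
#' pairwise median ratios (row state / column state). Ratios with a
#' zero denominator are NA and flagged.
#'
#' @param rates data.frame or matrix, cells in rows, states in columns,
#'   entries transient rates; or a named list of per-cell rate vectors.
#' @return list with \code{medians}, \code{foldChange} (matrix),
#'   \code{undefined} (logical matrix).
#' @export
foldChangeOfMedians <- function(rates) {
  if (is.list(rates) && !is.data.frame(rates))
    med <- vapply(rates, stats::median, 0, na.rm = TRUE)
  else med <- apply(as.matrix(rates), 2, stats::median, na.rm = TRUE)
  fc <- outer(med, med, "/")
  undefined <- outer(rep(TRUE, length(med)), med == 0, "&")
  dimnames(undefined) <- dimnames(fc)
  fc[undefined] <- NA_real_
  list(medians = med, foldChange = fc, undefined = undefined)
}

#' Two-component Gaussian mixture positivity classification
#'
#' Fits a 2-component univariate Gaussian mixture by EM to median stain
#' intensities (deterministic initialization at the 25th/75th
#' percentiles) and classifies an item as positive when its posterior
#' probability of belonging to the higher-mean component exceeds the
#' threshold (default 0.9). Degenerate (near-constant) input is flagged
#' and everything is classified negative.
#'
#' @param x median stain intensity per candidate (>= 4 values).
#' @param posteriorThreshold posterior required for positivity.
#' @param tol EM convergence tolerance on log-likelihood.
#' @param maxIter maximum EM iterations.
#' @return list with \code{means}, \code{sds}, \code{weights} (low then
#'   high component), \code{posteriorHigh}, \code{positive},
#'   \code{degenerate}, \code{iterations}, \code{logLik}.
#' @export
gmmPositivity <- function(x, posteriorThreshold = 0.9, tol = 1e-8,
                          maxIter = 500) {
  stopifnot(length(x) >= 4)
  n <- length(x)
  rng <- diff(range(x))
  if (rng < 1e-12 * max(1, abs(mean(x))) || stats::sd(x) == 0) {
    return(list(means = rep(mean(x), 2), sds = c(0, 0),
                weights = c(1, 0), posteriorHigh = rep(0, n),
                positive = rep(FALSE, n), degenerate = TRUE,
                iterations = 0L, logLik = NA_real_))
  }
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  sg <- rep(stats::sd(x) / 2, 2)
  w <- c(0.5, 0.5)
  ll0 <- -Inf
  sdFloor <- 1e-6 * rng
  it <- 0L
  repeat {
    it <- it + 1L
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    if (any(tot == 0)) tot[tot == 0] <- .Machine$double.xmin
    g2 <- d2 / tot
    g1 <- 1 - g2
    ll <- sum(log(tot))
    mu <- c(sum(g1 * x) / sum(g1), sum(g2 * x) / sum(g2))
    sg <- sqrt(c(sum(g1 * (x - mu[1])^2) / sum(g1),
                 sum(g2 * (x - mu[2])^2) / sum(g2)))
    sg <- pmax(sg, sdFloor)
    w <- c(mean(g1), mean(g2))
    if (abs(ll - ll0) < tol * (1 + abs(ll)) || it >= maxIter) break
    ll0 <- ll
  }
  # order components so that index 2 is the higher-mean ("positive") one
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sg <- rev(sg); w <- rev(w); g2 <- 1 - g2
  }
  degenerate <- w[2] < 1e-9 || abs(mu[2] - mu[1]) < sdFloor
  posterior <- if (degenerate) rep(0, n) else g2
  list(means = mu, sds = sg, weights = w, posteriorHigh = posterior,
       positive = !degenerate & posterior > posteriorThreshold,
       degenerate = degenerate, iterations = it, logLik = ll)
}

#' Filter soma candidates by morphological thresholds
#'
#' 2-D mode keeps candidates with pixel area in [30, 1500], circularity
#' in [0.3, 1.7] and equivalent diameter in [5, 40] pixels (inclusive
#' bounds); 3-D mode keeps candidates with total volume (soma plus
#' proximal processes) strictly below 2000 cubic micrometers.
#'
#' @param candidates data.frame of region candidates. 2-D mode requires
#'   columns \code{area}, \code{circularity}, \code{equivDiameter};
#'   3-D mode requires \code{volume}.
#' @param mode "2D" or "3D".
#' @param areaRange,circularityRange,diameterRange inclusive 2-D bounds.
#' @param maxVolume exclusive 3-D volume bound.
#' @return the subset of \code{candidates} passing all thresholds, with
#'   a \code{kept} attribute (logical over input rows).
#' @export
filterSomata <- function(candidates, mode = c("2D", "3D"),
                         areaRange = c(30, 1500),
                         circularityRange = c(0.3, 1.7),
                         diameterRange = c(5, 40), maxVolume = 2000) {
  mode <- match.arg(mode)
  need <- if (mode == "2D") c("area", "circularity", "equivDiameter")
          else "volume"
  miss <- setdiff(need, names(candidates))
  if (length(miss))
    stop("candidates lack required field(s): ", paste(miss, collapse = ", "))
  keep <- if (mode == "2D") {
    candidates$area >= areaRange[1] & candidates$area <= areaRange[2] &
      candidates$circularity >= circularityRange[1] &
      candidates$circularity <= circularityRange[2] &
      candidates$equivDiameter >= diameterRange[1] &
      candidates$equivDiameter <= diameterRange[2]
  } else {
    candidates$volume < maxVolume
  }
  out <- candidates[keep, , drop = FALSE]
  attr(out, "kept") <- keep
  out
}

#' ROI colocalization by pixel overlap
#'
#' An ROI in set A is colocalized when at least
#' \code{minOverlapFraction} of its pixels are shared with some ROI in
#' set B (e.g. c-Fos ROIs against virally labeled somata in the same
#' image frame).
#'
#' @param roisA,roisB lists of integer pixel-index vectors in a common
#'   coordinate frame.
#' @param minOverlapFraction required |A intersect B| / |A|.
#' @return list with \code{colocalized} (logical per ROI in A),
#'   \code{bestOverlap} (fractions), \code{nColocalized}.
#' @export
colocalize <- function(roisA, roisB, minOverlapFraction = 0.25) {
  stopifnot(is.list(roisA), is.list(roisB))
  best <- vapply(roisA, function(a) {
    if (!length(a)) return(0)
    m <- 0
    for (b in roisB) {
      ov <- length(intersect(a, b)) / length(a)
      if (ov > m) m <- ov
    }
    m
  }, 0)
  flags <- best >= minOverlapFraction
  list(colocalized = flags, bestOverlap = best,
       nColocalized = sum(flags))
}
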