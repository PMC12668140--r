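# Fluorescence-trace conditioning, transient detection, state-conditioned
# rates, the state-preference index S, survivor curves and simplex
# summaries.

#' Detrend and normalize a raw fluorescence trace to dF/F
#'
#' Subtracts a least-squares 3rd-order polynomial fit (removing slow
#' drift, e.g. photobleaching) and divides by the mean of the raw
#' trace, so that a value of 1 means 100% dF/F relative to the cell's
#' mean fluorescence.
#'
#' @param raw raw fluorescence samples (arbitrary units, positive mean).
#' @param order detrending polynomial order.
#' @return numeric dF/F trace of the same length.
#' @export
detrendNormalize <- function(raw, order = 3) {
  n <- length(raw)
  if (n <= order + 1) stop("trace too short to detrend")
  m <- mean(raw)
  if (abs(m) < 1e-12 * max(1, stats::sd(raw)))
    stop("raw trace mean is zero; cannot normalize")
  tt <- seq_len(n) / n
  X <- cbind(1, stats::poly(tt, order, raw = TRUE))
  fit <- stats::lm.fit(X, raw)
  (raw - fit$fitted.values) / m
}

# Topographic prominence of local maxima: extend left/right until a
# strictly higher sample or the signal end; prominence = peak minus the
# higher of the two interval minima.
peakProminences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    i <- p
    leftMin <- h
    while (i > 1) {
      i <- i - 1
      if (x[i] > h) break
      if (x[i] < leftMin) leftMin <- x[i]
    }
    i <- p
    rightMin <- h
    n <- length(x)
    while (i < n) {
      i <- i + 1
      if (x[i] > h) break
      if (x[i] < rightMin) rightMin <- x[i]
    }
    h - max(leftMin, rightMin)
  }, 0)
}

#' Detect calcium transients in a dF/F trace
#'
#' Local maxima are accepted as transients when they exceed a minimum
#' height (default 100% dF/F), have at least a minimum topographic
#' prominence (default 80% dF/F), and are separated by at least a
#' minimum interval (default 1 s); when two candidates violate the
#' separation rule the higher peak is kept.
#'
#' @param dff dF/F trace.
#' @param fs sampling rate in Hz.
#' @param minHeight minimum peak height in dF/F units.
#' @param minProminence minimum prominence in dF/F units.
#' @param minSeparationS minimum separation between kept peaks in s.
#' @return data.frame of class \code{TransientTrain} with columns
#'   \code{time} (s), \code{index}, \code{height}, \code{prominence},
#'   sorted by time.
#' @export
detectTransients <- function(dff, fs, minHeight = 1.0, minProminence = 0.8,
                             minSeparationS = 1.0) {
  stopifnot(fs > 0)
  n <- length(dff)
  if (n < 3)
    return(structure(data.frame(time = numeric(0), index = integer(0),
                                height = numeric(0),
                                prominence = numeric(0)),
                     class = c("TransientTrain", "data.frame")))
  d <- diff(dff)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L  # local maxima
  cand <- cand[dff[cand] >= minHeight]
  if (length(cand)) {
    prom <- peakProminences(dff, cand)
    keep <- prom >= minProminence
    cand <- cand[keep]
    prom <- prom[keep]
  } else prom <- numeric(0)
  # enforce separation: keep higher peaks first
  if (length(cand) > 1) {
    ord <- order(dff[cand], decreasing = TRUE)
    kept <- logical(length(cand))
    minSep <- minSeparationS * fs
    for (i in ord) {
      if (!any(kept & abs(cand - cand[i]) < minSep)) kept[i] <- TRUE
    }
    prom <- prom[kept]
    cand <- cand[kept]
  }
  o <- order(cand)
  structure(data.frame(time = (cand[o] - 1) / fs, index = cand[o],
                       height = dff[cand][o], prominence = prom[o]),
            class = c("TransientTrain", "data.frame"))
}

#' Two-photon transient detection by threshold crossing
#'
#' Two-photon variant: baseline F0 is the mean of the longest quiescent
#' stretch (at least \code{quietS} seconds below the trace median); the
#' F0-normalized trace is thresholded at its mean + 3 SD, and each
#' contiguous supra-threshold period is one event.
#'
#' @param trace background-subtracted fluorescence trace.
#' @param fs sampling rate in Hz.
#' @param nSD threshold in standard deviations above the mean.
#' @param quietS minimum quiescent-stretch duration in seconds.
#' @return list with \code{mask} (logical per sample), \code{events}
#'   (data.frame start/end in s), \code{f0}, \code{threshold}.
#' @export
detectTransients2P <- function(trace, fs, nSD = 3, quietS = 2) {
  stopifnot(fs > 0, length(trace) >= quietS * fs)
  below <- trace < stats::median(trace)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= quietS * fs)
  if (length(ok)) {
    pick <- ok[which.max(r$lengths[ok])]
    f0 <- mean(trace[starts[pick]:ends[pick]])
  } else if (any(below)) {
    f0 <- mean(trace[below])  # fallback: all below-median samples
  } else f0 <- mean(trace)    # constant trace
  z <- if (abs(f0) > 1e-12) (trace - f0) / abs(f0) else trace - f0
  thr <- mean(z) + nSD * stats::sd(z)
  mask <- z > thr
  rr <- rle(mask)
  ee <- cumsum(rr$lengths)
  ss <- ee - rr$lengths + 1L
  on <- which(rr$values)
  events <- data.frame(start = (ss[on] - 1) / fs, end = (ee[on] - 1) / fs)
  list(mask = mask, events = events, f0 = f0, threshold = thr)
}

#' Per-state transient rates
#'
#' Counts detected transients per vigilance state and divides by the
#' per-state exposure (minutes spent in the state within the labeled
#' record). States with zero exposure have undefined (NA) rates.
#'
#' @param events a \code{TransientTrain} (or numeric event times in s).
#' @param h a [Hypnogram-class] labeling the recording.
#' @return data.frame with \code{state}, \code{events},
#'   \code{exposureMin}, \code{rate} (transients/min).
#' @export
stateRates <- function(events, h) {
  stopifnot(is(h, "Hypnogram"))
  times <- if (is.data.frame(events)) events$time else as.numeric(events)
  lab <- stateLabels(h)
  w <- windowSeconds(h)
  durS <- length(lab) * w
  if (length(times) && any(times < 0 | times > durS))
    stop("event times fall outside the labeled record")
  winOf <- pmin(length(lab), floor(times / w) + 1L)
  counts <- table(factor(lab[winOf], levels = VIGILANCE_STATES))
  exposure <- table(factor(lab, levels = VIGILANCE_STATES)) * w / 60
  rate <- ifelse(exposure > 0, as.numeric(counts) / as.numeric(exposure),
                 NA_real_)
  data.frame(state = VIGILANCE_STATES, events = as.integer(counts),
             exposureMin = as.numeric(exposure), rate = rate)
}

#' State-preference index S
#'
#' For each recorded state i, \eqn{S_i = F_i / \sum_j F_j} with F the
#' per-state transient rate (transients/min): 0 means no transients in
#' that state, 1 means all transients exclusively there. The preferred
#' state is the one with the most transients (count, not rate), ties
#' broken toward greater exposure then fixed WAKE < NREM < REM order.
#' Cells with no transients in any state are flagged excluded.
#'
#' @param rates data.frame from [stateRates()], or a named numeric
#'   vector of per-state rates (counts and exposure then default to the
#'   rates themselves).
#' @return list with \code{S} (named, sums to 1 for included cells),
#'   \code{preferred}, \code{included}.
#' @export
statePreference <- function(rates) {
  if (is.data.frame(rates)) {
    st <- rates$state
    F <- rates$rate
    counts <- rates$events
    expo <- rates$exposureMin
  } else {
    st <- names(rates)
    F <- as.numeric(rates)
    counts <- F
    expo <- rep(1, length(F))
  }
  if (length(st) < 2) stop("need at least 2 recorded states")
  rec <- !is.na(F)
  st <- st[rec]; F <- F[rec]; counts <- counts[rec]; expo <- expo[rec]
  tot <- sum(F)
  if (tot == 0) {
    S <- stats::setNames(rep(NA_real_, length(st)), st)
    return(list(S = S, preferred = NA_character_, included = FALSE))
  }
  S <- stats::setNames(F / tot, st)
  ordKey <- match(st, VIGILANCE_STATES)
  ordKey[is.na(ordKey)] <- seq_along(st)[is.na(ordKey)]
  best <- order(-counts, -expo, ordKey)[1]
  list(S = S, preferred = st[best], included = TRUE)
}

#' Survivor function of per-cell state-preference values
#'
#' P(s) = fraction of included cells with S >= s. P(0.5) is the
#' fraction of cells firing at a higher rate in the state of interest
#' than in all others combined.
#'
#' @param sValues per-cell S values for one state (NA/excluded dropped).
#' @return list with \code{curve} (data.frame s, P), \code{at}
#'   (function evaluating P at arbitrary s), and
#'   \code{fractionPreferring} = P(0.5).
#' @export
survivorCurve <- function(sValues) {
  s <- sValues[!is.na(sValues)]
  if (!length(s)) stop("no included cells")
  grid <- sort(unique(c(0, s, 1)))
  P <- vapply(grid, function(q) mean(s >= q), 0)
  at <- function(q) vapply(q, function(qi) mean(s >= qi), 0)
  list(curve = data.frame(s = grid, P = P), at = at,
       fractionPreferring = at(0.5))
}

#' Barycentric simplex embedding of 3-state preferences
#'
#' Maps each cell's (WAKE, NREM, REM) preference vector (summing to 1)
#' to 2-D coordinates in an equilateral triangle with vertices
#' WAKE = (0, 0), NREM = (1, 0), REM = (1/2, sqrt(3)/2), and tabulates
#' the proportion of cells preferring each state (argmax).
#'
#' @param S matrix or data.frame (cells x 3, columns WAKE/NREM/REM),
#'   rows summing to 1.
#' @return list with \code{xy} (cells x 2), \code{preferred},
#'   \code{proportions} (named, summing to 1).
#' @export
simplexCoordinates <- function(S) {
  S <- as.matrix(S)
  stopifnot(ncol(S) == 3)
  if (is.null(colnames(S))) colnames(S) <- VIGILANCE_STATES
  S <- S[, VIGILANCE_STATES, drop = FALSE]
  if (any(abs(rowSums(S) - 1) > 1e-6))
    stop("each row of S must sum to 1")
  V <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), nrow = 3, byrow = TRUE)
  xy <- S %*% V
  colnames(xy) <- c("x", "y")
  pref <- VIGILANCE_STATES[max.col(S, ties.method = "first")]
  props <- table(factor(pref, levels = VIGILANCE_STATES)) / nrow(S)
  list(xy = xy, preferred = pref,
       proportions = stats::setNames(as.numeric(props), VIGILANCE_STATES))
}
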