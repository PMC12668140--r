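# State-dynamics and physiology metrics: time-in-state, bout tables,
# Markov transition matrices, jackknife CIs, righting-reflex
# probabilities, temperature deltas.

#' Per-epoch fraction of time in each state
#'
#' Splits the hypnogram's window grid into epochs (default 1 h) and
#' returns the fraction of windows in each state per epoch. Fractions
#' sum to 1 within every returned epoch; epochs containing no windows
#' are excluded.
#'
#' @param h a [Hypnogram-class].
#' @param epochS epoch length in seconds.
#' @return data.frame with columns \code{epochStart} (s), \code{WAKE},
#'   \code{NREM}, \code{REM}, \code{nWindows}.
#' @export
timeInState <- function(h, epochS = 3600) {
  stopifnot(is(h, "Hypnogram"), epochS > 0)
  lab <- stateLabels(h)
  starts <- (seq_along(lab) - 1) * windowSeconds(h)
  ep <- floor(starts / epochS)
  res <- lapply(sort(unique(ep)), function(e) {
    sel <- lab[ep == e]
    tab <- table(factor(sel, levels = VIGILANCE_STATES)) / length(sel)
    data.frame(epochStart = e * epochS, WAKE = tab[["WAKE"]],
               NREM = tab[["NREM"]], REM = tab[["REM"]],
               nWindows = length(sel))
  })
  do.call(rbind, res)
}

#' Run-length encode a hypnogram into bouts
#'
#' @param h a [Hypnogram-class] (persistence-filtered recommended, so
#'   that bouts satisfy the minimum-duration rule).
#' @return data.frame of class \code{BoutTable} with columns
#'   \code{state}, \code{start} (s), \code{duration} (s). Bouts are
#'   contiguous, non-overlapping and alternate in state.
#' @export
boutTable <- function(h) {
  stopifnot(is(h, "Hypnogram"))
  r <- rle(stateLabels(h))
  w <- windowSeconds(h)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)]) * w
  structure(data.frame(state = r$values, start = starts,
                       duration = r$lengths * w),
            class = c("BoutTable", "data.frame"))
}

#' Summarize bout durations per state
#'
#' @param bouts a \code{BoutTable} from [boutTable()].
#' @return data.frame with per-state \code{n}, \code{meanDuration},
#'   \code{medianDuration} (s).
#' @export
boutSummary <- function(bouts) {
  stopifnot(inherits(bouts, "BoutTable") || is.data.frame(bouts))
  res <- lapply(split(bouts$duration, bouts$state), function(d)
    data.frame(n = length(d), meanDuration = mean(d),
               medianDuration = stats::median(d)))
  out <- do.call(rbind, res)
  out$state <- rownames(out)
  rownames(out) <- NULL
  out[, c("state", "n", "meanDuration", "medianDuration")]
}

#' Normalize a statistic to a baseline value
#'
#' Expresses a statistic as percent of a within-cohort baseline
#' (e.g. NREM bout duration relative to each animal's pre-injection
#' hour).
#'
#' @param stat numeric statistic value(s).
#' @param baselineStat baseline value (> 0).
#' @return 100 * stat / baselineStat.
#' @export
normalizeToBaseline <- function(stat, baselineStat) {
  if (any(baselineStat == 0)) stop("baseline statistic must be non-zero")
  100 * stat / baselineStat
}

#' Bout-level Markov transition matrix
#'
#' Counts ordered pairs of consecutive bout states and row-normalizes by
#' outgoing counts. Self-transitions are structurally absent at bout
#' level (a bout ends only when the state changes), so the diagonal is
#' zero. Rows with no outgoing transitions are flagged undefined (NA
#' probabilities).
#'
#' @param x a \code{BoutTable}, a [Hypnogram-class] (run-length encoded
#'   first), or a character vector of consecutive bout states.
#' @return object of class \code{TransitionMatrix}: list with
#'   \code{counts} (3x3 integer), \code{probabilities} (3x3, rows
#'   summing to 1 where defined), \code{undefinedRows}.
#' @export
transitionMatrix <- function(x) {
  if (is(x, "Hypnogram")) states <- rle(stateLabels(x))$values
  else if (inherits(x, "BoutTable") || is.data.frame(x)) states <- x$state
  else states <- as.character(x)
  if (length(states) < 2) stop("need at least one transition")
  from <- factor(states[-length(states)], levels = VIGILANCE_STATES)
  to <- factor(states[-1], levels = VIGILANCE_STATES)
  counts <- table(from, to)
  rowN <- rowSums(counts)
  probs <- counts / ifelse(rowN > 0, rowN, NA)
  probs <- matrix(as.numeric(probs), 3, 3,
                  dimnames = list(from = VIGILANCE_STATES,
                                  to = VIGILANCE_STATES))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = dimnames(probs))
  structure(list(counts = counts, probabilities = probs,
                 undefinedRows = VIGILANCE_STATES[rowN == 0]),
            class = "TransitionMatrix")
}

#' Elementwise transition-probability ratio
#'
#' Ratio of post-intervention to baseline transition probabilities
#' (e.g. post-CNO normalized by the zeitgeber-time-matched period 24 h
#' prior). Cells with an undefined or zero baseline are NA and flagged.
#'
#' @param post,baseline \code{TransitionMatrix} objects.
#' @return list with \code{ratio} (3x3), \code{undefined} (logical 3x3).
#' @export
transitionRatio <- function(post, baseline) {
  stopifnot(inherits(post, "TransitionMatrix"),
            inherits(baseline, "TransitionMatrix"))
  b <- baseline$probabilities
  p <- post$probabilities
  undefined <- is.na(b) | is.na(p) | b == 0
  ratio <- ifelse(undefined, NA_real_, p / b)
  list(ratio = ratio, undefined = undefined)
}

#' Jackknife confidence interval across subjects
#'
#' Leave-one-subject-out pseudovalue jackknife:
#' \eqn{\tilde\theta_i = n\hat\theta - (n-1)\hat\theta_{(-i)}}, estimate
#' = mean pseudovalue, CI = estimate +/- t(0.975, n-1) * jackknife SE.
#' For the sample mean this coincides exactly with the classical
#' t-interval.
#'
#' @param x per-subject values (numeric vector), or a list of
#'   per-subject data if \code{statistic} needs more than a scalar each.
#' @param statistic function mapping the collection of subjects to a
#'   scalar; default the mean of the per-subject values.
#' @param conf confidence level.
#' @return list with \code{estimate}, \code{lower}, \code{upper},
#'   \code{se}, \code{n}.
#' @export
jackknifeCI <- function(x, statistic = NULL, conf = 0.95) {
  n <- length(x)
  if (n < 2) stop("jackknife requires at least 2 subjects")
  if (is.null(statistic)) statistic <- function(v) mean(unlist(v))
  full <- statistic(x)
  loo <- vapply(seq_len(n), function(i) statistic(x[-i]), 0)
  pseudo <- n * full - (n - 1) * loo
  est <- mean(pseudo)
  se <- stats::sd(pseudo) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  list(estimate = est, lower = est - tq * se, upper = est + tq * se,
       se = se, n = n)
}

#' Sliding-window righting probability with exact binomial CI
#'
#' Fraction of successful righting trials in sliding windows (default
#' 10 trials, step 1) with exact Clopper-Pearson confidence bounds from
#' the binomial distribution.
#'
#' @param outcomes ordered binary trial outcomes (0/1 or logical).
#' @param window window size in trials.
#' @param step step in trials.
#' @param conf confidence level.
#' @param intervalMin spacing of trials in minutes (3-min assessments);
#'   used only for the returned time column.
#' @return data.frame with \code{windowCenterTrial},
#'   \code{windowCenterMin}, \code{k}, \code{n}, \code{p},
#'   \code{lower}, \code{upper}.
#' @export
rightingProbability <- function(outcomes, window = 10, step = 1,
                                conf = 0.95, intervalMin = 3) {
  outcomes <- as.integer(outcomes)
  stopifnot(all(outcomes %in% c(0L, 1L)), length(outcomes) >= window)
  starts <- seq(1, length(outcomes) - window + 1, by = step)
  k <- vapply(starts, function(s) sum(outcomes[s:(s + window - 1)]), 0L)
  ci <- binomialCI(k, window, conf = conf)
  centers <- starts + (window - 1) / 2
  data.frame(windowCenterTrial = centers,
             windowCenterMin = (centers - 1) * intervalMin,
             k = k, n = window, p = k / window,
             lower = ci$lower, upper = ci$upper)
}

#' Windowed temperature change relative to a time-matched control period
#'
#' Mean temperature over a window centered a fixed offset after the
#' injection, minus the mean over the same window placed at the control
#' time (default 24 h later at the same zeitgeber time, to account for
#' diurnal variation).
#'
#' @param trace data.frame from [thermalTrace()] (columns \code{time},
#'   \code{temperature}), or a numeric vector with \code{fs} given.
#' @param injectionT injection time in seconds.
#' @param controlT control-period injection-equivalent time in seconds.
#' @param windowS averaging window length in seconds (default 50 min).
#' @param centerOffsetS window center offset after injection (default
#'   90 min).
#' @param fs sampling rate in Hz if \code{trace} is a bare vector.
#' @return temperature difference in the trace's units (post - control).
#' @export
temperatureDelta <- function(trace, injectionT,
                             controlT = injectionT + 86400,
                             windowS = 3000, centerOffsetS = 5400,
                             fs = NULL) {
  if (is.numeric(trace) && !is.null(fs))
    trace <- data.frame(time = (seq_along(trace) - 1) / fs,
                        temperature = trace)
  stopifnot(all(c("time", "temperature") %in% names(trace)))
  winMean <- function(center) {
    sel <- trace$time >= center - windowS / 2 &
      trace$time <= center + windowS / 2
    if (!any(sel)) stop("trace does not cover the analysis window at t = ",
                        center, " s")
    mean(trace$temperature[sel])
  }
  winMean(injectionT + centerOffsetS) - winMean(controlT + centerOffsetS)
}
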