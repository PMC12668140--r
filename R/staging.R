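# Vigilance-state classification: NMF spectral features, 8-dimensional
# feature vectors, a small feedforward network, leave-one-subject-out
# cross-validation, and the minimum-duration persistence filter.

#' Fit a non-negative matrix factorization of pooled spectrograms
#'
#' Rank-k factorization X ~ W H of a non-negative window-by-frequency
#' power matrix, minimizing squared reconstruction error by
#' multiplicative updates from a seeded random start. Reports the
#' fraction of spectral variance captured, defined as
#' 1 - ||X - WH||^2 / ||X - Xbar||^2 with Xbar the mean spectrum
#' replicated across windows.
#'
#' @param x a [Spectrogram-class], a list of them (pooled by row), or a
#'   non-negative matrix (windows x frequencies).
#' @param k factorization rank (number of spectral features).
#' @param maxIter maximum multiplicative-update iterations.
#' @param tol relative change in reconstruction error for convergence.
#' @param seed integer seed for the random initialization.
#' @return An object of class \code{NMFModel}: list with \code{basis}
#'   (k x frequency, non-negative), \code{frequencies},
#'   \code{varianceCaptured}, \code{k}.
#' @export
fitNMF <- function(x, k = 6, maxIter = 500, tol = 1e-9, seed = 1) {
  if (is(x, "Spectrogram")) x <- list(x)
  if (is.list(x) && all(vapply(x, is, TRUE, "Spectrogram"))) {
    freqs <- frequencyGrid(x[[1]])
    for (s in x) if (max(abs(frequencyGrid(s) - freqs)) > 1e-9)
      stop("pooled spectrograms must share a frequency grid")
    X <- do.call(rbind, lapply(x, powerMatrix))
  } else {
    X <- as.matrix(x)
    freqs <- seq_len(ncol(X))
  }
  if (any(X < 0)) stop("NMF input must be non-negative")
  n <- nrow(X); m <- ncol(X)
  stopifnot(k >= 1, k <= min(n, m))
  eps <- 1e-12
  withSeed(seed, {
    sc <- sqrt(mean(X) / k)
    W <- matrix(runif(n * k), n, k) * sc
    H <- matrix(runif(k * m), k, m) * sc
    errPrev <- Inf
    for (it in seq_len(maxIter)) {
      H <- H * (crossprod(W, X) / (crossprod(W, W %*% H) + eps))
      W <- W * (X %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
      if (it %% 10 == 0 || it == maxIter) {
        err <- sum((X - W %*% H)^2)
        if (is.finite(errPrev) && (errPrev - err) <= tol * errPrev) break
        errPrev <- err
      }
    }
    resid <- sum((X - W %*% H)^2)
    total <- sum(sweep(X, 2, colMeans(X))^2)
    # identical rows have zero variance about the mean spectrum; the
    # factorization then captures everything iff it reconstructs exactly
    vc <- if (total > 0) 1 - resid / total
          else as.numeric(resid <= 1e-10 * max(1, sum(X^2)))
    structure(list(basis = H, frequencies = freqs,
                   varianceCaptured = vc, k = k),
              class = "NMFModel")
  })
}

#' Project a spectrogram onto a fitted NMF basis
#'
#' Non-negative least-squares projection of each window's spectrum onto
#' the k fixed basis spectra.
#'
#' @param model an \code{NMFModel} from [fitNMF()].
#' @param spec a [Spectrogram-class] on the model's frequency grid, or a
#'   matrix (windows x frequencies).
#' @return windows x k matrix of non-negative loadings.
#' @export
transformNMF <- function(model, spec) {
  stopifnot(inherits(model, "NMFModel"))
  if (is(spec, "Spectrogram")) {
    if (length(frequencyGrid(spec)) != length(model$frequencies) ||
        max(abs(frequencyGrid(spec) - model$frequencies)) > 1e-9)
      stop("frequency grid does not match the fitted basis")
    X <- powerMatrix(spec)
  } else X <- as.matrix(spec)
  Bt <- t(model$basis)  # frequencies x k
  L <- matrix(0, nrow(X), model$k)
  for (w in seq_len(nrow(X)))
    L[w, ] <- pracma::lsqnonneg(Bt, X[w, ])$x
  L
}

#' Assemble and standardize the 8-dimensional staging features
#'
#' Concatenates k NMF loadings with EMG RMS and accelerometer RMS into
#' the per-window feature matrix, and z-scores each column. The
#' standardization parameters are estimated from the supplied data when
#' \code{center}/\code{scale} are NULL (training), and applied as given
#' otherwise (held-out data must be standardized with training
#' parameters, never its own).
#'
#' @param loadings windows x k NMF loading matrix.
#' @param emgRms,accelRms numeric vectors on the same window grid.
#' @param center,scale optional per-feature standardization parameters.
#' @return matrix with attributes \code{center} and \code{scale}.
#' @export
assembleFeatures <- function(loadings, emgRms, accelRms,
                             center = NULL, scale = NULL) {
  loadings <- as.matrix(loadings)
  if (nrow(loadings) != length(emgRms) || nrow(loadings) != length(accelRms))
    stop("feature inputs must share a window grid")
  X <- cbind(loadings, emg = emgRms, accel = accelRms)
  colnames(X) <- c(paste0("nmf", seq_len(ncol(loadings))), "emgRMS",
                   "accelRMS")
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale
  Xs
}

# Seeded downsampling of the majority classes to the rarest class size.
balanceClasses <- function(labels, seed = 1) {
  tab <- table(labels)
  nMin <- min(tab)
  withSeed(seed, {
    idx <- unlist(lapply(names(tab), function(cl) {
      i <- which(labels == cl)
      sort(sample(i, nMin))
    }), use.names = FALSE)
    sort(idx)
  })
}

#' Train the feedforward vigilance-state classifier
#'
#' A fully connected single-hidden-layer network (default 32 units) with
#' softmax output over the three states, trained on standardized
#' features with weight decay; deterministic for a fixed seed.
#'
#' @param features standardized feature matrix (windows x 8).
#' @param labels per-window state labels (character or [Hypnogram-class]).
#' @param hidden hidden layer size.
#' @param decay weight decay (L2) regularization.
#' @param maxit maximum optimizer iterations.
#' @param seed integer seed for weight initialization.
#' @return object of class \code{stateClassifier}.
#' @export
trainClassifier <- function(features, labels, hidden = 32, decay = 1e-3,
                            maxit = 300, seed = 1) {
  if (is(labels, "Hypnogram")) labels <- stateLabels(labels)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  missing <- setdiff(VIGILANCE_STATES, unique(labels))
  if (length(missing))
    stop("training data lacks class(es): ", paste(missing, collapse = ", "))
  y <- nnet::class.ind(factor(labels, levels = VIGILANCE_STATES))
  net <- withSeed(seed, {
    nnet::nnet(features, y, size = hidden, softmax = TRUE, decay = decay,
               maxit = maxit, trace = FALSE, MaxNWts = 5000)
  })
  structure(list(net = net, levels = VIGILANCE_STATES,
                 nFeatures = ncol(features)),
            class = "stateClassifier")
}

#' Predict state labels (and posteriors) for feature windows
#'
#' @param classifier a \code{stateClassifier} from [trainClassifier()].
#' @param features standardized feature matrix.
#' @param windowS window grid step in seconds for the returned hypnogram.
#' @return a [Hypnogram-class] (provenance "raw") with posterior matrix
#'   in attribute \code{posterior}.
#' @export
predictStates <- function(classifier, features, windowS = 2.5) {
  stopifnot(inherits(classifier, "stateClassifier"))
  post <- stats::predict(classifier$net, features)
  lab <- classifier$levels[max.col(post, ties.method = "first")]
  h <- Hypnogram(lab, windowS = windowS, provenance = "raw")
  attr(h, "posterior") <- post
  h
}

#' Minimum-duration persistence filter
#'
#' Scanning left to right, any maximal run of identical labels shorter
#' than \code{minRun} windows is merged into the preceding surviving
#' (>= minRun) state; leading short runs are merged into the first
#' surviving state. If no run reaches \code{minRun} the input is
#' returned unchanged (a terminal remnant). The operation is idempotent
#' and never introduces labels absent from its input.
#'
#' @param h a [Hypnogram-class].
#' @param minRun minimum run length in windows (default 15; at the
#'   2.5 s step grid this is a 37.5 s minimum bout).
#' @return a [Hypnogram-class] with provenance "persistence-filtered".
#' @export
persistenceFilter <- function(h, minRun = 15) {
  stopifnot(is(h, "Hypnogram"), minRun >= 1)
  lab <- stateLabels(h)
  r <- rle(lab)
  surv <- r$lengths >= minRun
  if (!any(surv) || all(surv)) {
    out <- lab
  } else {
    vals <- r$values
    survIdx <- which(surv)
    newVals <- character(length(vals))
    for (i in seq_along(vals)) {
      if (surv[i]) newVals[i] <- vals[i]
      else {
        prev <- survIdx[survIdx < i]
        if (length(prev)) newVals[i] <- vals[max(prev)]
        else newVals[i] <- vals[min(survIdx[survIdx > i])]
      }
    }
    out <- rep(newVals, r$lengths)
  }
  Hypnogram(out, windowS = windowSeconds(h),
            provenance = "persistence-filtered")
}

#' Extract staging features from a synthetic session
#'
#' Runs the full feature front-end on one session: EEG preprocessing
#' (decimation to 125 Hz, 0.5 Hz high-pass, mean re-reference),
#' multitaper spectrogram of the first EEG channel, EMG preprocessing
#' (differential reference, 300 Hz high-pass) with windowed RMS, and
#' accelerometer windowed RMS, all on one shared window grid, together
#' with the aligned ground-truth labels.
#'
#' @param session a [SyntheticSession-class].
#' @param windowS,stepS,nTapers spectrogram parameters.
#' @return list with \code{spec} ([Spectrogram-class]), \code{emgRms},
#'   \code{accelRms}, \code{labels}, \code{subject}, \code{stepS}.
#' @export
extractStagingFeatures <- function(session, windowS = 5, stepS = 2.5,
                                   nTapers = 35) {
  stopifnot(is(session, "SyntheticSession"))
  eeg <- preprocessEEG(session@eeg)
  spec <- multitaperSpectrogram(eeg, windowS = windowS, stepS = stepS,
                                nTapers = nTapers, channel = 1)
  emg <- preprocessEMG(session@emg)
  emgR <- windowedRMS(emg, windowS = windowS, stepS = stepS)
  accR <- windowedRMS(session@accel, windowS = windowS, stepS = stepS)
  nWin <- nrow(powerMatrix(spec))
  labAll <- stateLabels(session@states)
  # window k starts at (k-1)*stepS; label it by the state window opening it
  labIdx <- pmin(length(labAll),
                 floor((seq_len(nWin) - 1) * stepS /
                         windowSeconds(session@states)) + 1L)
  list(spec = spec, emgRms = emgR$rms[seq_len(nWin)],
       accelRms = accR$rms[seq_len(nWin)], labels = labAll[labIdx],
       subject = session@subject, stepS = stepS)
}

#' Leave-one-subject-out cross-validation of the staging pipeline
#'
#' For each held-out subject, fits the NMF basis, feature
#' standardization and classifier on the remaining subjects only
#' (class-balanced by seeded downsampling to the rarest state), then
#' scores the held-out subject's windows. Predictions are
#' persistence-filtered before scoring; the unfiltered (raw) accuracy
#' is reported alongside.
#'
#' @param subjects list of per-subject feature sets from
#'   [extractStagingFeatures()].
#' @param k NMF rank.
#' @param hidden,decay,maxit classifier parameters.
#' @param minRun persistence-filter minimum run (windows).
#' @param seed integer seed controlling NMF init, balancing and weights.
#' @return object of class \code{CVReport}: list with \code{perFold}
#'   data.frame, \code{overallAccuracy}, \code{overallAccuracyRaw},
#'   \code{confusion} (3x3 counts, true state in rows), \code{nWindows}.
#' @export
losoCV <- function(subjects, k = 6, hidden = 32, decay = 1e-3, maxit = 300,
                   minRun = 15, seed = 1) {
  stopifnot(length(subjects) >= 2)
  nS <- length(subjects)
  conf <- matrix(0L, 3, 3,
                 dimnames = list(true = VIGILANCE_STATES,
                                 predicted = VIGILANCE_STATES))
  perFold <- data.frame(subject = character(nS), accuracy = numeric(nS),
                        accuracyRaw = numeric(nS), nWindows = integer(nS))
  correct <- 0L; correctRaw <- 0L; total <- 0L
  for (fold in seq_len(nS)) {
    train <- subjects[-fold]
    test <- subjects[[fold]]
    art <- fitStagingModel(train, k = k, hidden = hidden, decay = decay,
                           maxit = maxit, seed = seed + fold)
    predRaw <- applyStagingModel(art, test)
    predFilt <- persistenceFilter(predRaw, minRun = minRun)
    truth <- test$labels
    accF <- mean(stateLabels(predFilt) == truth)
    accR <- mean(stateLabels(predRaw) == truth)
    perFold$subject[fold] <- test$subject
    perFold$accuracy[fold] <- accF
    perFold$accuracyRaw[fold] <- accR
    perFold$nWindows[fold] <- length(truth)
    correct <- correct + sum(stateLabels(predFilt) == truth)
    correctRaw <- correctRaw + sum(stateLabels(predRaw) == truth)
    total <- total + length(truth)
    conf <- conf + table(factor(truth, levels = VIGILANCE_STATES),
                         factor(stateLabels(predFilt),
                                levels = VIGILANCE_STATES))
  }
  structure(list(perFold = perFold,
                 overallAccuracy = correct / total,
                 overallAccuracyRaw = correctRaw / total,
                 confusion = conf, nWindows = total),
            class = "CVReport")
}

#' Fit the staging model (NMF + standardization + classifier) on a
#' training set of subjects
#'
#' @param train list of feature sets from [extractStagingFeatures()].
#' @param k,hidden,decay,maxit,seed as in [losoCV()].
#' @return list with \code{nmf}, \code{center}, \code{scale},
#'   \code{classifier}.
#' @export
fitStagingModel <- function(train, k = 6, hidden = 32, decay = 1e-3,
                            maxit = 300, seed = 1) {
  nmf <- fitNMF(lapply(train, `[[`, "spec"), k = k, seed = seed)
  feats <- lapply(train, function(s)
    cbind(transformNMF(nmf, s$spec), s$emgRms, s$accelRms))
  X <- do.call(rbind, feats)
  labels <- unlist(lapply(train, `[[`, "labels"), use.names = FALSE)
  Xs <- assembleFeatures(X[, seq_len(k), drop = FALSE], X[, k + 1],
                         X[, k + 2])
  bal <- balanceClasses(labels, seed = seed)
  clf <- trainClassifier(Xs[bal, , drop = FALSE], labels[bal],
                         hidden = hidden, decay = decay, maxit = maxit,
                         seed = seed)
  list(nmf = nmf, center = attr(Xs, "center"), scale = attr(Xs, "scale"),
       classifier = clf)
}

#' Apply a fitted staging model to one subject's features
#'
#' @param model artifact list from [fitStagingModel()].
#' @param subject feature set from [extractStagingFeatures()].
#' @return raw (unfiltered) predicted [Hypnogram-class].
#' @export
applyStagingModel <- function(model, subject) {
  L <- transformNMF(model$nmf, subject$spec)
  Xs <- assembleFeatures(L, subject$emgRms, subject$accelRms,
                         center = model$center, scale = model$scale)
  predictStates(model$classifier, Xs, windowS = subject$stepS)
}
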