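# NMF features, classifier, LOSO cross-validation, persistence filter.

test_that("NMF recovers exact low-rank structure and reports variance", {
  withr::with_seed(1, {
    W <- matrix(runif(40), 20, 2)
    H <- matrix(runif(30), 2, 15)
  })
  X <- W %*% H
  m <- fitNMF(X, k = 2, seed = 3)
  expect_gte(m$varianceCaptured, 0.999)
  expect_true(all(m$basis >= 0))

  # duplicated single spectrum: rank-1 recovery
  X1 <- matrix(rep(runif(15), each = 10), 10, 15)
  m1 <- fitNMF(X1, k = 1, seed = 2)
  expect_gte(m1$varianceCaptured, 1 - 1e-6)

  expect_error(fitNMF(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("rank-6 NMF captures >= 90% of synthetic spectral variance", {
  subs <- smallCohort()
  m <- fitNMF(lapply(subs, `[[`, "spec"), k = 6, seed = 1)
  expect_gte(m$varianceCaptured, 0.90)
})

test_that("NMF projection is a consistent nonnegative least-squares", {
  withr::with_seed(4, X <- matrix(runif(600), 40, 15))
  m <- fitNMF(X, k = 3, seed = 1)
  L <- transformNMF(m, X)
  expect_true(all(L >= 0))

  # a window equal to a basis vector loads on that component only
  probe <- rbind(m$basis[2, ] * 3, rep(0, 15))
  Lp <- transformNMF(m, probe)
  expect_equal(Lp[1, 2], 3, tolerance = 1e-6)
  expect_lt(max(Lp[1, -2]), 1e-6)
  # zero window -> zero loadings
  expect_equal(Lp[2, ], rep(0, 3))
})

test_that("feature assembly standardizes with training parameters only", {
  withr::with_seed(5, {
    L <- matrix(runif(60), 20, 3)
    emg <- runif(20, 5, 30)
    acc <- runif(20, 0, 1)
  })
  Xtr <- assembleFeatures(L, emg, acc)
  expect_equal(dim(Xtr), c(20, 5))
  expect_equal(unname(colMeans(Xtr)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(Xtr, 2, sd)), rep(1, 5), tolerance = 1e-12)

  # held-out data standardized with training parameters, not its own
  Xte <- assembleFeatures(L[1:5, ] + 10, emg[1:5], acc[1:5],
                          center = attr(Xtr, "center"),
                          scale = attr(Xtr, "scale"))
  expect_false(isTRUE(all.equal(unname(colMeans(Xte)), rep(0, 5))))
  expect_equal(attr(Xte, "center"), attr(Xtr, "center"))

  expect_error(assembleFeatures(L, emg[1:5], acc), "window grid")
})

test_that("classifier separates well-separated clusters and is seeded", {
  withr::with_seed(6, {
    X <- rbind(matrix(rnorm(200, 0), 100, 2),
               matrix(rnorm(200, 6), 100, 2),
               matrix(rnorm(200, -6), 100, 2))
  })
  y <- rep(c("WAKE", "NREM", "REM"), each = 100)
  clf <- trainClassifier(X, y, hidden = 8, seed = 1)
  pred <- predictStates(clf, X)
  expect_equal(mean(stateLabels(pred) == y), 1.0)

  # refit with the same seed: identical predictions
  clf2 <- trainClassifier(X, y, hidden = 8, seed = 1)
  expect_identical(stateLabels(predictStates(clf2, X)),
                   stateLabels(pred))

  # labels independent of features: held-out accuracy near chance
  withr::with_seed(7, yShuf <- sample(y))
  clfS <- trainClassifier(X[1:250, ], yShuf[1:250], hidden = 8, seed = 1)
  accS <- mean(stateLabels(predictStates(clfS, X[251:300, ])) ==
                 yShuf[251:300])
  expect_lt(accS, 0.6)

  expect_error(trainClassifier(X[1:200, ], y[1:200]), "lacks class")
})

test_that("persistence filter merges short runs per the minimum-duration rule", {
  # 14-window REM run inside NREM is relabeled NREM
  h <- runHypno(NREM = 20, REM = 14, NREM = 20)
  expect_equal(unique(stateLabels(persistenceFilter(h))), "NREM")

  # W x20, N x5, W x15: N absorbed into preceding W, output all W
  h2 <- runHypno(WAKE = 20, NREM = 5, WAKE = 15)
  expect_equal(stateLabels(persistenceFilter(h2)), rep("WAKE", 40))

  # single-state input unchanged
  h3 <- runHypno(NREM = 40)
  expect_equal(stateLabels(persistenceFilter(h3)), stateLabels(h3))

  # leading short run merges into the following surviving state
  h4 <- runHypno(REM = 3, WAKE = 30)
  expect_equal(stateLabels(persistenceFilter(h4)), rep("WAKE", 33))

  # a 15-window run survives exactly at the threshold
  h5 <- runHypno(WAKE = 20, NREM = 15, WAKE = 20)
  expect_equal(stateLabels(persistenceFilter(h5)), stateLabels(h5))
})

test_that("persistence filter is idempotent and introduces no new labels", {
  withr::with_seed(8, {
    for (i in 1:20) {
      # bout-structured labels: geometric run lengths around the
      # persistence threshold so both short and long runs occur
      runLens <- rgeom(30, 1 / 18) + 1
      states <- sample(c("WAKE", "NREM", "REM"), 30, replace = TRUE)
      lab <- rep(states, runLens)
      h <- Hypnogram(lab)
      f1 <- persistenceFilter(h)
      f2 <- persistenceFilter(f1)
      expect_identical(stateLabels(f1), stateLabels(f2))
      expect_true(all(stateLabels(f1) %in% unique(lab)))
      if (any(runLens >= 15))
        expect_true(all(rle(stateLabels(f1))$lengths >= 15))
    }
  })
})

test_that("LOSO achieves perfect accuracy on identically separable subjects
           and chance when labels are independent of features", {
  subs <- smallCohort()
  cv <- losoCV(subs[1:2], seed = 1)
  expect_s3_class(cv$perFold, "data.frame")
  expect_gt(cv$overallAccuracy, 0.9)
  expect_equal(sum(cv$confusion), cv$nWindows)
  # confusion row sums equal per-class true window counts
  truth <- unlist(lapply(subs[1:2], `[[`, "labels"))
  expect_equal(unname(rowSums(cv$confusion)),
               as.vector(table(factor(truth,
                                      c("WAKE", "NREM", "REM")))))

  # shuffled labels: accuracy near 1/3
  shuf <- lapply(subs[1:2], function(s) {
    s$labels <- withr::with_seed(9, sample(s$labels))
    s
  })
  cvS <- losoCV(shuf, seed = 1)
  expect_lt(cvS$overallAccuracyRaw, 0.5)
})

test_that("held-out data never influences the trained artifacts", {
  subs <- smallCohort()
  # training on subjects 1-2 must be identical whether subject 3's data
  # exists or not (losoCV passes only the training subjects through)
  direct <- fitStagingModel(subs[1:2], seed = 1 + 3)
  viaCV <- fitStagingModel(subs[c(1, 2)], seed = 1 + 3)
  expect_identical(direct$nmf$basis, viaCV$nmf$basis)
  expect_identical(direct$classifier$net$wts, viaCV$classifier$net$wts)
  expect_identical(direct$center, viaCV$center)
})

test_that("staging accuracy is monotone non-decreasing in generator SNR", {
  accAt <- function(contrast) {
    prof <- defaultSpectralProfile()
    prof$states$NREM$delta <- prof$states$WAKE$delta * contrast
    prof$states$REM$theta <- prof$states$WAKE$theta * contrast
    prof$states$WAKE$emg <- prof$states$NREM$emg * contrast
    subs <- lapply(1:2, function(i) {
      st <- simulateStateSequence(nWindows = 240, dwellWindows = 10,
                                  seed = 300 + i)
      sig <- synthesizeSignals(st, prof, seed = 400 + i)
      sess <- new("SyntheticSession", eeg = sig$eeg, emg = sig$emg,
                  accel = sig$accel, states = st,
                  calcium = matrix(0, 2400, 0), calciumFs = 4,
                  calciumEvents = list(), subject = paste0("s", i),
                  seed = 300L + i)
      extractStagingFeatures(sess)
    })
    losoCV(subs, seed = 5)$overallAccuracyRaw
  }
  accs <- vapply(c(1.05, 2, 10), accAt, 0)
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], 0.9)
})
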