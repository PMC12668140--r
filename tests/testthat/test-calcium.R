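# dF/F conditioning, transient detection (both variants), state rates,
# preference index, survivor curves, simplex summaries.

test_that("detrending removes cubic drift and preserves dF/F amplitude", {
  n <- 400
  tt <- seq_len(n) / n

  # pure cubic input: residual ~ 0
  cub <- 100 + 20 * tt - 15 * tt^2 + 8 * tt^3
  expect_lt(max(abs(detrendNormalize(cub))), 1e-10)

  # raw = m * (1 + transient): transient amplitude preserved in dF/F
  tr <- numeric(n); tr[200:205] <- 1.8
  m <- 250
  raw <- m * (1 + tr)
  dff <- detrendNormalize(raw)
  # detrending removes the small polynomial leakage of the transient
  expect_equal(max(dff) - stats::median(dff), 1.8, tolerance = 0.05)

  # adding an offset changes output only via the mean normalization
  raw2 <- raw + 100
  dff2 <- detrendNormalize(raw2)
  expect_equal(dff2 * mean(raw2), dff * mean(raw), tolerance = 1e-8)

  expect_error(detrendNormalize(rep(0, 100)), "mean is zero")
})

test_that("transient detection enforces height, prominence and separation", {
  fs <- 4
  expect_equal(nrow(detectTransients(rep(0.2, 100), fs)), 0)

  # three peaks of 1.5 dF/F, 5 s apart: all detected
  tr <- numeric(200); tr[c(20, 40, 60)] <- 1.5
  d3 <- detectTransients(tr, fs)
  expect_equal(nrow(d3), 3)
  expect_equal(d3$index, c(20, 40, 60))

  # two peaks 0.5 s apart: only the higher is kept
  tr2 <- numeric(100); tr2[20] <- 1.5; tr2[22] <- 1.9
  d1 <- detectTransients(tr2, fs)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$height, 1.9)

  # a secondary bump on the shoulder of a larger transient: height
  # passes (2.0 dF/F) but prominence above its saddle (0.1) fails
  sh <- numeric(80)
  sh[20] <- 2.5
  sh[21:39] <- 1.9
  sh[40] <- 2.0
  dSh <- detectTransients(sh, fs)
  expect_equal(nrow(dSh), 1)
  expect_equal(dSh$height, 2.5)
  # lowering the saddle restores the bump's prominence
  sh[21:39] <- 1.0
  expect_equal(nrow(detectTransients(sh, fs)), 2)
})

test_that("detection recovers generated ground truth at default noise", {
  ss <- simulateStateSequence(nWindows = 1440, seed = 11)
  prec <- rec <- numeric(4)
  for (i in 1:4) {
    cal <- synthesizeCalcium(ss, rates = c(WAKE = 0.5, NREM = 2, REM = 1),
                             noiseSd = 0.1, driftPoly = 0, seed = i)
    det <- detectTransients(cal$trace, fs = cal$fs)
    m <- matchEvents(det$time, cal$eventTimes, tol = 0.75)
    prec[i] <- m$precision
    rec[i] <- m$recall
  }
  expect_gte(mean(prec), 0.95)
  expect_gte(mean(rec), 0.95)
})

test_that("two-photon threshold detection behaves like a 3-sigma rule", {
  fs <- 4
  # pure Gaussian noise: supra-threshold fraction near the normal tail
  withr::with_seed(3, g <- 100 + rnorm(40000))
  r <- detectTransients2P(g, fs)
  expect_lt(abs(mean(r$mask) - 0.00135), 0.0001 + 0.00135)
  expect_lt(mean(r$mask), 0.005)

  # an injected 5-sigma plateau is one contiguous event
  withr::with_seed(4, g2 <- 100 + rnorm(4000))
  g2[2000:2020] <- g2[2000:2020] + 5
  r2 <- detectTransients2P(g2, fs)
  covering <- r2$events$start <= 1999 / fs & r2$events$end >= 2019 / fs
  expect_equal(sum(covering), 1)

  # constant trace: no events
  r0 <- detectTransients2P(rep(50, 100), fs)
  expect_equal(nrow(r0$events), 0)
})

test_that("state rates divide counts by per-state exposure", {
  h <- runHypno(NREM = 240)  # 10 min NREM
  ev <- seq(10, 590, length.out = 10)
  r <- stateRates(ev, h)
  expect_equal(r$rate[r$state == "NREM"], 1.0)
  expect_equal(r$exposureMin[r$state == "NREM"], 10)
  # zero-exposure states undefined
  expect_true(all(is.na(r$rate[r$state != "NREM"])))

  h2 <- runHypno(WAKE = 120, NREM = 120)
  r2 <- stateRates(c(1, 2, 3), h2)  # all events in wake
  expect_equal(r2$rate[r2$state == "NREM"], 0)
  expect_equal(r2$rate[r2$state == "WAKE"], 0.6)

  expect_error(stateRates(c(1e6), h2), "outside")
})

test_that("state preference index sums to 1 and follows the printed medians", {
  # symmetric two-state case
  sp <- statePreference(c(iso = 1, wake = 1))
  expect_equal(unname(sp$S["iso"]), 0.5)

  # the published per-state median rates give S_NREM = 0.620
  sp2 <- statePreference(c(NREM = 0.5076, REM = 0.2437, WAKE = 0.0677))
  expect_equal(unname(sp2$S["NREM"]), 0.620, tolerance = 5e-4)
  expect_equal(sum(sp2$S), 1)
  expect_equal(sp2$preferred, "NREM")

  # all-zero cells are excluded
  sp0 <- statePreference(c(WAKE = 0, NREM = 0, REM = 0))
  expect_false(sp0$included)
  expect_true(is.na(sp0$preferred))

  # scale invariance
  spA <- statePreference(c(WAKE = 0.2, NREM = 1.4, REM = 0.4))
  spB <- statePreference(c(WAKE = 0.2, NREM = 1.4, REM = 0.4) * 17)
  expect_equal(spA$S, spB$S)
})

test_that("preference ties break by exposure then fixed state order", {
  r <- data.frame(state = c("WAKE", "NREM", "REM"), events = c(4, 4, 1),
                  exposureMin = c(10, 20, 5), rate = c(0.4, 0.2, 0.2))
  expect_equal(statePreference(r)$preferred, "NREM")  # more exposure
  r2 <- r; r2$exposureMin <- c(10, 10, 5)
  expect_equal(statePreference(r2)$preferred, "WAKE")  # fixed order
})

test_that("survivor curve reports the fraction preferring a state", {
  s <- survivorCurve(rep(1, 5))
  expect_equal(s$fractionPreferring, 1)
  expect_equal(s$at(0.5), 1)

  s0 <- survivorCurve(c(0.1, 0.2, 0.3))
  expect_equal(s0$fractionPreferring, 0)

  sv <- survivorCurve(c(0.9, 0.8, 0.6, 0.4, 0.2))
  expect_equal(sv$fractionPreferring, 3 / 5)
  expect_equal(sv$at(0), 1)
  expect_true(all(diff(sv$curve$P) <= 0))
})

test_that("simplex embedding maps preferences into the triangle", {
  cen <- simplexCoordinates(matrix(1 / 3, 1, 3))
  expect_equal(as.numeric(cen$xy), c(0.5, sqrt(3) / 6), tolerance = 1e-12)

  vert <- simplexCoordinates(matrix(c(1, 0, 0), 1))
  expect_equal(as.numeric(vert$xy), c(0, 0))

  # an NREM-biased cohort has the highest NREM proportion
  withr::with_seed(5, {
    S <- cbind(runif(40, 0, 0.2), runif(40, 0.5, 0.9), runif(40, 0, 0.2))
    S <- S / rowSums(S)
  })
  colnames(S) <- c("WAKE", "NREM", "REM")
  sx <- simplexCoordinates(S)
  expect_equal(names(which.max(sx$proportions)), "NREM")
  expect_equal(sum(sx$proportions), 1)

  expect_error(simplexCoordinates(matrix(c(1, 1, 1), 1)), "sum to 1")
})
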