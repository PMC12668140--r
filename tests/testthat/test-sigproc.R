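# Filtering, decimation, multitaper spectral estimation, windowed RMS,
# band fractions, power ratios, thermal traces.

mkTS <- function(x, fs = 1000, ncolumns = 1) {
  TimeSeries(matrix(rep(x, ncolumns), ncol = ncolumns), fs = fs)
}

test_that("EEG preprocessing removes DC, attenuates sub-cutoff drift, and
           passes the physiological band with zero phase", {
  fs <- 1000
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)

  # constant offset on both channels -> (mean re-referenced) zero output
  const <- TimeSeries(cbind(rep(5, length(tt)), rep(3, length(tt))), fs)
  out <- preprocessEEG(const)
  expect_equal(samplingRate(out), 125)
  expect_lt(max(abs(sampleMatrix(out))), 1e-6)

  # 0.1 Hz drift on one channel: attenuated >= 60 dB by the squared
  # 4th-order Butterworth response at f/fc = 0.2
  drift <- TimeSeries(cbind(sin(2 * pi * 0.1 * tt), rep(0, length(tt))), fs)
  outD <- preprocessEEG(drift)
  mid <- seq(from = round(0.3 * nrow(sampleMatrix(outD))),
             to = round(0.7 * nrow(sampleMatrix(outD))))
  # channel 1 minus the mean halves amplitude; allow for that factor
  gain <- max(abs(sampleMatrix(outD)[mid, 1])) / 0.5
  expect_lt(20 * log10(gain), -60)

  # 10 Hz is in the passband: amplitude within 1%, zero lag
  tone <- TimeSeries(cbind(sin(2 * pi * 10 * tt), rep(0, length(tt))), fs)
  outT <- preprocessEEG(tone)
  y <- sampleMatrix(outT)[mid, 1] * 2  # undo the re-reference halving
  ref <- sin(2 * pi * 10 * (mid - 1) / 125)
  expect_equal(max(abs(y)), 1, tolerance = 0.01)
  cc <- ccf(y, ref, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(preprocessEEG(TimeSeries(matrix(rnorm(100), ncol = 2), 500)),
               "1000 Hz")
  expect_error(preprocessEEG(mkTS(rnorm(1000))), "2 EEG channels")
})

test_that("EMG preprocessing differences the pair and high-passes at 300 Hz", {
  fs <- 1000
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)

  same <- TimeSeries(cbind(rnorm(length(tt)), 0), fs)
  same@samples[, 2] <- same@samples[, 1]
  expect_lt(max(abs(sampleMatrix(preprocessEMG(same)))), 1e-8)

  # 50 Hz common mode on both channels is removed by differencing
  cm <- TimeSeries(cbind(sin(2 * pi * 50 * tt), sin(2 * pi * 50 * tt)), fs)
  expect_lt(max(abs(sampleMatrix(preprocessEMG(cm)))), 1e-8)

  # 350 Hz differential signal passes within 3 dB
  hi <- TimeSeries(cbind(sin(2 * pi * 350 * tt), 0), fs)
  y <- sampleMatrix(preprocessEMG(hi))[2000:8000, 1]
  expect_gt(max(abs(y)), 10^(-3 / 20))

  expect_error(preprocessEMG(mkTS(rnorm(1000))), "2 EMG channels")
})

test_that("multitaper spectrogram is calibrated and energy-conserving", {
  fs <- 125
  withr::with_seed(1, x <- rnorm(fs * 300))
  spec <- multitaperSpectrogram(TimeSeries(x, fs))
  expect_s4_class(spec, "Spectrogram")
  f <- frequencyGrid(spec)
  m <- colMeans(powerMatrix(spec))
  # unit-variance white noise: one-sided density 2/fs, flat within 10%
  inner <- f > 4 & f < 58
  expect_lt(max(abs(m[inner] / (2 / fs) - 1)), 0.10)

  # Parseval: integrated density ~ windowed variance within 5%
  df <- f[2] - f[1]
  totalPow <- mean(rowSums(powerMatrix(spec))) * df
  expect_equal(totalPow, 1, tolerance = 0.05)

  # a pure 10 Hz line peaks in the bin containing 10 Hz (narrow taper
  # family: the 35-taper default smooths over +/- 3.6 Hz by design)
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  spec2 <- multitaperSpectrogram(TimeSeries(sin(2 * pi * 10 * tt), fs),
                                 nTapers = 5, nw = 3)
  peakF <- frequencyGrid(spec2)[apply(powerMatrix(spec2), 1, which.max)]
  expect_true(all(abs(peakF - 10) <= 0.2 + 1e-9))

  expect_error(multitaperSpectrogram(TimeSeries(rnorm(100), fs)),
               "shorter than one analysis window")
  expect_error(multitaperSpectrogram(TimeSeries(rnorm(10 * fs), fs),
                                     windowS = 0.2), "taper count")
})

test_that("spectrogram and RMS share one window grid across modalities", {
  dur <- 120
  ts1 <- TimeSeries(rnorm(125 * dur), 125)
  ts2 <- TimeSeries(rnorm(1000 * dur), 1000)
  spec <- multitaperSpectrogram(ts1)
  rms <- windowedRMS(ts2)
  expect_equal(windowCenters(spec), rms$windowCenter)
})

test_that("windowed RMS matches closed forms", {
  fs <- 1000
  expect_equal(unique(windowedRMS(mkTS(rep(3, fs * 20)))$rms), 3)
  expect_equal(unique(windowedRMS(mkTS(rep(0, fs * 20)))$rms), 0)
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  r <- windowedRMS(mkTS(2 * sin(2 * pi * 10 * tt)))
  expect_equal(mean(r$rms), 2 / sqrt(2), tolerance = 1e-3)
})

test_that("band fraction matches analytic ratios and stays in [0, 1]", {
  fs <- 125
  withr::with_seed(2, spec <- multitaperSpectrogram(TimeSeries(rnorm(fs * 200), fs)))

  # flat spectrum: fraction ~ bandwidth ratio (3.5 / 62)
  swa <- bandFraction(spec)
  expect_equal(mean(swa$fraction), (4 - 0.5) / (62.5 - 0.5),
               tolerance = 0.05)
  expect_true(all(swa$fraction >= 0 & swa$fraction <= 1))

  # all power inside the band -> 1; all outside -> 0
  f <- frequencyGrid(spec)
  inBand <- matrix(0, 4, length(f))
  inBand[, f >= 1 & f <= 3] <- 5
  sIn <- new("Spectrogram", power = inBand, frequencies = f,
             windowCenters = 2.5 + (0:3) * 2.5, windowS = 5, stepS = 2.5,
             nTapers = 1)
  expect_equal(bandFraction(sIn)$fraction, rep(1, 4))
  outBand <- matrix(0, 4, length(f))
  outBand[, f >= 20 & f <= 40] <- 5
  sOut <- new("Spectrogram", power = outBand, frequencies = f,
              windowCenters = 2.5 + (0:3) * 2.5, windowS = 5, stepS = 2.5,
              nTapers = 1)
  expect_equal(bandFraction(sOut)$fraction, rep(0, 4))

  expect_error(bandFraction(spec, band = c(4, 4)), "empty band")
  expect_error(bandFraction(spec, band = c(0.5, 70)), "within totalBand")
})

test_that("power ratio is elementwise and flags zero baselines", {
  fs <- 125
  withr::with_seed(3, spec <- multitaperSpectrogram(TimeSeries(rnorm(fs * 60), fs)))
  r1 <- powerRatio(spec, spec)
  expect_equal(r1$ratio, rep(1, length(r1$ratio)))

  double <- new("Spectrogram", power = 2 * powerMatrix(spec),
                frequencies = frequencyGrid(spec),
                windowCenters = windowCenters(spec), windowS = 5,
                stepS = 2.5, nTapers = 35)
  expect_equal(powerRatio(double, spec)$ratio,
               rep(2, ncol(powerMatrix(spec))))

  zero <- new("Spectrogram", power = 0 * powerMatrix(spec),
              frequencies = frequencyGrid(spec),
              windowCenters = windowCenters(spec), windowS = 5,
              stepS = 2.5, nTapers = 35)
  rz <- powerRatio(spec, zero)
  expect_true(all(rz$undefined))
  expect_true(all(is.na(rz$ratio)))
})

test_that("thermal trace isolates the animal and rejects artifacts", {
  # uniform frames
  expect_equal(unique(thermalTrace(array(30, c(8, 8, 40)))$temperature), 30)

  # exactly 1% of pixels at 37 on a 20 background
  fr <- array(20, c(20, 20, 40))
  fr[1:2, 1:2, ] <- 37
  expect_equal(unique(thermalTrace(fr)$temperature), 37)

  # single-frame 5-degree artifact removed by the 5-min moving median
  fr2 <- array(30, c(10, 10, 80))
  fr2[, , 40] <- 35
  expect_equal(unique(thermalTrace(fr2)$temperature), 30)

  # baseline normalization
  tr <- thermalTrace(array(30, c(5, 5, 100)), refRange = c(0, 500))
  expect_equal(unique(tr$temperature), 0)
})
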