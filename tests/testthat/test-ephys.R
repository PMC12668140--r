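# Chirp stimuli, impedance profiles, resonance metrics, step and spike
# metrics.

test_that("chirp sweeps logarithmically from f0 to f1", {
  ch <- makeChirp(f0 = 0.2, f1 = 40, T = 20, dt = 0.1, padS = 0)
  expect_equal(ch$instFreq[1], 0.2)
  expect_equal(ch$instFreq[length(ch$instFreq)], 40, tolerance = 1e-6)
  iMid <- which.min(abs(ch$time - 10))
  expect_equal(ch$instFreq[iMid], sqrt(0.2 * 40), tolerance = 1e-3)
  expect_equal(ch$current[1], 0)
})

test_that("impedance profile is the spectral ratio in megaohms", {
  ch <- makeChirp(amplitude = 50)
  # V = I numerically: flat profile at 1000 MOhm per mV/pA
  z <- impedanceProfile(ch$current, ch$current, dt = ch$dt)
  expect_lt(diff(range(impedanceValues(z))), 1e-6)
  expect_equal(mean(impedanceValues(z)), 1000)

  expect_error(impedanceProfile(rep(0, 1000), rnorm(1000), dt = 0.1),
               "vanishes")
})

test_that("simulated membranes match the analytic impedance within 2% RMS", {
  ch <- makeChirp(amplitude = 50)
  for (p in list(MembraneParams(gL = 10, C = 150),
                 MembraneParams(gL = 10, C = 150, g1 = 30, tauW = 60))) {
    v <- simulateMembrane(p, ch$current, dt = ch$dt)
    z <- impedanceProfile(ch$current, v, dt = ch$dt)
    za <- analyticImpedance(p, frequencyGrid(z))
    rmsErr <- sqrt(mean((impedanceValues(z) - za)^2)) / mean(za)
    expect_lt(rmsErr, 0.02)
  }
})

test_that("resonance metrics follow their definitions and scale invariance", {
  # constructed profile: peak 2x the 0.5 Hz value, at 4 Hz
  f <- seq(0.2, 40, by = 0.1)
  zz <- 50 + 50 * exp(-(f - 4)^2 / 4)
  zz <- zz / (50 + 50 * exp(-(0.5 - 4)^2 / 4)) * 50  # |Z|(0.5) = 50
  zz <- zz / max(zz) * 100                           # |Z|max = 100
  prof <- new("ImpedanceProfile", frequencies = f, impedance = zz)
  m <- resonanceMetrics(prof)
  expect_equal(m$fR, 4, tolerance = 0.1)
  expect_equal(m$strength, max(zz) / zz[f == 0.5], tolerance = 1e-9)
  expect_gt(m$f3dB, m$fR)
  expect_equal(zz[which.min(abs(f - m$f3dB))], sqrt(0.5) * 100,
               tolerance = 0.02)

  # positive rescaling leaves all metrics unchanged
  m2 <- resonanceMetrics(new("ImpedanceProfile", frequencies = f,
                             impedance = 17 * zz))
  expect_equal(m2$fR, m$fR)
  expect_equal(m2$strength, m$strength)
  expect_equal(m2$f3dB, m$f3dB)

  # monotone-decreasing profile peaked at 0.5 Hz: strength 1
  fmono <- seq(0.5, 40, by = 0.1)
  mono <- new("ImpedanceProfile", frequencies = fmono,
              impedance = 100 / (1 + fmono))
  mm <- resonanceMetrics(mono)
  expect_equal(mm$strength, 1)
  expect_equal(mm$fR, 0.5)

  # no 3 dB crossing below the band edge is flagged
  flat <- new("ImpedanceProfile", frequencies = fmono,
              impedance = rep(80, length(fmono)))
  expect_true(resonanceMetrics(flat)$f3dBAtBandEdge)
})

test_that("ET classification is strict at the 2 Hz boundary", {
  expect_true(classifyET(4))
  expect_false(classifyET(2.0))
  expect_false(classifyET(1.2))
  expect_equal(classifyET(c(0.6, 2.5, 8)), c(FALSE, TRUE, TRUE))
})

test_that("an ohmic cell shows unity sag and zero rebound slope", {
  rc <- MembraneParams(gL = 10, C = 150)  # 100 MOhm
  currents <- seq(-150, 50, by = 20)
  V <- stepSweeps(rc, currents)
  m <- subthresholdStepMetrics(currents, V, dt = 0.1)
  expect_equal(m$RinMax, 100, tolerance = 0.01)
  expect_equal(m$RinSteady, 100, tolerance = 0.01)
  expect_equal(m$sag, 1, tolerance = 1e-3)
  expect_equal(m$reboundSlope, 0, tolerance = 1e-3)

  # doubling all currents leaves the resistances unchanged (linearity)
  V2 <- stepSweeps(rc, 2 * currents)
  m2 <- subthresholdStepMetrics(2 * currents, V2, dt = 0.1,
                                linearMaxPA = -20)
  expect_equal(m2$RinMax, m$RinMax, tolerance = 0.01)
  expect_equal(m2$RinSteady, m$RinSteady, tolerance = 0.01)
})

test_that("a slow-feedback membrane shows sag > 1 and negative rebound slope", {
  hcn <- MembraneParams(gL = 10, C = 150, g1 = 30, tauW = 60)
  currents <- seq(-150, 50, by = 20)
  V <- stepSweeps(hcn, currents)
  m <- subthresholdStepMetrics(currents, V, dt = 0.1)
  expect_gt(m$sag, 1)
  expect_gt(m$RinMax, m$RinSteady)
  expect_equal(m$RinSteady, 25, tolerance = 0.01)  # 1/(gL+g1)
  expect_lt(m$reboundSlope, 0)
})

test_that("spike metrics follow the stated rules on constructed trains", {
  dt <- 0.05
  n <- round(1000 / dt)
  sub <- rep(-70, n)
  two <- spikeSweep(c(100, 150))
  # ISIs 50,60,70 then 80s: ten spikes, SFA = 60/80
  tTen <- cumsum(c(100, 50, 60, 70, 80, 80, 80, 80, 80, 80))
  ten <- spikeSweep(tTen)
  m <- suprathresholdMetrics(c(50, 100, 150), cbind(sub, two, ten), dt)
  expect_equal(m$rheobase, 100)
  expect_equal(m$firstISI, 50, tolerance = 0.1)
  expect_equal(m$SFA, 60 / 80, tolerance = 0.01)
  expect_equal(unname(m$spikeCounts), c(0, 2, 10))

  # subthreshold-only protocol: rheobase undefined
  m0 <- suprathresholdMetrics(c(50, 100), cbind(sub, sub), dt)
  expect_true(is.na(m0$rheobase))
  expect_true(is.na(m0$SFA))
})

test_that("AP threshold is the first 20 V/s crossing", {
  dt <- 0.05
  # piecewise-linear rise: 5 V/s from -70 to -42, then 240 V/s to +30,
  # falling at 120 V/s; slopes chosen to hit sample boundaries exactly
  slow <- seq(-70, -42, by = 5 * dt)
  fast <- seq(-42, 30, by = 240 * dt)
  fall <- seq(30, -66, by = -120 * dt)
  v <- c(rep(-70, 200), slow, fast[-1], fall[-1], rep(-70, 2000))
  m <- suprathresholdMetrics(100, matrix(v, ncol = 1), dt)
  expect_lt(abs(m$apThreshold - (-42)), 0.5)
  expect_equal(m$maxDvdt, 240, tolerance = 2)
  expect_equal(m$minDvdt, -120, tolerance = 2)
  # half level is (-42 + 30)/2 = -6 mV: crossed 0.15 ms before the
  # peak on the rise and 0.30 ms after it on the fall
  expect_equal(m$halfWidth, 0.45, tolerance = 0.02)
})
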