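fgBench <- seq(100, 5000, by = 2)
wallLossless <- wallModel(0, fixAir)
wallDefault <- wallModel(0.02, fixAir)

test_that("lossless uniform-tube peaks match the transcendental modes", {
  tf <- simulateTF(fixTubeArea, list(), wallLossless, fgBench,
                   flangeWidthMm = 2, radiation = "reactive")
  pk <- findFormants(tf, prominenceDb = 3)
  modes <- transcendentalModes(fixTube, fixAir, 5000)
  expect_identical(nrow(pk), length(modes))
  expect_lt(max(abs(pk$freqHz - modes) / modes), 0.01)
})

test_that("grid refinement leaves peak frequencies stable", {
  tf1 <- simulateTF(fixTubeArea, list(), wallDefault, fgBench,
                    flangeWidthMm = 2, dx = 2.8)
  tf2 <- simulateTF(fixTubeArea, list(), wallDefault, fgBench,
                    flangeWidthMm = 2, dx = 1.4)
  f1 <- findFormants(tf1, 3)$freqHz
  f2 <- findFormants(tf2, 3)$freqHz
  expect_identical(length(f1), length(f2))
  expect_lt(max(abs(f1 - f2) / f1), 0.002)
  expect_error(simulateTF(fixTubeArea, list(), wallDefault, fgBench,
                          dx = 30), "element")
})

test_that("wall absorption damps peaks without moving them", {
  tf0 <- simulateTF(fixTubeArea, list(), wallLossless, fgBench,
                    flangeWidthMm = 2)
  tf5 <- simulateTF(fixTubeArea, list(),
                    wallModel(0.05, fixAir), fgBench, flangeWidthMm = 2)
  p0 <- findFormants(tf0, 3)
  p5 <- findFormants(tf5, 3)
  expect_identical(nrow(p0), nrow(p5))
  expect_true(all(p5$magDb < p0$magDb))
  expect_lt(max(abs(p5$freqHz - p0$freqHz) / p0$freqHz), 0.01)
})

test_that("a closed side branch carves a trough at its quarter-wave frequency", {
  fg <- seq(100, 8000, by = 2)
  branch <- sideBranch(attachX = 25, length = 19, area = 180)
  tfWith <- simulateTF(fixTubeArea, list(branch), wallDefault, fg,
                       flangeWidthMm = 2)
  tfWithout <- simulateTF(fixTubeArea, list(), wallDefault, fg,
                          flangeWidthMm = 2)
  # branch-free tract: no deep trough in the 3-6 kHz search region
  tr0 <- findTroughs(tfWithout, prominenceDb = 20)
  expect_length(tr0[tr0 >= 3000 & tr0 <= 6000], 0)

  pred <- fixAir@c / (4 * 0.019)
  tr <- findTroughs(tfWith, prominenceDb = 20)
  tr <- tr[tr >= 3000 & tr <= 6000]
  expect_gte(length(tr), 1)
  # deepest trough within +-5 % of the quarter-wave prediction
  m <- magnitudeDb(tfWith)
  deepest <- tr[which.min(vapply(tr, function(f)
    m[which.min(abs(fg - f))], numeric(1)))]
  expect_lt(abs(deepest - pred) / pred, 0.05)

  # longer sinus -> lower antiresonance
  deepIn <- function(len) {
    tfL <- simulateTF(fixTubeArea,
                      list(sideBranch(25, len, 180)), wallDefault, fg,
                      flangeWidthMm = 2)
    trL <- findTroughs(tfL, prominenceDb = 20)
    trL <- trL[trL >= 2500 & trL <= 6500]
    mL <- magnitudeDb(tfL)
    trL[which.min(vapply(trL, function(f)
      mL[which.min(abs(fg - f))], numeric(1)))]
  }
  expect_true(deepIn(17) > deepIn(19) && deepIn(19) > deepIn(21))

  # two unequal branches give two resolvable troughs
  tf2 <- simulateTF(fixTubeArea,
                    list(sideBranch(25, 19, 180),
                         sideBranch(30, 25, 180)),
                    wallDefault, fg, flangeWidthMm = 2)
  tr2 <- findTroughs(tf2, prominenceDb = 20)
  expect_gte(sum(tr2 >= 2500 & tr2 <= 6000), 2)
})

test_that("side branches act as formant repellents around the antiresonance", {
  fg <- seq(100, 8000, by = 2)
  branch <- sideBranch(25, 19, 180)
  tfWith <- simulateTF(fixTubeArea, list(branch), wallDefault, fg,
                       flangeWidthMm = 2)
  tfWithout <- simulateTF(fixTubeArea, list(), wallDefault, fg,
                          flangeWidthMm = 2)
  fA <- fixAir@c / (4 * 0.019)
  rep <- repulsionAnalysis(tfWith, tfWithout, fA)
  expect_true(all(rep$signConsistent))
  expect_true(any(rep$side == "below") && any(rep$side == "above"))
  # a nonzero effect on both sides of the antiresonance
  expect_lt(min(rep$shiftHz[rep$side == "below"]), 0)
  expect_gt(max(rep$shiftHz[rep$side == "above"]), 0)

  same <- repulsionAnalysis(tfWith, tfWith, fA)
  expect_true(all(same$shiftHz == 0))
})

test_that("formant and trough pickers handle degenerate spectra", {
  f <- seq(100, 4000, by = 10)
  bump <- new("TransferFunction", freq = f,
              values = -10 + 20 * exp(-((f - 1200) / 150)^2),
              meta = list(type = "magnitude_db"))
  pk <- findFormants(bump, 3)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$freqHz, 1200)
  expect_identical(pk$label, "F1")

  flatTop <- bump
  v <- as.numeric(bump@values)
  i <- which.max(v)
  v[i + 1] <- v[i]               # plateau: peaks merge with a warning
  flatTop@values <- v
  expect_warning(pkM <- findFormants(flatTop, 3), "merged")
  expect_identical(nrow(pkM), 1L)

  expect_length(findTroughs(bump, 3), 0)
})

test_that("the fossae-removal filter cancels the branch signature", {
  fg <- seq(50, 10000, by = 10)
  branch <- sideBranch(25, 19, 180)
  tfWith <- simulateTF(fixTubeArea, list(branch), wallDefault, fg,
                       flangeWidthMm = 2)
  tfWithout <- simulateTF(fixTubeArea, list(), wallDefault, fg,
                          flangeWidthMm = 2)
  fs <- 22050
  filt <- fossaeRemovalFilter(tfWith, tfWithout, fs)
  expect_s4_class(filt, "SpectralFilter")

  # identical spectra -> flat 0 dB filter, audio passes unchanged
  flat <- fossaeRemovalFilter(tfWith, tfWith, fs)
  set.seed(5)
  audio <- sampledSignal(rnorm(8192), fs)
  out <- applyFilter(audio, flat)
  expect_lt(max(abs(samples(out) - samples(audio))) /
              max(abs(samples(audio))), 1e-6)

  # a voice sung through the branch tract, filtered, matches the
  # branch-free voice at its harmonics in the trough region
  rigWith <- rigSpec(tractIr = tfWith, noiseSnrDb = Inf, seed = 9,
                     fs = fs, tractTaps = 2048)
  rigWithout <- rigSpec(tractIr = tfWithout, noiseSnrDb = Inf, seed = 9,
                        fs = fs, tractTaps = 2048)
  vWith <- makeVoiceFixture(103.8, rigWith, duration = 1)
  vWithout <- makeVoiceFixture(103.8, rigWithout, duration = 1)
  vFilt <- applyFilter(vWith, filt)
  spec <- function(sig) {
    n <- length(samples(sig))
    Mod(fft(samples(sig) * 0.5 * (1 - cos(2 * pi * seq_len(n) / n))))
  }
  sF <- spec(vFilt); sW <- spec(vWithout)
  n <- length(samples(vFilt))
  harmonics <- seq(103.8, fs / 2 - 200, by = 103.8)
  harmonics <- harmonics[harmonics >= 3500 & harmonics <= 5500]
  hb <- vapply(harmonics, function(f) {
    i0 <- round(f * n / fs) + 1
    reg <- (i0 - 3):(i0 + 3)
    20 * log10(max(sF[reg]) / max(sW[reg]))
  }, numeric(1))
  expect_lt(max(abs(hb)), 1)

  # applying the filter and then its inverse restores the audio
  inv <- fossaeRemovalFilter(tfWithout, tfWith, fs)
  voiceBack <- applyFilter(applyFilter(vWith, filt), inv)
  core <- round(0.1 * n):round(0.9 * n)
  err <- samples(voiceBack)[core] - samples(vWith)[core]
  expect_lt(20 * log10(sqrt(sum(err^2) / sum(samples(vWith)[core]^2))),
            -60)
})
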