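test_that("frequency-domain convolution matches direct convolution", {
  set.seed(3)
  a <- rnorm(200)
  b <- rnorm(55)
  direct <- as.numeric(convolve(a, rev(b), type = "open"))
  expect_lt(max(abs(sweeptract:::fftConvolve(a, b) - direct)) /
              max(abs(direct)), 1e-9)
})

test_that("identity system puts a single dominant lobe at lag T", {
  tl <- deconvolveTimeline(fixEss, fixInv)
  expect_equal(tl@tLinear, (length(samples(fixInv)) - 1) / fixSpec@fs)
  x <- samples(tl)
  pk <- which.max(abs(x))
  expect_lt(abs((pk - 1) / tl@fs - fixSpec@duration), 2 / tl@fs)
  # extracted LIR holds essentially all energy near the linear lag
  ir <- extractIR(tl, fixSpec, order = 1)
  near <- round((tl@tLinear + c(-0.005, 0.005)) * tl@fs) + 1
  eNear <- sum(x[near[1]:near[2]]^2)
  expect_gte(sum(samples(ir)^2) / eNear, 0.99)
})

test_that("a known 200-tap filter is recovered from its sweep response", {
  h <- as.numeric(signal::fir1(199, c(300, 5000) / (fixSpec@fs / 2),
                               type = "pass"))
  rec <- sampledSignal(sweeptract:::fftConvolve(samples(fixEss), h),
                       fixSpec@fs)
  tl <- deconvolveTimeline(rec, fixInv)
  ir <- extractIR(tl, fixSpec, order = 1)
  tf <- irToSpectrum(ir)
  want <- firMagnitudeDb(h, fixSpec@fs, freqHz(tf))
  band <- freqHz(tf) >= 400 & freqHz(tf) <= 4500
  got <- 20 * log10(sweeptract:::calibratedMagnitude(tf))
  expect_lt(max(abs(got[band] - want[band])), 0.5)
  # in-band relative L2 error of the linear magnitudes < 1 %
  gm <- sweeptract:::calibratedMagnitude(tf)[band]
  wm <- 10^(want[band] / 20)
  expect_lt(sqrt(sum((gm - wm)^2) / sum(wm^2)), 0.01)
})

test_that("harmonic lags follow T log(k)/log(f2/f1) and are located", {
  tl0 <- new("IrTimeline", samples = numeric(480), fs = 48,
             tLinear = 10)
  spec10 <- sweepSpec()   # T = 10 s, f2/f1 = 1000
  lg <- locateHarmonics(tl0, spec10, kMax = 4)
  expect_equal(lg$lagS[1], 10)
  expect_equal(10 - lg$lagS[2], 10 * log(2) / log(1000), tolerance = 1e-12)
  expect_equal(10 - lg$lagS[4], 2 * (10 - lg$lagS[2]), tolerance = 1e-12)

  # quadratic distortion creates a secondary response at the k = 2 lag
  y <- samples(fixEss) + 0.1 * samples(fixEss)^2
  tl <- deconvolveTimeline(sampledSignal(y, fixSpec@fs), fixInv)
  adv <- fixSpec@duration * log(2) / log(fixSpec@f2 / fixSpec@f1)
  x <- samples(tl)
  fs <- tl@fs
  i0 <- round((tl@tLinear - adv) * fs) + 1
  reg <- (i0 - round(0.05 * fs)):(i0 + round(0.05 * fs))
  i2 <- reg[which.max(abs(x[reg]))]
  expect_lt(abs((i2 - 1) / fs - (tl@tLinear - adv)), 0.002)

  # order-2 extraction captures >= 90 % of the distortion lobe's energy
  ir2 <- extractIR(tl, fixSpec, order = 2)
  lobe <- (i0 - round(0.01 * fs)):(i0 + round(0.01 * fs))
  expect_gte(sum(samples(ir2)^2) / sum(x[lobe]^2), 0.9)
  expect_identical(ir2@order, 2)
})

test_that("impulse-response spectra follow the power-of-two FFT algorithm", {
  ir <- new("ImpulseResponse", samples = c(1, rep(0, 299)), fs = 48000,
            order = 1, tStart = 0)
  tf <- irToSpectrum(ir)
  expect_equal(tf@meta$n, 512)
  expect_lt(diff(range(Mod(tfValues(tf)))), 1e-12)  # flat delta spectrum
  expect_equal(freqHz(tf), 48000 * (0:256) / 512)

  ir2 <- new("ImpulseResponse", samples = rnorm(1024), fs = 48000,
             order = 1, tStart = 0)
  expect_equal(irToSpectrum(ir2)@meta$n, 1024)

  # Parseval with the plain DFT convention, after undoing normalisation
  x <- samples(ir2) / max(abs(samples(ir2)))
  tf2 <- irToSpectrum(ir2)
  v <- tfValues(tf2)
  n <- tf2@meta$n
  eFreq <- (Mod(v[1])^2 + Mod(v[n / 2 + 1])^2 +
              2 * sum(Mod(v[2:(n / 2)])^2)) / n
  expect_lt(abs(eFreq / sum(x^2) - 1), 1e-9)

  expect_error(irToSpectrum(new("ImpulseResponse", samples = numeric(5),
                                fs = 48000, order = 1, tStart = 0)),
               "zero")
})

test_that("complex averaging cancels noise like 1/sqrt(n)", {
  tfs <- replicate(3, irToSpectrum(new("ImpulseResponse",
                                       samples = c(1, 0.5, 0.2, rep(0, 61)),
                                       fs = 48000, order = 1,
                                       tStart = 0)), simplify = FALSE)
  avg <- complexAverage(tfs)
  expect_equal(tfValues(avg),
               tfValues(tfs[[1]]) * tfs[[1]]@meta$scale)
  neg <- tfs[[1]]
  neg@values <- -neg@values
  z <- complexAverage(list(tfs[[1]], neg))
  expect_lt(max(Mod(tfValues(z))), 1e-12)

  # three noisy rig repeats vs the noiseless spectrum
  rigN <- rigSpec(driverIr = fixRigA@driverIr,
                  distortionCoeffs = c(1, 0.05),
                  tractIr = fixTract, noiseSnrDb = 40, seed = 77,
                  fs = 48000)
  rig0 <- rigSpec(driverIr = fixRigA@driverIr,
                  distortionCoeffs = c(1, 0.05),
                  tractIr = fixTract, noiseSnrDb = Inf, seed = 77,
                  fs = 48000)
  lir <- function(rig, r) {
    tl <- deconvolveTimeline(simulateMeasurement(fixEss, rig, TRUE, r),
                             fixInv)
    irToSpectrum(extractIR(tl, fixSpec, order = 1, window =
                             tl@tLinear + c(0, 0.02)))
  }
  ref <- lir(rig0, 1)
  reps <- lapply(1:3, function(r) lir(rigN, r))
  band <- freqHz(ref) >= 200 & freqHz(ref) <= 9000
  dbErr <- function(tf) {
    d <- 20 * log10(sweeptract:::calibratedMagnitude(tf)[band] /
                      sweeptract:::calibratedMagnitude(ref)[band])
    sqrt(mean(d^2))
  }
  ratio <- dbErr(reps[[1]]) / dbErr(complexAverage(reps))
  expect_gte(ratio, 1.6)
  expect_lte(ratio, 2.0)

  bad <- irToSpectrum(new("ImpulseResponse", samples = c(1, 0, 0),
                          fs = 24000, order = 1, tStart = 0))
  expect_error(complexAverage(list(tfs[[1]], bad)), "grid")
})

test_that("dB subtraction removes the driver and is gain invariant", {
  tf <- irToSpectrum(new("ImpulseResponse",
                         samples = c(1, -0.4, 0.2, rep(0, 60)),
                         fs = 48000, order = 1, tStart = 0))
  z <- subtractReference(tf, tf)
  expect_true(all(abs(tfValues(z)) < 1e-12))
  expect_identical(z@meta$type, "magnitude_db")
  # doubling the driver gain scales both measurements and cancels in dB
  drv <- irToSpectrum(new("ImpulseResponse",
                          samples = c(0.8, 0.1, rep(0, 62)),
                          fs = 48000, order = 1, tStart = 0))
  sys2 <- tf; sys2@values <- 2 * sys2@values
  drv2 <- drv; drv2@values <- 2 * drv2@values
  expect_equal(tfValues(subtractReference(sys2, drv2)),
               tfValues(subtractReference(tf, drv)), tolerance = 1e-9)

  # known tract through the full measure -> subtract pipeline
  tfMeas <- measureRig(fixRigA)
  want <- firMagnitudeDb(fixTract, 48000, freqHz(tfMeas))
  band <- freqHz(tfMeas) >= 100 & freqHz(tfMeas) <= 10000
  expect_lt(max(abs(tfValues(tfMeas)[band] - want[band])), 0.5)
})
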