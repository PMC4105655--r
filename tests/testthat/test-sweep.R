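test_that("instantaneous frequency follows the exponential law and is monotone", {
  fs <- fixSpec@fs
  x <- samples(fixEssPlain)
  n <- length(x)
  # analytic-signal phase derivative as an oracle for instantaneous freq
  X <- fft(x)
  X[(n %/% 2 + 2):n] <- 0
  X[2:(n %/% 2)] <- 2 * X[2:(n %/% 2)]
  z <- fft(X, inverse = TRUE) / n
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi
  finst <- dph * fs / (2 * pi)
  t <- (seq_len(n - 1) - 0.5) / fs
  # monotone over the whole sweep; quantitative check away from the
  # low-frequency end, where the analytic-signal estimate is biased by
  # the few cycles elapsed
  probe <- round(seq(0.05, 1.95, by = 0.05) * fs)
  fMeas <- vapply(probe, function(i) mean(finst[(i - 20):(i + 20)]),
                  numeric(1))
  expect_true(all(diff(fMeas) > 0))
  probe <- round(seq(0.75, 1.95, by = 0.05) * fs)
  fMeas <- vapply(probe, function(i) mean(finst[(i - 200):(i + 200)]),
                  numeric(1))
  fLaw <- fixSpec@f1 * (fixSpec@f2 / fixSpec@f1)^(t[probe] / 2)
  expect_lt(max(abs(fMeas / fLaw - 1)), 1e-3)
  # start frequency from the first samples (phase ~ asin of amplitude)
  f0 <- (asin(x[3]) - asin(x[2])) * fs / (2 * pi)
  expect_lt(abs(f0 / fixSpec@f1 - 1), 1e-3)
})

test_that("sweep has the expected length and -3 dB/octave spectral slope", {
  expect_identical(length(samples(fixEssPlain)), 96000L)
  x <- samples(fixEssPlain)
  n <- length(x)
  P <- Mod(fft(x))^2
  fr <- fixSpec@fs * (seq_len(n) - 1) / n
  # average the periodogram in octave-spaced bands over [100, 10000] Hz
  edges <- 2^seq(log2(100), log2(10000), by = 0.5)
  lev <- fc <- numeric(length(edges) - 1)
  for (i in seq_along(lev)) {
    sel <- fr >= edges[i] & fr < edges[i + 1]
    lev[i] <- 10 * log10(mean(P[sel]))
    fc[i] <- sqrt(edges[i] * edges[i + 1])
  }
  slope <- coef(lm(lev ~ log2(fc)))[2]
  expect_lt(abs(slope - (-3)), 0.3)
})

test_that("fade envelopes are exact at their endpoints and local in support", {
  env <- fadeEnvelope(fixSpec, "in")
  expect_s4_class(env, "EnvelopeParams")   # validity enforces endpoints
  envO <- fadeEnvelope(fixSpec, "out")
  expect_true(validObject(envO))

  faded <- applyFadeIn(fixEssPlain, fixSpec)
  expect_identical(samples(faded)[1], 0)
  iAfter <- (round(env@tEnd * fixSpec@fs) + 2):length(samples(faded))
  expect_identical(samples(faded)[iAfter], samples(fixEssPlain)[iAfter])

  fadedO <- applyFadeOut(fixEssPlain, fixSpec)
  xo <- samples(fadedO)
  expect_identical(xo[length(xo)], 0)
  iBefore <- seq_len(round(envO@tStart * fixSpec@fs))
  expect_identical(xo[iBefore], samples(fixEssPlain)[iBefore])

  badSpec <- fixSpec
  expect_error(applyFadeIn(fixEssPlain, sweepSpec(f1 = 60, duration = 2,
                                                  fs = 48000)),
               "fEnvLo")
})

test_that("fades suppress pre- and post-ringing by at least 40 dB", {
  cvPlain <- samples(deconvolveTimeline(fixEssPlain, fixInvPlain))
  cvFaded <- samples(deconvolveTimeline(fixEss, fixInv))
  fs <- fixSpec@fs
  pk <- length(samples(fixInv))          # main lobe index (lag = T)
  margin <- round(0.1 * fs)              # exclude band-limited skirt
  preDrop <- 20 * log10(max(abs(cvPlain[1:(pk - margin)])) /
                          max(abs(cvFaded[1:(pk - margin)])))
  postDrop <- 20 * log10(max(abs(cvPlain[(pk + margin):length(cvPlain)])) /
                           max(abs(cvFaded[(pk + margin):length(cvFaded)])))
  expect_gte(preDrop, 40)
  expect_gte(postDrop, 40)
})

test_that("inverse filter modulation is unity where the sweep reaches f2", {
  n <- length(samples(fixEssPlain))
  fs <- fixSpec@fs
  scale <- 4 * fixSpec@f2 / ((2 / log(1000)) * fs^2)
  # first inverse sample corresponds to the last sweep sample (t ~ T)
  m1 <- samples(fixInvPlain)[1] / (samples(fixEssPlain)[n] * scale)
  expect_lt(abs(m1 - 1), 1e-3)
})

test_that("ess convolved with its inverse is a calibrated band-limited delta", {
  cv <- samples(deconvolveTimeline(fixEss, fixInv))
  fs <- fixSpec@fs
  pk <- which.max(abs(cv))
  expect_lt(abs((pk - 1) / fs - fixSpec@duration), 2 / fs)
  w <- round(0.001 * fs)
  expect_gte(sum(cv[(pk - w):(pk + w)]^2) / sum(cv^2), 0.95)
  nf <- 2^ceiling(log2(length(cv)))
  CV <- fft(c(cv, rep(0, nf - length(cv))))
  fr <- fs * (seq_len(nf) - 1) / nf
  band <- fr >= 2 * fixSpec@fEnvLo & fr <= fixSpec@fEnvHi / 2
  mg <- 20 * log10(Mod(CV[band]))
  expect_lt(max(abs(mg - mean(mg))), 0.5)
})

test_that("sweep spec validation names the violated bound", {
  expect_error(sweepSpec(f1 = -5), "f1")
  expect_error(sweepSpec(f2 = 1e6, fs = 48000), "Nyquist")
  expect_error(sweepSpec(duration = 0), "duration")
  expect_error(buildInverseFilter(sampledSignal(1:10, 48000), fixSpec),
               "length")
})
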