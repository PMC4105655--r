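# Shared fixtures, computed once per test run.  Desk-scale sweep:
# 20 Hz - 20 kHz in 2 s at 48 kHz (same band as the default spec, shorter
# and slower-rate so the suite stays fast).

fixSpec <- sweepSpec(duration = 2, fs = 48000)
fixAir <- airModel(5)

fixEssPlain <- generateESS(fixSpec)
fixEss <- applyFadeOut(applyFadeIn(fixEssPlain, fixSpec), fixSpec)
fixInv <- buildInverseFilter(fixEss, fixSpec)
fixInvPlain <- buildInverseFilter(fixEssPlain, fixSpec)

# formant-like test tract: smooth spectral shape with three peaks and a
# dip, ~0.25 peak linear gain so rig outputs keep headroom
makeFormantTract <- function(fs = 48000, taps = 512) {
  fg <- seq(0, fs / 2, length.out = 513)
  shape <- 6 * exp(-((fg - 500) / 300)^2) +
    8 * exp(-((fg - 1500) / 400)^2) +
    10 * exp(-((fg - 2600) / 500)^2) -
    8 * exp(-((fg - 4400) / 600)^2) - 12
  as.numeric(signal::fir2(taps, fg / (fs / 2), 10^(shape / 20)))
}
fixTract <- makeFormantTract()

# dB magnitude of an FIR on an arbitrary frequency grid (direct DFT)
firMagnitudeDb <- function(h, fs, freqs) {
  n <- seq_along(h) - 1
  mag <- vapply(freqs, function(f)
    Mod(sum(h * exp(-2i * pi * f * n / fs))), numeric(1))
  20 * log10(mag)
}

# two rigs sharing the tract but with different drivers and distortion
fixRigA <- rigSpec(driverIr = 0.4 * as.numeric(signal::fir1(64, 0.85)),
                   distortionCoeffs = c(1, 0.05, 0.02),
                   tractIr = fixTract, noiseSnrDb = 80, seed = 11,
                   fs = 48000)
fixRigB <- rigSpec(driverIr = 0.35 * as.numeric(
                     signal::fir2(96, c(0, 0.05, 0.5, 1),
                                  c(0.6, 1, 0.9, 0.4))),
                   distortionCoeffs = c(1, 0.1, -0.1, 0.03),
                   tractIr = fixTract, noiseSnrDb = 80, seed = 202,
                   fs = 48000)

measureRig <- function(rig, repeats = 3) {
  recs <- lapply(seq_len(repeats),
                 function(r) simulateMeasurement(fixEss, rig, TRUE, r))
  refs <- lapply(seq_len(repeats),
                 function(r) simulateMeasurement(fixEss, rig, FALSE,
                                                 r + 10))
  measureTransferFunction(recs, refs, fixInv, fixSpec)
}

# benchmark cylinder: 142 mm long, 15 mm radius, 2 mm flange
fixTube <- tubeSpec(142, 15, 2)
fixTubeArea <- areaFunction(c(0, 142), rep(pi * 15^2, 2))
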