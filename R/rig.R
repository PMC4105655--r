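#' Simulate one sweep measurement on the virtual rig
#'
#' Emulates the measurement chain: the sweep is convolved with the driver
#' impulse response, passed through the memoryless polynomial nonlinearity
#' `y = a1 x + a2 x^2 + ...` (the source of temporally separated harmonic
#' responses in the deconvolved timeline), optionally convolved with the
#' tract filter, and recorded with additive Gaussian microphone noise at
#' the rig's SNR.  The output is fully determined by `(seed, repIndex)`;
#' identical calls are bit-identical.  Output exceeding full scale is
#' rescaled to +-1 with a warning.
#'
#' @param ess the excitation sweep as a [SampledSignal-class].
#' @param rig a [RigSpec-class].
#' @param includeTract include the tract filter (`FALSE` measures the
#'   driver alone, the subtraction reference).
#' @param repIndex repeat index; each repeat draws independent noise.
#' @return the recording as a [SampledSignal-class].
#' @seealso [measureTransferFunction()]
#' @export
simulateMeasurement <- function(ess, rig, includeTract = TRUE,
                                repIndex = 1) {
  validObject(rig)
  if (ess@fs != rig@fs)
    stop("sweep rate (", ess@fs, ") differs from rig rate (", rig@fs, ")")
  x <- fftConvolve(ess@samples, rig@driverIr)
  y <- numeric(length(x))
  for (j in seq_along(rig@distortionCoeffs))
    if (rig@distortionCoeffs[j] != 0)
      y <- y + rig@distortionCoeffs[j] * x^j
  if (includeTract) y <- fftConvolve(y, rig@tractIr)
  if (is.finite(rig@noiseSnrDb)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed((rig@seed + 7919 * repIndex) %% .Machine$integer.max)
    y <- y + stats::rnorm(length(y), 0,
                          sqrt(mean(y^2)) * 10^(-rig@noiseSnrDb / 20))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  peak <- max(abs(y))
  if (peak > 1) {
    warning(sprintf("output clipped at %.3g x full scale; rescaled", peak))
    y <- y / peak
  }
  sampledSignal(y, rig@fs)
}

#' Synthesise a sung-voice fixture
#'
#' A harmonic glottal pulse train at fundamental `f0` filtered by the
#' rig's tract impulse response, with a seeded noise floor: a desk-scale
#' stand-in for a recorded sung vowel whose spectrum carries the tract's
#' formants and any side-branch trough.
#'
#' @param f0 fundamental frequency in Hz.
#' @param rig a [RigSpec-class] whose `tractIr` shapes the voice.
#' @param duration duration in seconds (> 0).
#' @param noiseFloorDb noise level in dB relative to the voice RMS.
#' @return a [SampledSignal-class].
#' @export
makeVoiceFixture <- function(f0, rig, duration = 1, noiseFloorDb = -80) {
  if (f0 <= 0) stop("f0 must be > 0")
  n <- round(duration * rig@fs)
  if (n < 1) stop("duration too short: empty signal")
  src <- numeric(n)
  pos <- round(seq(1, n, by = rig@fs / f0))
  pos <- pos[pos <= n]
  src[pos] <- 1
  y <- fftConvolve(src, rig@tractIr)[seq_len(n)]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed((rig@seed + 104729) %% .Machine$integer.max)
  y <- y + stats::rnorm(n, 0, sqrt(mean(y^2)) * 10^(noiseFloorDb / 20))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  sampledSignal(y, rig@fs)
}
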