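#' Generate an exponential sine sweep
#'
#' Synthesises `x(t) = A sin(2 pi f1 L (exp(t/L) - 1))` with
#' `L = duration / log(f2/f1)`, whose instantaneous frequency rises
#' exponentially from `f1` at t = 0 to `f2` at t = `duration`.  The power
#' spectral density of this signal falls at -3 dB per octave, because the
#' sweep spends time inversely proportional to frequency in each octave.
#'
#' @param spec a [SweepSpec-class].
#' @return a [SampledSignal-class] of `round(duration * fs)` samples.
#' @examples
#' ess <- generateESS(sweepSpec(duration = 0.5, fs = 8000, fEnvHi = 3500,
#'                              f2 = 4000))
#' @seealso [applyFadeIn()], [applyFadeOut()], [buildInverseFilter()]
#' @export
generateESS <- function(spec) {
  validObject(spec)
  n <- round(spec@duration * spec@fs)
  t <- (seq_len(n) - 1) / spec@fs
  L <- sweepRate(spec)
  phase <- 2 * pi * spec@f1 * L * (exp(t / L) - 1)
  sampledSignal(spec@amplitude * sin(phase), spec@fs)
}

# exponential time constant of the sweep, in seconds
sweepRate <- function(spec) spec@duration / log(spec@f2 / spec@f1)

#' Instantaneous frequency of the sweep at time t
#' @param spec a [SweepSpec-class].
#' @param t time in seconds (vectorised).
#' @return frequency in Hz: `f1 * (f2/f1)^(t/duration)`.
#' @export
instantaneousFrequency <- function(spec, t) {
  spec@f1 * exp(t / sweepRate(spec))
}

#' Time at which the sweep reaches a given instantaneous frequency
#' @param spec a [SweepSpec-class].
#' @param f frequency in Hz (vectorised), within `[f1, f2]`.
#' @return time in seconds: `L * log(f/f1)`.
#' @export
timeAtFrequency <- function(spec, f) {
  sweepRate(spec) * log(f / spec@f1)
}

#' Fade envelope parameters
#'
#' Solve the sine-squared envelope `sin(a t + b)^2` in closed form.  The
#' fade-in rises from exactly 0 at t = 0 to 1 at the last sampled time not
#' later than the moment the sweep reaches `fEnvLo` (one quarter period);
#' the fade-out is at 1 at the first sampled time not earlier than the
#' moment the sweep reaches `fEnvHi` and decays to exactly 0 at the last
#' sample.
#'
#' @param spec a [SweepSpec-class].
#' @param type `"in"` or `"out"`.
#' @return an [EnvelopeParams-class].
#' @export
fadeEnvelope <- function(spec, type = c("in", "out")) {
  type <- match.arg(type)
  fs <- spec@fs
  n <- round(spec@duration * fs)
  if (type == "in") {
    t1 <- timeAtFrequency(spec, spec@fEnvLo)
    n1 <- floor(t1 * fs)          # max sampled time <= t1
    if (n1 < 1) stop("fade-in support shorter than one sample; ",
                     "fEnvLo is too close to f1")
    t1s <- n1 / fs
    new("EnvelopeParams", a = pi / (2 * t1s), b = 0, tStart = 0,
        tEnd = t1s, type = "in")
  } else {
    t2 <- timeAtFrequency(spec, spec@fEnvHi)
    n2 <- ceiling(t2 * fs)        # min sampled time >= t2
    tl <- (n - 1) / fs            # last sampled time
    if (n2 >= n - 1) stop("fade-out support shorter than one sample; ",
                          "fEnvHi is too close to f2")
    t2s <- n2 / fs
    a <- pi / (2 * (tl - t2s))
    new("EnvelopeParams", a = a, b = pi / 2 - a * t2s, tStart = t2s,
        tEnd = tl, type = "out")
  }
}

#' Apply the sine-squared fade-in to a sweep
#'
#' Samples up to the time where the instantaneous frequency equals
#' `fEnvLo` (snapped to the sample grid) are multiplied by a quarter-period
#' sine-squared ramp which is exactly 0 at the first sample; all later
#' samples are returned unchanged.  Together with [applyFadeOut()] this
#' suppresses the broadband "pre-ringing" burst that an abrupt sweep start
#' leaves in the deconvolved timeline.
#'
#' @param sig the sweep as a [SampledSignal-class].
#' @param spec the [SweepSpec-class] that generated it.
#' @return a faded [SampledSignal-class].
#' @export
applyFadeIn <- function(sig, spec) {
  if (spec@fEnvLo <= spec@f1 || spec@fEnvLo >= spec@f2)
    stop("fEnvLo must lie strictly inside (f1, f2)")
  env <- fadeEnvelope(spec, "in")
  fs <- sig@fs
  i <- seq_len(round(env@tEnd * fs) + 1)
  t <- (i - 1) / fs
  x <- sig@samples
  x[i] <- x[i] * sin(env@a * t + env@b)^2
  x[1] <- 0   # exact zero start
  sampledSignal(x, fs, sig@t0)
}

#' Apply the sine-squared fade-out to a sweep
#'
#' Mirror of [applyFadeIn()]: samples from the time where the
#' instantaneous frequency equals `fEnvHi` are multiplied by a
#' quarter-period sine-squared decay reaching exactly 0 at the last
#' sample; earlier samples are unchanged.  Suppresses the "post-ringing"
#' burst caused by the abrupt sweep end.
#'
#' @inheritParams applyFadeIn
#' @return a faded [SampledSignal-class].
#' @export
applyFadeOut <- function(sig, spec) {
  if (spec@fEnvHi <= spec@f1 || spec@fEnvHi >= spec@f2)
    stop("fEnvHi must lie strictly inside (f1, f2)")
  env <- fadeEnvelope(spec, "out")
  fs <- sig@fs
  n <- length(sig@samples)
  i <- (round(env@tStart * fs) + 1):n
  t <- (i - 1) / fs
  x <- sig@samples
  x[i] <- x[i] * sin(env@a * t + env@b)^2
  x[n] <- 0   # exact zero end
  sampledSignal(x, fs, sig@t0)
}

#' Build the amplitude-modulated inverse filter of a sweep
#'
#' The sweep is time-reversed and post-modulated: the time-reversed sweep
#' still falls at -3 dB/octave, so its amplitude is modulated with the
#' exponential envelope `f_inst(t) / f2` (equal to 1 where the
#' instantaneous frequency reaches `f2`, i.e. at t = duration) so that the
#' inverse filter rises at +3 dB/octave and the convolution
#' `ess (*) inverse` approximates a band-limited unit impulse at lag
#' `duration`.  An analytic amplitude calibration `4 f2 / (L fs^2)` makes
#' the in-band magnitude of that convolution unity (0 dB), so deconvolved
#' impulse responses come out in the units of the system under test.
#'
#' @param ess the (possibly faded) sweep as a [SampledSignal-class].
#' @param spec the [SweepSpec-class] that generated it.
#' @return the inverse filter as a [SampledSignal-class].
#' @seealso [deconvolveTimeline()]
#' @export
buildInverseFilter <- function(ess, spec) {
  n <- round(spec@duration * spec@fs)
  if (length(ess@samples) != n)
    stop("sweep length (", length(ess@samples),
         ") does not match spec length (", n, ")")
  t <- (seq_len(n) - 1) / spec@fs
  L <- sweepRate(spec)
  modulation <- instantaneousFrequency(spec, t) / spec@f2
  scale <- 4 * spec@f2 / (L * spec@fs^2)
  sampledSignal(rev(ess@samples * modulation) * scale, spec@fs)
}
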