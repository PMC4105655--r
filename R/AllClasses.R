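#' @import methods
NULL

setClassUnion("numericOrComplex", c("numeric", "complex"))

#' Exponential sine sweep specification
#'
#' Parameters of an exponential sine sweep (ESS) and of its sine-squared
#' fade envelopes.  The instantaneous frequency of the sweep rises
#' exponentially from `f1` at t = 0 to `f2` at t = `duration`; the fade-in
#' ramps the amplitude from zero up to full scale while the sweep traverses
#' `[f1, fEnvLo]`, and the fade-out brings it back to zero over
#' `[fEnvHi, f2]`.
#'
#' @slot f1 start frequency in Hz.
#' @slot f2 end frequency in Hz (at most the Nyquist frequency).
#' @slot duration sweep duration in seconds.
#' @slot fs sampling rate in Hz.
#' @slot fEnvLo frequency in Hz at which the fade-in envelope reaches 1.
#' @slot fEnvHi frequency in Hz at which the fade-out envelope leaves 1.
#' @slot amplitude peak linear amplitude of the sweep.
#' @seealso [sweepSpec()], [generateESS()]
#' @export
setClass("SweepSpec",
  representation(f1 = "numeric", f2 = "numeric", duration = "numeric",
                 fs = "numeric", fEnvLo = "numeric", fEnvHi = "numeric",
                 amplitude = "numeric"))

setValidity("SweepSpec", function(object) {
  msg <- character()
  if (object@f1 <= 0) msg <- c(msg, "f1 must satisfy f1 > 0")
  if (object@fEnvLo <= object@f1)
    msg <- c(msg, "fEnvLo must satisfy fEnvLo > f1")
  if (object@fEnvHi <= object@fEnvLo)
    msg <- c(msg, "fEnvHi must satisfy fEnvHi > fEnvLo")
  if (object@f2 <= object@fEnvHi)
    msg <- c(msg, "f2 must satisfy f2 > fEnvHi")
  if (object@f2 > object@fs / 2)
    msg <- c(msg, "f2 must satisfy f2 <= fs/2 (Nyquist)")
  if (object@duration <= 0) msg <- c(msg, "duration must satisfy duration > 0")
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be positive")
  if (length(msg)) msg else TRUE
})

#' Uniformly sampled waveform
#'
#' A real-valued signal on a uniform time grid, the basic audio container
#' of the package (sweeps, inverse filters, recordings, rig outputs).
#'
#' @slot samples numeric vector of sample values (finite).
#' @slot fs sampling rate in Hz.
#' @slot t0 start-time offset in seconds of the first sample.
#' @seealso [sampledSignal()], [readWav()], [writeWav()]
#' @export
setClass("SampledSignal",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric"))

setValidity("SampledSignal", function(object) {
  msg <- character()
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Sine-squared fade envelope parameters
#'
#' The envelope is sin(a t + b)^2 on the support `[tStart, tEnd]`.  A
#' fade-in rises from exactly 0 at `tStart` to 1 at `tEnd` within a
#' quarter period; a fade-out mirrors this.  Validity enforces those
#' endpoint values to 1e-9.
#'
#' @slot a angular-rate parameter in rad/s.
#' @slot b phase parameter in rad.
#' @slot tStart,tEnd envelope support in seconds.
#' @slot type `"in"` or `"out"`.
#' @export
setClass("EnvelopeParams",
  representation(a = "numeric", b = "numeric", tStart = "numeric",
                 tEnd = "numeric", type = "character"))

setValidity("EnvelopeParams", function(object) {
  env <- function(t) sin(object@a * t + object@b)^2
  lo <- env(object@tStart); hi <- env(object@tEnd)
  want <- if (object@type == "in") c(0, 1) else c(1, 0)
  if (!object@type %in% c("in", "out"))
    return("type must be 'in' or 'out'")
  if (abs(lo - want[1]) > 1e-9 || abs(hi - want[2]) > 1e-9)
    return(sprintf(
      "envelope endpoints are (%.3g, %.3g), expected (%g, %g) within 1e-9",
      lo, hi, want[1], want[2]))
  TRUE
})

#' Deconvolved impulse-response timeline
#'
#' Full linear convolution of a recording with the ESS inverse filter.
#' The linear impulse response sits at lag `tLinear` (the sweep duration);
#' harmonic-distortion responses of order k are packed earlier, advanced
#' by `duration * log(k) / log(f2/f1)`.
#'
#' @slot samples the deconvolved timeline.
#' @slot fs sampling rate in Hz.
#' @slot tLinear lag in seconds of the linear response.
#' @seealso [deconvolveTimeline()], [locateHarmonics()], [extractIR()]
#' @export
setClass("IrTimeline",
  representation(samples = "numeric", fs = "numeric", tLinear = "numeric"))

setValidity("IrTimeline", function(object) {
  dur <- length(object@samples) / object@fs
  if (object@tLinear < 0 || object@tLinear > dur)
    return("tLinear must lie within [0, duration] of the timeline")
  TRUE
})

#' Windowed impulse response
#'
#' @slot samples windowed real samples.
#' @slot fs sampling rate in Hz.
#' @slot order harmonic order (1 = linear impulse response).
#' @slot tStart timeline lag in seconds of the first sample.
#' @export
setClass("ImpulseResponse",
  representation(samples = "numeric", fs = "numeric", order = "numeric",
                 tStart = "numeric"))

setValidity("ImpulseResponse", function(object) {
  msg <- character()
  if (object@order < 1) msg <- c(msg, "order must be >= 1")
  if (!length(object@samples)) msg <- c(msg, "samples must be nonempty")
  if (length(msg)) msg else TRUE
})

#' Acoustic transfer function on a frequency grid
#'
#' Either a complex spectrum (e.g. the FFT of an impulse response) or a
#' real magnitude curve in dB (e.g. after driver-reference subtraction).
#' `meta` carries provenance: a label, the normalisation scale removed in
#' [irToSpectrum()], and `type` (`"complex"` or `"magnitude_db"`).
#'
#' @slot freq strictly increasing frequency grid in Hz.
#' @slot values complex spectrum or numeric dB magnitudes, same length as
#'   `freq`.
#' @slot meta named list of provenance fields.
#' @seealso [irToSpectrum()], [subtractReference()], [simulateTF()]
#' @export
setClass("TransferFunction",
  representation(freq = "numeric", values = "numericOrComplex",
                 meta = "list"))

setValidity("TransferFunction", function(object) {
  msg <- character()
  if (length(object@freq) != length(object@values))
    msg <- c(msg, "freq and values must have equal length")
  if (length(object@freq) > 1 && any(diff(object@freq) <= 0))
    msg <- c(msg, "freq must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Cylindrical tube geometry
#'
#' @slot length physical length in mm.
#' @slot radius inner radius in mm.
#' @slot flange flange width in mm (may be `Inf`).
#' @slot area cross-section area in mm^2 (pi * radius^2 for a cylinder,
#'   enforced to 0.1 %).
#' @seealso [tubeSpec()], [transcendentalModes()], [endCorrection()]
#' @export
setClass("TubeSpec",
  representation(length = "numeric", radius = "numeric", flange = "numeric",
                 area = "numeric"))

setValidity("TubeSpec", function(object) {
  msg <- character()
  if (object@length <= 0) msg <- c(msg, "length must be > 0")
  if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
  if (object@flange <= 0) msg <- c(msg, "flange must be > 0")
  if (object@area <= 0) msg <- c(msg, "area must be > 0")
  if (abs(object@area - pi * object@radius^2) > 1e-3 * pi * object@radius^2)
    msg <- c(msg, "area must equal pi*radius^2 within 0.1% for a cylinder")
  if (length(msg)) msg else TRUE
})

#' Piriform fossa geometry
#'
#' Length and volume measurements of the piriform sinuses of one subject
#' and vowel, the inputs of the quarter-wave antiresonance predictor.
#'
#' @slot lengthMm sinus length in mm.
#' @slot pv piriform fossa volume in cm^3.
#' @slot vtv vocal-tract volume in cm^3 (must exceed `pv`).
#' @slot label subject/vowel tag.
#' @seealso [piriformAntiresonance()], [antiresonanceSummary()],
#'   [piriformGeometries()]
#' @export
setClass("PiriformGeometry",
  representation(lengthMm = "numeric", pv = "numeric", vtv = "numeric",
                 label = "character"))

setValidity("PiriformGeometry", function(object) {
  msg <- character()
  if (object@lengthMm <= 0) msg <- c(msg, "lengthMm must be > 0")
  if (object@pv <= 0) msg <- c(msg, "pv must be > 0")
  if (object@pv >= object@vtv) msg <- c(msg, "pv must satisfy 0 < pv < vtv")
  if (length(msg)) msg else TRUE
})

#' Air properties
#'
#' Speed of sound and density; `c` is recomputed from the temperature with
#' [speedOfSound()] unless overridden.
#'
#' @slot temperatureC air temperature in degrees Celsius.
#' @slot c speed of sound in m/s.
#' @slot rho air density in kg/m^3.
#' @export
setClass("AirModel",
  representation(temperatureC = "numeric", c = "numeric", rho = "numeric"))

setValidity("AirModel", function(object) {
  if (object@c <= 0) return("c must be > 0")
  if (object@rho <= 0) return("rho must be > 0")
  TRUE
})

#' Vocal-tract area function
#'
#' Cross-section area versus distance from the glottis, the input of the
#' 1-D plane-wave simulator.
#'
#' @slot x positions from the glottis in mm, strictly increasing, >= 2
#'   points.
#' @slot area cross-section areas in mm^2, all positive.
#' @seealso [areaFunction()], [simulateTF()], [readAreaFunction()]
#' @export
setClass("AreaFunction",
  representation(x = "numeric", area = "numeric"))

setValidity("AreaFunction", function(object) {
  msg <- character()
  if (length(object@x) < 2) msg <- c(msg, "need >= 2 points")
  if (length(object@x) != length(object@area))
    msg <- c(msg, "x and area must have equal length")
  if (any(diff(object@x) <= 0)) msg <- c(msg, "x must be strictly increasing")
  if (any(object@area <= 0)) msg <- c(msg, "areas must be > 0")
  if (length(msg)) msg else TRUE
})

#' Side branch of the main tract
#'
#' A uniform side tube attached to the main tract, closed at its far end
#' for a piriform fossa.  It enters the 1-D model as a parallel input
#' admittance at its attachment point.
#'
#' @slot attachX attachment position in mm from the glottis.
#' @slot length branch length in mm.
#' @slot area branch cross-section in mm^2.
#' @slot closedEnd `TRUE` for a closed far end (fossa).
#' @export
setClass("SideBranch",
  representation(attachX = "numeric", length = "numeric", area = "numeric",
                 closedEnd = "logical"))

setValidity("SideBranch", function(object) {
  msg <- character()
  if (object@length <= 0) msg <- c(msg, "length must be > 0")
  if (object@area <= 0) msg <- c(msg, "area must be > 0")
  if (length(msg)) msg else TRUE
})

#' Wall absorption model
#'
#' A frequency-independent absorption factor alpha between 0 and 1 for the tract
#' walls, converted internally to a real normal impedance
#' `Zn = zeta * rho * c` with `alpha = 4 zeta / (zeta + 1)^2`.
#'
#' @slot alpha absorption factor, 0 (rigid) to 1 (fully absorbing).
#' @slot air an [AirModel-class].
#' @export
setClass("WallModel",
  representation(alpha = "numeric", air = "AirModel"))

setValidity("WallModel", function(object) {
  if (object@alpha < 0 || object@alpha > 1)
    return("alpha must lie in [0, 1]")
  TRUE
})

#' Virtual measurement rig
#'
#' Synthetic driver -> memoryless polynomial nonlinearity -> tract filter
#' -> probe microphone with additive noise chain, fully determined by a
#' seed, so that the whole ESS measurement pipeline can be exercised
#' without hardware.
#'
#' @slot driverIr short FIR impulse response of the driver.
#' @slot distortionCoeffs polynomial coefficients `(a1, a2, ...)` of the
#'   memoryless nonlinearity `y = a1 x + a2 x^2 + ...`; `a1` must be
#'   nonzero.
#' @slot tractIr FIR impulse response of the tract under test (may be the
#'   unit impulse for a driver-only measurement).
#' @slot noiseSnrDb microphone signal-to-noise ratio in dB (may be `Inf`).
#' @slot seed integer seed for the noise generator.
#' @slot fs sampling rate in Hz.
#' @seealso [rigSpec()], [simulateMeasurement()]
#' @export
setClass("RigSpec",
  representation(driverIr = "numeric", distortionCoeffs = "numeric",
                 tractIr = "numeric", noiseSnrDb = "numeric",
                 seed = "numeric", fs = "numeric"))

setValidity("RigSpec", function(object) {
  msg <- character()
  if (!length(object@distortionCoeffs) || object@distortionCoeffs[1] == 0)
    msg <- c(msg, "linear distortion coefficient a1 must be nonzero")
  if (is.na(object@noiseSnrDb)) msg <- c(msg, "noiseSnrDb must not be NA")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Zero-phase spectral filter specification
#'
#' A magnitude-only (zero-phase) filter defined by a gain curve in dB on
#' a frequency grid, as produced by [fossaeRemovalFilter()].
#' [applyFilter()] realises it losslessly in the frequency domain — the
#' equivalent of a long symmetric (zero-phase) FIR — so a filter and its
#' inverse (the negated curve) cancel exactly.  [firCoefficients()]
#' exports a windowed linear-phase FIR approximation for use elsewhere.
#'
#' @slot freq frequency grid in Hz; gain is held constant beyond the
#'   grid edges.
#' @slot gainDb gain curve in dB.
#' @slot fs audio sampling rate in Hz the filter was designed for.
#' @slot label description of the filter.
#' @export
setClass("SpectralFilter",
  representation(freq = "numeric", gainDb = "numeric", fs = "numeric",
                 label = "character"))

setValidity("SpectralFilter", function(object) {
  if (length(object@freq) != length(object@gainDb))
    return("freq and gainDb must have equal length")
  if (any(diff(object@freq) <= 0))
    return("freq must be strictly increasing")
  TRUE
})

#' Resolved run configuration
#'
#' The validated settings of a measurement run (sweep spec, window policy,
#' number of repeats, air temperature), serialisable to YAML alongside the
#' outputs so that runs are reproducible.
#'
#' @slot sweep a [SweepSpec-class].
#' @slot repeats number of sweep repeats to average.
#' @slot temperatureC air temperature in degrees Celsius.
#' @slot windowThresholdDb isolation-window threshold in dB below the
#'   response peak.
#' @slot outputDir directory where outputs are written.
#' @slot logLevel one of "quiet", "info", "debug".
#' @seealso [runConfig()], [saveRunConfig()]
#' @export
setClass("RunConfig",
  representation(sweep = "SweepSpec", repeats = "numeric",
                 temperatureC = "numeric", windowThresholdDb = "numeric",
                 outputDir = "character", logLevel = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@repeats < 1) msg <- c(msg, "repeats must be >= 1")
  if (object@windowThresholdDb <= 0)
    msg <- c(msg, "windowThresholdDb must be > 0")
  if (!object@logLevel %in% c("quiet", "info", "debug"))
    msg <- c(msg, "logLevel must be quiet, info or debug")
  if (length(msg)) msg else TRUE
})
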