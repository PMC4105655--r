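#' Extract the sample vector of a signal-like object
#' @param x a [SampledSignal-class], [IrTimeline-class] or
#'   [ImpulseResponse-class].
#' @return numeric vector of samples.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' Sampling rate in Hz
#' @param x a signal-like object.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Duration in seconds
#' @param x a [SampledSignal-class] or [SweepSpec-class].
#' @return duration in seconds.
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Frequency grid of a transfer function
#' @param x a [TransferFunction-class].
#' @return numeric vector of frequencies in Hz.
#' @export
setGeneric("freqHz", function(x) standardGeneric("freqHz"))

#' Raw values of a transfer function
#' @param x a [TransferFunction-class].
#' @return complex spectrum or numeric dB magnitudes.
#' @export
setGeneric("tfValues", function(x) standardGeneric("tfValues"))

#' Magnitude in dB of a transfer function
#'
#' For a complex-valued spectrum this is `20*log10(|H|)` (including any
#' normalisation scale recorded in `meta$scale`); a `magnitude_db`
#' transfer function is returned as is.
#' @param x a [TransferFunction-class].
#' @return numeric vector of dB magnitudes.
#' @export
setGeneric("magnitudeDb", function(x) standardGeneric("magnitudeDb"))

#' @rdname samples
#' @export
setMethod("samples", "SampledSignal", function(x) x@samples)
#' @rdname samples
#' @export
setMethod("samples", "IrTimeline", function(x) x@samples)
#' @rdname samples
#' @export
setMethod("samples", "ImpulseResponse", function(x) x@samples)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "SampledSignal", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "IrTimeline", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "ImpulseResponse", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "SweepSpec", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "RigSpec", function(x) x@fs)

#' @rdname duration
#' @export
setMethod("duration", "SampledSignal",
          function(x) length(x@samples) / x@fs)
#' @rdname duration
#' @export
setMethod("duration", "SweepSpec", function(x) x@duration)

#' @rdname freqHz
#' @export
setMethod("freqHz", "TransferFunction", function(x) x@freq)

#' @rdname tfValues
#' @export
setMethod("tfValues", "TransferFunction", function(x) x@values)

#' @rdname magnitudeDb
#' @export
setMethod("magnitudeDb", "TransferFunction", function(x) {
  if (identical(x@meta$type, "magnitude_db")) return(as.numeric(x@values))
  sc <- if (!is.null(x@meta$scale)) x@meta$scale else 1
  20 * log10(pmax(abs(x@values) * sc, .Machine$double.xmin))
})

setMethod("show", "SweepSpec", function(object) {
  cat(sprintf(
    "SweepSpec: %g Hz -> %g Hz in %g s at fs = %g Hz\n", object@f1,
    object@f2, object@duration, object@fs))
  cat(sprintf("  fades: in up to %g Hz, out from %g Hz; amplitude %g\n",
              object@fEnvLo, object@fEnvHi, object@amplitude))
})

setMethod("show", "SampledSignal", function(object) {
  cat(sprintf("SampledSignal: %d samples at %g Hz (%.4g s), t0 = %g s\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs, object@t0))
})

setMethod("show", "IrTimeline", function(object) {
  cat(sprintf(
    "IrTimeline: %d samples at %g Hz, linear response at lag %.6g s\n",
    length(object@samples), object@fs, object@tLinear))
})

setMethod("show", "ImpulseResponse", function(object) {
  cat(sprintf(
    "ImpulseResponse (order %d): %d samples at %g Hz, from lag %.6g s\n",
    object@order, length(object@samples), object@fs, object@tStart))
})

setMethod("show", "TransferFunction", function(object) {
  ty <- if (is.null(object@meta$type)) "complex" else object@meta$type
  lab <- if (is.null(object@meta$label)) "" else
    paste0(" [", object@meta$label, "]")
  cat(sprintf("TransferFunction%s: %d bins, %.4g-%.5g Hz, %s\n", lab,
              length(object@freq), min(object@freq), max(object@freq), ty))
})

setMethod("show", "TubeSpec", function(object) {
  cat(sprintf(
    "TubeSpec: L = %g mm, a = %g mm, flange = %g mm, S = %.4g mm^2\n",
    object@length, object@radius, object@flange, object@area))
})

setMethod("show", "PiriformGeometry", function(object) {
  cat(sprintf(
    "PiriformGeometry '%s': L = %g mm, PV = %g cm^3, VTV = %g cm^3 (%.2f%%)\n",
    object@label, object@lengthMm, object@pv, object@vtv,
    100 * object@pv / object@vtv))
})

setMethod("show", "AirModel", function(object) {
  cat(sprintf("AirModel: %g degC, c = %.5g m/s, rho = %g kg/m^3\n",
              object@temperatureC, object@c, object@rho))
})

setMethod("show", "AreaFunction", function(object) {
  cat(sprintf("AreaFunction: %d points, 0-%g mm, areas %.3g-%.3g mm^2\n",
              length(object@x), max(object@x), min(object@area),
              max(object@area)))
})

setMethod("show", "SideBranch", function(object) {
  cat(sprintf("SideBranch: L = %g mm, S = %g mm^2 at x = %g mm (%s end)\n",
              object@length, object@area, object@attachX,
              if (object@closedEnd) "closed" else "open"))
})

setMethod("show", "RigSpec", function(object) {
  cat(sprintf(
    "RigSpec: driver %d taps, distortion order %d, tract %d taps, SNR %g dB, seed %d\n",
    length(object@driverIr), length(object@distortionCoeffs),
    length(object@tractIr), object@noiseSnrDb, object@seed))
})

setMethod("show", "SpectralFilter", function(object) {
  cat(sprintf(
    "SpectralFilter '%s': %d points, %g-%g Hz, gain %.1f to %.1f dB at fs %g\n",
    object@label, length(object@freq), min(object@freq), max(object@freq),
    min(object@gainDb), max(object@gainDb), object@fs))
})
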