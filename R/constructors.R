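#' Create a sweep specification
#'
#' Defaults cover the full audio band at a professional recorder rate:
#' 20 Hz to 20 kHz in 10 s at fs = 192 kHz, with the fade-in complete at
#' 50 Hz and the fade-out starting at 18 kHz.
#'
#' @param f1,f2 start and end frequencies in Hz.
#' @param duration sweep duration in seconds.
#' @param fs sampling rate in Hz.
#' @param fEnvLo,fEnvHi fade-in target and fade-out start frequencies in
#'   Hz; must satisfy `f1 < fEnvLo < fEnvHi < f2 <= fs/2`.
#' @param amplitude peak linear amplitude.
#' @return a [SweepSpec-class].
#' @examples
#' sweepSpec(duration = 2, fs = 48000)
#' @export
sweepSpec <- function(f1 = 20, f2 = 20000, duration = 10, fs = 192000,
                      fEnvLo = 50, fEnvHi = 18000, amplitude = 1) {
  new("SweepSpec", f1 = f1, f2 = f2, duration = duration, fs = fs,
      fEnvLo = fEnvLo, fEnvHi = fEnvHi, amplitude = amplitude)
}

#' Create a sampled signal
#' @param samples numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param t0 start-time offset in seconds.
#' @return a [SampledSignal-class].
#' @export
sampledSignal <- function(samples, fs, t0 = 0) {
  new("SampledSignal", samples = as.numeric(samples), fs = fs, t0 = t0)
}

#' Create a cylindrical tube specification
#' @param length physical length in mm.
#' @param radius inner radius in mm.
#' @param flange flange width in mm.
#' @param area cross-section in mm^2; defaults to `pi * radius^2`.
#' @return a [TubeSpec-class].
#' @examples
#' tubeSpec(142, 15, 2)  # the benchmark cylinder
#' @export
tubeSpec <- function(length, radius, flange, area = pi * radius^2) {
  new("TubeSpec", length = length, radius = radius, flange = flange,
      area = area)
}

#' Create a piriform fossa geometry record
#' @param lengthMm sinus length in mm.
#' @param pv piriform volume in cm^3.
#' @param vtv vocal-tract volume in cm^3.
#' @param label subject/vowel tag.
#' @return a [PiriformGeometry-class].
#' @export
piriformGeometry <- function(lengthMm, pv, vtv, label = "") {
  new("PiriformGeometry", lengthMm = lengthMm, pv = pv, vtv = vtv,
      label = label)
}

#' Create an air model
#'
#' Unless `c` is supplied, the speed of sound is recomputed from the
#' temperature with [speedOfSound()].
#'
#' @param temperatureC air temperature in degrees Celsius.
#' @param c speed of sound in m/s (overrides the temperature law).
#' @param rho air density in kg/m^3.
#' @return an [AirModel-class].
#' @examples
#' airModel(5)  # anechoic-chamber conditions at 5 degrees C
#' @export
airModel <- function(temperatureC = 5, c = NULL, rho = 1.2) {
  if (is.null(c)) c <- speedOfSound(temperatureC)
  new("AirModel", temperatureC = temperatureC, c = c, rho = rho)
}

#' Create a vocal-tract area function
#' @param x positions from the glottis in mm.
#' @param area cross-section areas in mm^2.
#' @return an [AreaFunction-class].
#' @export
areaFunction <- function(x, area) {
  new("AreaFunction", x = as.numeric(x), area = as.numeric(area))
}

#' Create a side branch
#' @param attachX attachment position in mm from the glottis.
#' @param length branch length in mm.
#' @param area branch cross-section in mm^2.
#' @param closedEnd `TRUE` for a closed far end (piriform fossa).
#' @return a [SideBranch-class].
#' @export
sideBranch <- function(attachX, length, area, closedEnd = TRUE) {
  new("SideBranch", attachX = attachX, length = length, area = area,
      closedEnd = closedEnd)
}

#' Create a wall absorption model
#' @param alpha frequency-independent absorption factor in `[0, 1]`.
#' @param air an [AirModel-class].
#' @return a [WallModel-class].
#' @export
wallModel <- function(alpha = 0.02, air = airModel()) {
  new("WallModel", alpha = alpha, air = air)
}

#' Create a virtual measurement rig
#'
#' @param driverIr FIR impulse response of the driver; defaults to an
#'   ideal (unit-impulse) driver.
#' @param distortionCoeffs polynomial coefficients `(a1, a2, ...)` of the
#'   memoryless nonlinearity.
#' @param tractIr FIR impulse response of the tract; a [TransferFunction-class]
#'   may be given instead and is realised as a linear-phase FIR.
#' @param noiseSnrDb microphone SNR in dB (`Inf` for noiseless).
#' @param seed integer noise seed.
#' @param fs sampling rate in Hz.
#' @param tractTaps FIR length used when `tractIr` is a transfer function.
#' @return a [RigSpec-class].
#' @export
rigSpec <- function(driverIr = 1, distortionCoeffs = 1, tractIr = 1,
                    noiseSnrDb = Inf, seed = 1, fs = 48000,
                    tractTaps = 1024) {
  if (is(tractIr, "TransferFunction"))
    tractIr <- tfToFir(tractIr, fs, n = tractTaps)
  new("RigSpec", driverIr = as.numeric(driverIr),
      distortionCoeffs = as.numeric(distortionCoeffs),
      tractIr = as.numeric(tractIr), noiseSnrDb = noiseSnrDb,
      seed = as.numeric(seed), fs = fs)
}

#' Create a run configuration
#' @param sweep a [SweepSpec-class].
#' @param repeats number of sweep repeats averaged per measurement.
#' @param temperatureC air temperature in degrees Celsius.
#' @param windowThresholdDb isolation-window threshold in dB below peak.
#' @param outputDir output directory.
#' @param logLevel "quiet", "info" or "debug".
#' @return a [RunConfig-class].
#' @export
runConfig <- function(sweep = sweepSpec(), repeats = 3, temperatureC = 5,
                      windowThresholdDb = 60, outputDir = ".",
                      logLevel = "info") {
  new("RunConfig", sweep = sweep, repeats = repeats,
      temperatureC = temperatureC, windowThresholdDb = windowThresholdDb,
      outputDir = outputDir, logLevel = logLevel)
}
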