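#' Deconvolve a recording into an impulse-response timeline
#'
#' Full linear convolution of the recording with the inverse filter
#' (computed in the frequency domain; equivalent to direct convolution to
#' ~1e-9 relative).  The exponential sweep packs harmonic-distortion
#' responses *before* the linear response on the lag axis: the linear
#' impulse response sits at the lag equal to the sweep duration, and the
#' order-k distortion is advanced by `duration * log(k) / log(f2/f1)`.
#'
#' The linear lag is taken from the inverse-filter length; the global
#' maximum of a short-time energy envelope is used as a cross-check and a
#' warning is emitted if the two disagree by more than 50 ms.
#'
#' @param recorded the recorded response as a [SampledSignal-class].
#' @param inverse the inverse filter from [buildInverseFilter()].
#' @return an [IrTimeline-class].
#' @export
deconvolveTimeline <- function(recorded, inverse) {
  if (recorded@fs != inverse@fs)
    stop("sampling rates differ (", recorded@fs, " vs ", inverse@fs, " Hz)")
  fs <- recorded@fs
  tl <- fftConvolve(recorded@samples, inverse@samples)
  tLinear <- (length(inverse@samples) - 1) / fs
  env <- movingRms(tl, round(5e-4 * fs))
  tPeak <- (which.max(env) - 1) / fs
  if (abs(tPeak - tLinear) > 0.05)
    warning(sprintf(
      "energy envelope peaks at %.4f s but the linear lag is %.4f s; %s",
      tPeak, tLinear, "check the recording alignment"))
  new("IrTimeline", samples = tl, fs = fs, tLinear = tLinear)
}

#' Predicted lags of the harmonic-distortion responses
#'
#' For harmonic order k the response is advanced before the linear one by
#' `duration * log(k) / log(f2/f1)`; order 1 is the linear response
#' itself.
#'
#' @param tl an [IrTimeline-class].
#' @param spec the [SweepSpec-class] of the measurement.
#' @param kMax highest harmonic order to report.
#' @return `data.frame(order, lagS)` with lags in seconds.
#' @export
locateHarmonics <- function(tl, spec, kMax = 5) {
  if (kMax < 1) stop("kMax must be >= 1")
  k <- seq_len(kMax)
  data.frame(order = k,
             lagS = tl@tLinear - spec@duration * log(k) /
               log(spec@f2 / spec@f1))
}

#' Extract one impulse response from the timeline
#'
#' Isolates the response of a given harmonic order (1 = linear) in a
#' window around its predicted lag.  The automatic policy mirrors manual
#' isolation on a log-magnitude display: the window starts at the last
#' upstream sample where the short-time envelope has fallen
#' `thresholdDb` below the response peak, and ends symmetrically, or at
#' the start of the neighbouring response if that comes sooner (with a
#' warning).  Explicit window bounds may be given instead.
#'
#' @param tl an [IrTimeline-class].
#' @param spec the [SweepSpec-class] of the measurement.
#' @param order harmonic order to extract (1 = linear impulse response).
#' @param thresholdDb envelope threshold below the peak, in dB.
#' @param window optional `c(tStart, tEnd)` in timeline seconds,
#'   overriding the automatic policy.
#' @return an [ImpulseResponse-class].
#' @export
extractIR <- function(tl, spec, order = 1, thresholdDb = 60,
                      window = NULL) {
  fs <- tl@fs
  x <- tl@samples
  n <- length(x)
  if (!is.null(window)) {
    i0 <- max(1L, round(window[1] * fs) + 1L)
    i1 <- min(n, round(window[2] * fs) + 1L)
    return(new("ImpulseResponse", samples = x[i0:i1], fs = fs,
               order = order, tStart = (i0 - 1) / fs))
  }
  lags <- locateHarmonics(tl, spec, kMax = order + 1L)
  lagK <- lags$lagS[order]
  if (lagK < 0) stop("order ", order, " lies before the timeline start")
  gapUp <- lags$lagS[order] - lags$lagS[order + 1L]  # to next (earlier) order
  gapDown <- if (order > 1) lags$lagS[order - 1L] - lags$lagS[order] else
    (n - 1) / fs - lagK
  half <- 0.45 * gapUp
  i0s <- max(1L, round((lagK - half) * fs) + 1L)
  i1s <- min(n, round((lagK + min(half, gapDown * 0.45)) * fs) + 1L)
  p <- i0s - 1L + which.max(abs(x[i0s:i1s]))
  env <- movingRms(x[i0s:i1s], round(2e-4 * fs))
  pk <- max(env)
  thr <- pk * 10^(-thresholdDb / 20)
  pl <- p - i0s + 1L
  below <- which(env[seq_len(pl)] <= thr)
  start <- if (length(below)) i0s - 1L + max(below) else i0s
  end <- p + (p - start)
  lim <- if (order > 1) {
    round((lags$lagS[order - 1L] - 0.45 * (lags$lagS[order - 1L] -
                                             lagK)) * fs) + 1L
  } else n
  if (end > lim) {
    warning("isolation window truncated at the neighbouring response")
    end <- lim
  }
  end <- min(end, n)
  new("ImpulseResponse", samples = x[start:end], fs = fs, order = order,
      tStart = (start - 1) / fs)
}

#' Transfer function of an impulse response
#'
#' Implements the four-step transform: (1) find the next power of two not
#' smaller than the window length, (2) normalise the amplitude to unit
#' peak, (3) zero-pad to that length, (4) discrete Fourier transform on
#' the grid `fs * j / N`.  The removed normalisation factor is recorded in
#' `meta$scale`, so calibrated magnitudes remain available downstream.
#'
#' @param ir an [ImpulseResponse-class].
#' @param normalize normalise to unit peak before the FFT (the default);
#'   `FALSE` keeps raw amplitudes and `meta$scale = 1`.
#' @return a one-sided [TransferFunction-class] (0 to fs/2) with complex
#'   values.
#' @export
irToSpectrum <- function(ir, normalize = TRUE) {
  x <- ir@samples
  peak <- max(abs(x))
  if (peak == 0) stop("impulse response is identically zero")
  nfft <- nextPow2(length(x))
  if (normalize) x <- x / peak else peak <- 1
  X <- stats::fft(c(x, rep(0, nfft - length(x))))
  half <- seq_len(nfft %/% 2 + 1)
  new("TransferFunction", freq = ir@fs * (half - 1) / nfft,
      values = X[half],
      meta = list(type = "complex", scale = peak, n = nfft,
                  order = ir@order))
}

#' Complex average of repeated spectra
#'
#' Element-wise complex mean over repeats on an identical frequency grid,
#' which cancels uncorrelated measurement noise (the in-band deviation
#' from the noiseless spectrum shrinks like 1/sqrt(n)).  Any per-repeat
#' normalisation scales recorded by [irToSpectrum()] are reapplied before
#' averaging so that repeats with different peak levels average
#' consistently.
#'
#' @param spectra list of at least two [TransferFunction-class] objects.
#' @return the averaged [TransferFunction-class] (`meta$scale = 1`).
#' @export
complexAverage <- function(spectra) {
  if (length(spectra) < 2) stop("need at least two spectra")
  f0 <- spectra[[1]]@freq
  for (s in spectra[-1])
    if (!isTRUE(all.equal(s@freq, f0)))
      stop("frequency grids differ between spectra")
  vals <- lapply(spectra, function(s) {
    sc <- if (!is.null(s@meta$scale)) s@meta$scale else 1
    s@values * sc
  })
  avg <- Reduce(`+`, vals) / length(vals)
  new("TransferFunction", freq = f0, values = avg,
      meta = list(type = "complex", scale = 1,
                  nAveraged = length(spectra)))
}

#' Subtract a driver reference spectrum
#'
#' Returns the magnitude difference in dB,
#' `20 log10|H_system| - 20 log10|H_driver|`, i.e. the transfer function
#' of the standalone tract with the driver's (and microphone's) frequency
#' response cancelled.  Phase is not propagated.  Near-zero driver bins
#' are floored at `epsilon` with a warning.
#'
#' @param tfSystem spectrum measured with the tract in place.
#' @param tfDriver spectrum of the driver alone.
#' @param epsilon linear magnitude floor for near-zero bins.
#' @return a magnitude-dB [TransferFunction-class].
#' @export
subtractReference <- function(tfSystem, tfDriver, epsilon = 1e-12) {
  if (!isTRUE(all.equal(tfSystem@freq, tfDriver@freq)))
    stop("frequency grids differ")
  mS <- calibratedMagnitude(tfSystem)
  mD <- calibratedMagnitude(tfDriver)
  nFloor <- sum(mD < epsilon) + sum(mS < epsilon)
  if (nFloor > 0)
    warning(nFloor, " near-zero bins floored at epsilon = ", epsilon)
  d <- 20 * log10(pmax(mS, epsilon)) - 20 * log10(pmax(mD, epsilon))
  new("TransferFunction", freq = tfSystem@freq, values = d,
      meta = list(type = "magnitude_db", label = "tract (driver removed)"))
}

calibratedMagnitude <- function(tf) {
  sc <- if (!is.null(tf@meta$scale)) tf@meta$scale else 1
  abs(tf@values) * sc
}

#' Measure a tract transfer function from sweep recordings
#'
#' The complete measurement pipeline: each recording is deconvolved with
#' the inverse filter, the linear impulse response is isolated and
#' transformed, repeats are complex-averaged, and the driver-alone
#' reference is subtracted in dB, yielding the transfer function of the
#' standalone tract, independent of the driver's own response and
#' harmonic distortion.
#'
#' @param recordings list of [SampledSignal-class] recordings made with
#'   the tract in place (repeats of the same sweep).
#' @param references list of recordings of the driver alone.
#' @param inverse the inverse filter.
#' @param spec the [SweepSpec-class] used.
#' @param thresholdDb isolation-window threshold (see [extractIR()]).
#' @param window optional fixed isolation window, `c(tStart, tEnd)` s.
#' @return a magnitude-dB [TransferFunction-class].
#' @export
measureTransferFunction <- function(recordings, references, inverse, spec,
                                    thresholdDb = 60, window = NULL) {
  spectra <- function(recs) {
    lapply(recs, function(r) {
      tl <- deconvolveTimeline(r, inverse)
      irToSpectrum(extractIR(tl, spec, order = 1,
                             thresholdDb = thresholdDb, window = window))
    })
  }
  sS <- spectra(recordings)
  sD <- spectra(references)
  avg <- function(ss) if (length(ss) > 1) complexAverage(ss) else ss[[1]]
  subtractReference(avg(sS), avg(sD))
}
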