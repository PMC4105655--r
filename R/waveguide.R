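#' Simulate the transfer function of a tract with side branches
#'
#' One-dimensional plane-wave (transmission-line) model of a vocal-tract
#' area function.  The tract is resampled into uniform elements (at least
#' 20 per shortest wavelength), each propagated with its exact chain
#' matrix; closed side branches enter as parallel input admittances at
#' their attachment points; a unit volume-velocity source drives the
#' glottis end; the lips radiate into free field and the pressure is
#' evaluated at a probe in front of the lips (3 cm by default).
#'
#' Wall absorption is a frequency-independent factor `alpha`, mapped to a
#' real normal impedance `Zn = zeta rho c` through
#' `alpha = 4 zeta / (zeta + 1)^2` and applied as a distributed shunt
#' conductance on the duct perimeter.  The radiation load is a flanged
#' piston: reactance from the end correction ([endCorrection()], scaled
#' by [oecc()] for a finite flange) and, with `radiation = "piston"`, the
#' piston radiation resistance `1 - J1(2ka)/(ka)`.  `radiation =
#' "reactive"` drops the resistance, giving a strictly lossless model
#' when `alpha = 0` whose peaks coincide with [transcendentalModes()].
#'
#' @param tract an [AreaFunction-class] (positions in mm from glottis).
#' @param branches list of [SideBranch-class] objects (may be empty).
#' @param wall a [WallModel-class].
#' @param fGrid frequency grid in Hz (plane-wave validity ends around
#'   10 kHz for vocal-tract bores).
#' @param probeDistance probe distance from the lips in m.
#' @param flangeWidthMm flange width at the lips in mm (`Inf` for a
#'   baffled opening).
#' @param radiation `"piston"` (resistive + reactive, default) or
#'   `"reactive"` (lossless).
#' @param dx element length in mm; `NULL` picks
#'   `min(c / (20 fMax), L/50)` automatically.  A coarser request is
#'   refused with the required element count.
#' @return a complex [TransferFunction-class] (probe pressure per unit
#'   glottal volume velocity).
#' @examples
#' tr <- areaFunction(c(0, 142), c(707, 707))   # uniform 15 mm bore
#' tf <- simulateTF(tr, list(), wallModel(0.02, airModel(5)),
#'                  seq(100, 5000, by = 10))
#' @export
simulateTF <- function(tract, branches = list(), wall = wallModel(),
                       fGrid = seq(50, 10000, by = 5),
                       probeDistance = 0.03, flangeWidthMm = Inf,
                       radiation = c("piston", "reactive"), dx = NULL) {
  radiation <- match.arg(radiation)
  air <- wall@air
  cc <- air@c; rho <- air@rho
  Lmm <- max(tract@x) - min(tract@x)
  dxReq <- 1e3 * cc / (20 * max(fGrid))       # mm, 20 elements / lambda
  if (is.null(dx)) dx <- min(dxReq, Lmm / 50)
  if (dx > dxReq)
    stop(sprintf(
      "element length %.3g mm under-resolves %g Hz: need <= %.3g mm (%d elements)",
      dx, max(fGrid), dxReq, ceiling(Lmm / dxReq)))
  nSeg <- max(2L, ceiling(Lmm / dx))
  xs <- seq(min(tract@x), max(tract@x), length.out = nSeg + 1L)
  ar <- stats::approx(tract@x, tract@area, xout = xs)$y
  segArea <- (ar[-1] + ar[-length(ar)]) / 2 * 1e-6      # m^2
  segLen <- diff(xs) * 1e-3                             # m
  brSeg <- vapply(branches, function(b) {
    if (b@attachX < min(tract@x) || b@attachX > max(tract@x))
      stop("branch attachment at ", b@attachX, " mm is outside the tract")
    max(2L, which.min(abs(xs - b@attachX)))
  }, integer(1))

  w <- 2 * pi * fGrid
  k <- w / cc
  zeta <- if (wall@alpha <= 0) Inf else
    (2 - wall@alpha + 2 * sqrt(1 - wall@alpha)) / wall@alpha

  # chain matrix of one uniform duct of area S (m^2), length l (m)
  segMat <- function(S, l) {
    P <- 2 * sqrt(pi * S)
    Zser <- 1i * w * rho / S
    Ysh <- 1i * w * S / (rho * cc^2) +
      (if (is.finite(zeta)) P / (zeta * rho * cc) else 0)
    g <- sqrt(Zser * Ysh)
    Zc <- sqrt(Zser / Ysh)
    list(A = cosh(g * l), B = Zc * sinh(g * l),
         C = sinh(g * l) / Zc, D = cosh(g * l))
  }
  branchAdmittance <- function(b) {
    S <- b@area * 1e-6; l <- b@length * 1e-3
    P <- 2 * sqrt(pi * S)
    Zser <- 1i * w * rho / S
    Ysh <- 1i * w * S / (rho * cc^2) +
      (if (is.finite(zeta)) P / (zeta * rho * cc) else 0)
    g <- sqrt(Zser * Ysh)
    Zc <- sqrt(Zser / Ysh)
    if (b@closedEnd) tanh(g * l) / Zc else 1 / (Zc * tanh(g * l))
  }

  A <- rep(1 + 0i, length(w)); B <- A * 0; C <- A * 0; D <- A
  for (i in seq_len(nSeg)) {
    m <- segMat(segArea[i], segLen[i])
    A2 <- A * m$A + B * m$C; B2 <- A * m$B + B * m$D
    C2 <- C * m$A + D * m$C; D2 <- C * m$B + D * m$D
    A <- A2; B <- B2; C <- C2; D <- D2
    hit <- which(brSeg == i + 1L)
    for (j in hit) {
      Yb <- branchAdmittance(branches[[j]])
      C <- C + A * Yb; D <- D + B * Yb
    }
  }

  SL <- segArea[nSeg]
  aL <- sqrt(SL / pi)
  ka <- k * aL
  dInf <- aL * 0.8216 / (1 + (0.77 * ka)^2 / (1 + 0.77 * ka))
  dl <- oecc(aL * 1e3, flangeWidthMm) * dInf
  Rr <- if (radiation == "piston") {
    r <- ifelse(ka > 0, 1 - besselJ(2 * ka, 1) / ka, 0)
    pmax(r, 0)
  } else 0
  Zrad <- (rho * cc / SL) * (Rr + 1i * k * dl)

  Ulips <- 1 / (C * Zrad + D)            # unit glottal volume velocity
  p <- 1i * w * rho * Ulips * exp(-1i * k * probeDistance) /
    (4 * pi * probeDistance)
  new("TransferFunction", freq = fGrid, values = p,
      meta = list(type = "complex", scale = 1,
                  label = sprintf("1-D simulation (%d elements, alpha=%g)",
                                  nSeg, wall@alpha)))
}

#' Find formants (magnitude peaks) of a transfer function
#'
#' Local maxima of the dB magnitude with at least `prominenceDb` of
#' prominence, returned in ascending frequency and labelled F1, F2, ...
#' Peaks closer than one grid step merge into a single formant (plateaus
#' count once) with a warning.
#'
#' @param tf a [TransferFunction-class].
#' @param prominenceDb minimum peak prominence in dB.
#' @return `data.frame(label, freqHz, magDb, prominenceDb)`.
#' @export
findFormants <- function(tf, prominenceDb = 3) {
  m <- magnitudeDb(tf)
  pk <- peaksWithProminence(m)
  if (nrow(pk) && any(pk$plateau))
    warning("peaks closer than the grid step were merged")
  pk <- pk[pk$prominence >= prominenceDb, , drop = FALSE]
  if (!nrow(pk))
    return(data.frame(label = character(), freqHz = numeric(),
                      magDb = numeric(), prominenceDb = numeric()))
  data.frame(label = paste0("F", seq_len(nrow(pk))),
             freqHz = tf@freq[pk$index], magDb = pk$value,
             prominenceDb = pk$prominence)
}

#' Find spectral troughs (antiresonances)
#'
#' Mirror of [findFormants()] on the inverted magnitude: local minima
#' with at least `prominenceDb` of (downward) prominence.
#'
#' @inheritParams findFormants
#' @return trough frequencies in Hz, ascending.
#' @export
findTroughs <- function(tf, prominenceDb = 3) {
  m <- -magnitudeDb(tf)
  pk <- peaksWithProminence(m)
  pk <- pk[pk$prominence >= prominenceDb, , drop = FALSE]
  tf@freq[pk$index]
}

#' Formant shifts caused by a side branch
#'
#' Pairs the formants of a tract simulated with and without its side
#' branch(es) and reports the shift of each.  A closed side branch acts
#' as a formant repellent around its first antiresonance `f_antires`:
#' formants below it shift down, formants above shift up (the sign rule
#' reverses beyond the branch's half-wave impedance pole at about
#' `2 f_antires`).  Formants are paired by order; if the counts differ
#' they are aligned by nearest frequency and flagged.
#'
#' @param tfWith,tfWithout transfer functions on one grid, with and
#'   without the branch.
#' @param fAntires branch antiresonance frequency in Hz (e.g. from
#'   [piriformAntiresonance()]).
#' @param prominenceDb passed to [findFormants()].
#' @return `data.frame(order, fWithoutHz, fWithHz, shiftHz, side,
#'   signConsistent)`; attribute `aligned` is `"order"` or
#'   `"nearest"`.
#' @export
repulsionAnalysis <- function(tfWith, tfWithout, fAntires,
                              prominenceDb = 3) {
  if (!isTRUE(all.equal(tfWith@freq, tfWithout@freq)))
    stop("transfer functions must share one frequency grid")
  fW <- findFormants(tfWith, prominenceDb)$freqHz
  fO <- findFormants(tfWithout, prominenceDb)$freqHz
  aligned <- "order"
  if (length(fW) != length(fO)) {
    warning("formant counts differ (", length(fW), " vs ", length(fO),
            "); aligning by nearest frequency")
    aligned <- "nearest"
    nn <- min(length(fW), length(fO))
    if (length(fW) > length(fO)) {
      keep <- vapply(fO, function(f) which.min(abs(fW - f)), integer(1))
      fW <- fW[keep]
    } else {
      keep <- vapply(fW, function(f) which.min(abs(fO - f)), integer(1))
      fO <- fO[keep]
    }
  }
  shift <- fW - fO
  side <- ifelse(fO < fAntires, "below", "above")
  out <- data.frame(order = seq_along(shift), fWithoutHz = fO,
                    fWithHz = fW, shiftHz = shift, side = side,
                    signConsistent = ifelse(side == "below", shift <= 0,
                                            shift >= 0))
  attr(out, "aligned") <- aligned
  out
}

#' Design the fossae-removal filter
#'
#' Zero-phase filter whose dB gain is the difference between the
#' spectrum without and the spectrum with the piriform fossae; applied
#' to a voice recorded (or synthesised) with fossae it mimics the
#' fossa-less voice.  Swapping the arguments designs the exact inverse
#' (the negated curve), so a removal filter and its inverse cancel.
#' The gain is held constant beyond the grid edges.
#'
#' @param tfWith,tfWithout transfer functions on one grid (with /
#'   without fossae).
#' @param fs target audio sampling rate in Hz; must be at least twice
#'   the highest grid frequency.
#' @return a [SpectralFilter-class].
#' @seealso [applyFilter()], [firCoefficients()]
#' @export
fossaeRemovalFilter <- function(tfWith, tfWithout, fs) {
  if (!isTRUE(all.equal(tfWith@freq, tfWithout@freq)))
    stop("transfer functions must share one frequency grid")
  if (fs < 2 * max(tfWith@freq))
    stop("audio fs must be >= twice the highest grid frequency")
  new("SpectralFilter", freq = tfWith@freq,
      gainDb = magnitudeDb(tfWithout) - magnitudeDb(tfWith), fs = fs,
      label = "fossae removal (spectral difference)")
}

#' Apply a zero-phase spectral filter to audio
#'
#' Realises the filter's magnitude curve in the frequency domain with
#' zero phase: the audio is zero-padded well past the filter's implied
#' impulse-response length, its spectrum multiplied by the interpolated
#' linear gain, and transformed back.  The output is time-aligned with
#' the input (no group delay) and trimmed to the same length.  Because
#' the realisation is exact on the transform grid, applying a filter and
#' then its inverse (the negated gain curve) returns the input to within
#' rounding error.
#'
#' @param audio a [SampledSignal-class].
#' @param filt a [SpectralFilter-class] designed at the audio's rate.
#' @return the filtered [SampledSignal-class].
#' @export
applyFilter <- function(audio, filt) {
  if (audio@fs != filt@fs)
    stop("audio rate (", audio@fs, ") differs from filter design rate (",
         filt@fs, ")")
  x <- audio@samples
  n <- length(x)
  nf <- nextPow2(n + 8192)     # padding absorbs the implied IR tails
  half <- nf %/% 2 + 1
  fgrid <- audio@fs * (seq_len(half) - 1) / nf
  g <- 10^(interpHold(filt@freq, filt@gainDb, fgrid) / 20)
  G <- c(g, rev(g[2:(half - 1)]))
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nf - n))) * G,
                     inverse = TRUE)) / nf
  sampledSignal(y[seq_len(n)], audio@fs, audio@t0)
}

#' Export a linear-phase FIR approximation of a spectral filter
#'
#' Windowed frequency-sampling design ([signal::fir2]) of the filter's
#' gain curve, for use in external convolution engines.  The returned
#' taps have a group delay of `n/2` samples.
#'
#' @param filt a [SpectralFilter-class].
#' @param n FIR order (even).
#' @return numeric vector of `n + 1` taps.
#' @export
firCoefficients <- function(filt, n = 2048) {
  if (n %% 2 != 0) n <- n + 1
  fgrid <- seq(0, filt@fs / 2, length.out = 1025)
  m <- 10^(interpHold(filt@freq, filt@gainDb, fgrid) / 20)
  as.numeric(signal::fir2(n, fgrid / (filt@fs / 2), m))
}
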