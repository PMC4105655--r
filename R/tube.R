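#' Speed of sound in air
#'
#' `c(T) = 331.3 sqrt(1 + T/273)` m/s.  At 5 degrees C (the anechoic
#' measurement condition) this gives 334.32 m/s, the value consistent
#' with back-solving `c = 4 L f` from the bundled piriform geometry
#' table.
#'
#' @param temperatureC air temperature in degrees Celsius, in (-50, 100).
#' @return speed of sound in m/s.
#' @examples
#' speedOfSound(5)
#' @export
speedOfSound <- function(temperatureC) {
  if (any(temperatureC <= -50 | temperatureC >= 100))
    stop("temperatureC must lie in (-50, 100)")
  331.3 * sqrt(1 + temperatureC / 273)
}

#' Quarter-wave resonances of a closed-open tube
#'
#' `f_n = (2n - 1) c / (4 L)`: the odd-harmonic series of a quarter
#' wavelength resonator of effective (acoustical) length `L`.
#'
#' @param lEffMm effective acoustical length in mm.
#' @param air an [AirModel-class].
#' @param nModes number of modes.
#' @return frequencies in Hz.
#' @examples
#' quarterWaveModes(20.50, airModel(5), 1)  # ~4077 Hz
#' @export
quarterWaveModes <- function(lEffMm, air = airModel(), nModes = 5) {
  if (lEffMm <= 0) stop("lEffMm must be > 0")
  n <- seq_len(nModes)
  (2 * n - 1) * air@c / (4 * lEffMm * 1e-3)
}

#' Low-frequency end correction of an open tube end
#'
#' Effective lengthening of the tube due to the plug of air vibrating
#' just outside the open end.  For an infinite circular flange the
#' Dalmont fit (after Norris and Cheng) is used,
#' `delta/a = 0.8216 / (1 + (0.77 ka)^2 / (1 + 0.77 ka))`, valid for
#' `ka < 1.5`; without a flange the Levine-Schwinger value 0.6133 a with
#' Dalmont's k-dependence applies.  A finite flange scales the
#' infinite-flange correction by the open-end correction coefficient
#' ([oecc()]).
#'
#' @param tube a [TubeSpec-class].
#' @param k wavenumber in rad/m (vectorised).  `k = 0` gives the
#'   low-frequency limit.
#' @param flange `"finite"` (default; uses the tube's flange width),
#'   `"infinite"` or `"none"`.
#' @return end correction in mm.
#' @examples
#' endCorrection(tubeSpec(142, 15, 2), 0, "infinite") / 15  # 0.8216
#' @export
endCorrection <- function(tube, k, flange = c("finite", "infinite", "none")) {
  flange <- match.arg(flange)
  a <- tube@radius * 1e-3
  ka <- k * a
  if (any(ka >= 1.5))
    warning("ka >= 1.5: outside the validity of the end-correction fit")
  inf <- a * 0.8216 / (1 + (0.77 * ka)^2 / (1 + 0.77 * ka))
  d <- switch(flange,
    infinite = inf,
    none = a * (0.6133 * (1 + 0.044 * ka^2) / (1 + 0.19 * ka^2) -
                  0.02 * sin(2 * ka)^2),
    finite = oecc(tube@radius, tube@flange) * inf)
  d * 1e3
}

#' Open-end correction coefficient for a finite flange
#'
#' Empirical low-frequency factor by which the infinite-flange end
#' correction is multiplied to account for a flange of finite width `w`:
#' `OECC = (0.821 - 0.13 (0.42 + w/a)^-0.54) / 0.821`.  It tends to 1 as
#' the flange widens and to the unflanged ratio (~0.747) at `w = 0`.
#'
#' @param radiusMm open-end radius in mm.
#' @param flangeMm flange width in mm (may be `Inf`).
#' @return dimensionless coefficient.
#' @export
oecc <- function(radiusMm, flangeMm) {
  if (radiusMm <= 0 || flangeMm < 0) stop("radius and flange must be > 0")
  w <- flangeMm / radiusMm
  if (is.infinite(w)) return(1)
  (0.821 - 0.13 * (0.42 + w)^-0.54) / 0.821
}

#' Resonances of a closed-open tube from the transcendental condition
#'
#' Solves `cot(k L) = k delta(k)` for a tube closed at one end and
#' radiating from the other, where `delta(k)` is the frequency-dependent
#' end correction (the inertive radiation load); the cross-section enters
#' through `a = sqrt(S/pi)`.  With `delta` constant (low frequency) the
#' roots are the quarter-wave modes of the acoustical length
#' `L + delta`; with `endCorrection = "none"` they are exactly the
#' quarter-wave modes of the physical length.  Each root is isolated in
#' one quarter-period interval of `kL` and refined to 0.01 Hz.
#'
#' Plane-wave theory requires the cross-sectional dimension to stay below
#' half a wavelength; a warning is given when `fMax` exceeds `c / (4 a)`
#' (about 5.6 kHz for a 15 mm radius).
#'
#' @param tube a [TubeSpec-class].
#' @param air an [AirModel-class].
#' @param fMax highest frequency searched, Hz.
#' @param endCorrection `"finite"` (default), `"infinite"` or `"none"`.
#' @param tol root tolerance in Hz.
#' @return resonance frequencies in Hz (possibly empty).
#' @examples
#' transcendentalModes(tubeSpec(142, 15, 2), airModel(5), 5000)
#' @export
transcendentalModes <- function(tube, air = airModel(), fMax = 10000,
                                endCorrection = c("finite", "infinite",
                                                  "none"),
                                tol = 0.01) {
  endCorrection <- match.arg(endCorrection)
  L <- tube@length * 1e-3
  a <- sqrt(tube@area / pi) * 1e-3
  cc <- air@c
  if (fMax > cc / (4 * a))
    warning(sprintf(
      "plane-wave assumption doubtful above %.0f Hz for radius %g mm",
      cc / (4 * a), a * 1e3))
  dl <- function(k) {
    if (endCorrection == "none") return(rep(0, length(k)))
    ka <- k * a
    inf <- a * 0.8216 / (1 + (0.77 * ka)^2 / (1 + 0.77 * ka))
    if (endCorrection == "finite")
      oecc(tube@radius, tube@flange) * inf else inf
  }
  g <- function(f) {
    k <- 2 * pi * f / cc
    1 / tan(k * L) - k * dl(k)
  }
  roots <- numeric()
  n <- 1L
  repeat {
    fLo <- ((n - 1) * pi + 1e-9) * cc / (2 * pi * L)
    fHi <- ((n - 1) * pi + pi / 2 + 1e-9) * cc / (2 * pi * L)
    if (fLo > fMax) break
    r <- stats::uniroot(g, c(fLo, fHi), tol = tol)$root
    if (r > fMax) break
    roots <- c(roots, r)
    n <- n + 1L
  }
  roots
}

#' Quarter-wave antiresonance of the piriform fossae
#'
#' The piriform sinuses act as closed side branches of the vocal tract;
#' their n-th spectral zero is predicted by the quarter-wave resonator
#' formula `F_n = (2n - 1) c / (4 L)` with `L` the sinus length.
#'
#' @param geom a [PiriformGeometry-class].
#' @param air an [AirModel-class].
#' @param n mode number (1 = first antiresonance, the 4-5 kHz trough).
#' @return frequency in Hz.
#' @examples
#' piriformAntiresonance(piriformGeometry(17.63, 3.47, 44.58), airModel(5))
#' @export
piriformAntiresonance <- function(geom, air = airModel(), n = 1) {
  (2 * n - 1) * air@c / (4 * geom@lengthMm * 1e-3)
}

#' Summary of piriform antiresonances across geometries
#'
#' First antiresonance per geometry plus their mean and sample (n - 1)
#' standard deviation, and the fossa-to-tract volume ratio
#' `100 * PV / VTV` that tracks the magnitude of the spectral effect.
#'
#' @param geoms list of [PiriformGeometry-class] objects (>= 2).
#' @param air an [AirModel-class].
#' @return list with `meanHz`, `sdHz` and a per-geometry `table`
#'   (`label`, `lengthMm`, `antiresonanceHz`, `volumeRatioPct`).
#' @export
antiresonanceSummary <- function(geoms, air = airModel()) {
  if (length(geoms) < 2) stop("need at least two geometries")
  f <- vapply(geoms, piriformAntiresonance, numeric(1), air = air)
  tab <- data.frame(
    label = vapply(geoms, function(g) g@label, character(1)),
    lengthMm = vapply(geoms, function(g) g@lengthMm, numeric(1)),
    antiresonanceHz = f,
    volumeRatioPct = vapply(geoms, function(g) 100 * g@pv / g@vtv,
                            numeric(1)))
  list(meanHz = mean(f), sdHz = stats::sd(f), table = tab)
}
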