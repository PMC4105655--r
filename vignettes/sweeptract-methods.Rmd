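---
title: "Measuring and modelling vocal-tract transfer functions with exponential sine sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling vocal-tract transfer functions with exponential sine sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweeptract)
```

## The problem

The piriform fossae are the two pear-shaped cavities lateral to the
laryngeal vestibule at the lower end of the pharynx.  Acoustically they
are closed side branches of the vocal tract: they introduce a spectral
zero (a trough) in the voice output, typically between 4 and 5 kHz, and
they push formant frequencies away from that zero — formants below it
move down, formants above it move up.  Quantifying this effect requires
(a) a way to *measure* the transfer function of a physical tract model
that does not depend on the loudspeaker and microphone used, and (b) a
*model* that predicts where the trough sits and how the formants move.
This package implements both, plus a synthetic measurement rig so the
whole chain can be validated on a desk.

## The exponential sine sweep method

The excitation is the exponential sine sweep (ESS)

$$x(t) = \sin\!\big(2\pi f_1 L\, (e^{t/L} - 1)\big), \qquad
  L = \frac{T}{\ln(f_2/f_1)},$$

whose instantaneous frequency rises exponentially from $f_1$ at $t = 0$
to $f_2$ at $t = T$.  Its power spectral density falls at
$-3$ dB/octave.  Convolving the recorded response with a time-reversed,
amplitude-modulated copy of the sweep (the *inverse filter*) compresses
the linear response into a band-limited impulse at lag $T$, while the
$k$-th harmonic-distortion product of the playback chain is compressed
into its own impulse at lag $T - L\ln k$ — *before* the linear
response, where it can be windowed away.  This temporal separation is
what makes the measurement transducer-independent: distortion generated
in the driver or microphone never contaminates the linear impulse
response (LIR).

Implementation choices:

* **Post-modulation.**  The time-reversed sweep still falls at
  $-3$ dB/octave, so it is multiplied by the exponential envelope
  $f_{\mathrm{inst}}(t)/f_2$, normalised to 1 at the sample where the
  instantaneous frequency reaches $f_2$.  (The alternative —
  pre-modulating the excitation to a flat spectrum — is out of scope.)
* **Amplitude calibration.**  The inverse filter additionally carries
  the analytic factor $4 f_2 / (L f_s^2)$, derived by stationary phase,
  which makes the in-band magnitude of
  $\mathrm{ess} \ast \mathrm{inverse}$ unity.  Deconvolved impulse
  responses therefore come out in the physical units of the system
  under test; the factor cancels in the driver subtraction, so it does
  not affect tract spectra either way.
* **Fades.**  An abrupt sweep start (slope discontinuity) and end
  (amplitude discontinuity) each inject a broadband burst that shows up
  as "pre-ringing" and "post-ringing" around the deconvolved impulse.
  Both ends are therefore shaped with quarter-period sine-squared
  envelopes, solved in closed form, with the crossover times snapped to
  the sample grid (last sample at or before the fade-in target
  frequency; first sample at or after the fade-out start frequency).
  The first and last samples are exactly zero.  Note that the two fades
  act jointly: because the inverse filter is built from the same
  signal, the *end* discontinuity also leaks into the *pre*-impulse
  region (and vice versa), so meaningful ringing suppression requires
  both fades.  With both on, the bursts outside a $\pm 100$ ms
  neighbourhood of the main lobe drop by more than 40 dB in our tests;
  the $\pm 100$ ms skirt itself is band-limitation, not ringing.
* **Isolation window.**  The published workflow isolated each impulse
  response by hand on a log-magnitude display.  For reproducibility the
  default policy is automatic: the window opens at the last upstream
  sample where the short-time RMS envelope is 60 dB below the response
  peak and closes symmetrically, or at the neighbouring response if
  that comes sooner.  Manual bounds can be passed instead.
* **Spectra.**  Each windowed impulse response is normalised to unit
  peak, zero-padded to the next power of two and Fourier transformed
  (the removed scale is kept in the object's metadata so calibrated
  magnitudes survive).  Repeats — three by default — are averaged as
  complex numbers, which cancels uncorrelated noise like
  $1/\sqrt{n}$.  The driver-alone spectrum is subtracted from the
  with-tract spectrum on a dB magnitude scale; phase is not propagated
  through the subtraction.  Near-zero reference bins are floored at
  $10^{-12}$ with a warning.

### Default sweep parameters

The source publication does not state the sweep band or duration it
used, so the package defaults are a full-band studio choice: 20 Hz to
20 kHz in 10 s at 192 kHz, fades complete at 50 Hz and starting at
18 kHz.  The test-suite and examples use the same band scaled down to
2 s at 48 kHz, which keeps every property of the method intact (all
lags scale with $T$) at a fraction of the compute.

## Analytic tube acoustics

For a cylinder closed at one end and open at the other, the resonances
are odd multiples of $c/4L'$, where $L'$ is the *acoustical* length:
the physical length plus the end correction for the air plug vibrating
just outside the opening.  The implemented pieces are:

* `speedOfSound()`: $c(T) = 331.3\sqrt{1 + T/273}$ m/s.  At the 5 °C
  measurement condition this gives 334.32 m/s, the value that
  back-solves exactly from every row of the bundled piriform table
  ($c = 4 L f$); the common alternative convention
  $331.45\sqrt{T_K/273.15}$ misses those frequencies by about 2 Hz.
* `endCorrection()`: the Dalmont fit (after Norris and Cheng) for an
  infinitely flanged opening,
  $\delta_\infty/a = 0.8216\,[1 + (0.77ka)^2/(1 + 0.77ka)]^{-1}$,
  valid for $ka < 1.5$; the Levine–Schwinger value $0.6133a$ (with
  Dalmont's $k$-dependence) for no flange.
* `oecc()`: the Hall finite-flange interpolation used in the
  speech-acoustics literature,
  $\delta/a = 0.821 - 0.13\,(0.42 + w/a)^{-0.54}$, expressed as the
  open-end correction coefficient $\mathrm{OECC} = \delta/\delta_\infty$
  ($\to 1$ for a wide flange, $\approx 0.747$ unflanged).
* `transcendentalModes()`: the 1-D resonance condition with an inertive
  radiation load, $\cot(kL) = k\,\delta(k)$, with
  $\delta(k) = \mathrm{OECC}\cdot\delta_\infty(ka)$ and
  $a = \sqrt{S/\pi}$.  Each root lies in one quarter-period interval of
  $kL$, so root isolation is exact; bisection refines to 0.01 Hz.  With
  $\delta$ constant the roots reduce to the quarter-wave series of
  $L + \delta$.  A warning is raised when the search extends beyond
  $c/4a$, where plane-wave theory becomes doubtful (about 5.6 kHz for a
  15 mm bore).
* `piriformAntiresonance()`: the sinus as a quarter-wave resonator,
  $F_n = (2n-1)\,c/4L_\mathrm{sinus}$, with per-singer summaries
  (mean, $n-1$ standard deviation, and the fossa-to-tract volume ratio
  $100\,PV/VTV$ that tracks the size of the spectral effect).

## The 1-D waveguide simulator

The reference numerical results were produced with a 3-D finite-element
solver, which is out of scope here; the package provides the standard
1-D plane-wave (transmission-line) model instead, which the cited
literature itself justifies up to roughly 5 kHz for vocal-tract bores.
The tract's area function is resampled into uniform elements — at least
20 per shortest wavelength; a coarser request is refused with the
required element count — and each element is propagated with its exact
chain matrix.  Losses and loads:

* **Walls.**  A frequency-independent absorption factor $\alpha$
  (default 0.02; the published value is configuration, not a claim) is
  mapped to a real normal impedance $Z_n = \zeta \rho c$ through
  $\alpha = 4\zeta/(\zeta+1)^2$ and enters as a distributed shunt
  conductance on the element perimeter.
* **Side branches.**  A closed branch of length $L_b$ and area $S_b$
  attaches as a parallel input admittance
  $Y_b = \tanh(\gamma L_b)/Z_c$ at its attachment node — pressure
  continuity, flow sum.  Its first impedance zero sits at
  $c/4L_b$, producing the spectral trough; its first impedance *pole*
  sits an octave higher, at $c/2L_b$, and the formant-repulsion sign
  rule necessarily reverses above that pole because the branch
  reactance changes sign there.  Sign-pattern checks are therefore
  scoped to formants below the pole.
* **Radiation.**  A flanged-piston load at the lips: reactance from the
  end correction (scaled by the OECC for a finite flange) and, by
  default, the piston resistance $1 - J_1(2ka)/ka$.  Because radiation
  resistance is itself a loss, the *strictly lossless* configuration
  used for benchmarking against the transcendental roots sets
  $\alpha = 0$ **and** `radiation = "reactive"`; with the resistance
  included, the upper modes of a 30 mm bore are heavily damped and
  shift a few percent — physics, not numerics.
* **Probe.**  A unit volume-velocity source drives the glottis; the
  output is the free-field pressure 3 cm in front of the lips,
  $p = j\omega\rho\,U_\mathrm{lips}\,e^{-jkr}/4\pi r$.

Formants are local maxima of the dB magnitude with a prominence
threshold (3 dB default); troughs are the mirror image.  For
antiresonance detection in lossy simulations a 20 dB prominence is a
good separator: in our uniform-tube tests the branch trough carries
~28 dB of prominence while ordinary inter-formant dips in the same
region stay below 10 dB.

The fossae-removal filter is the dB difference between the
branch-free and with-branch spectra, realised as a zero-phase filter in
the frequency domain (the equivalent of a long symmetric FIR): the
audio spectrum is multiplied by the interpolated gain with generous
zero-padding.  Because the realisation is exact on the transform grid,
a filter and its inverse (the negated curve) cancel to rounding error;
a windowed linear-phase FIR export is available for external use.

## The virtual rig

`simulateMeasurement()` emulates the measurement chain: driver FIR
$\rightarrow$ memoryless polynomial nonlinearity
($y = a_1 x + a_2 x^2 + \dots$, the simplest model that produces the
temporally separated harmonic responses the method exploits)
$\rightarrow$ optional tract FIR $\rightarrow$ additive Gaussian
microphone noise.  All randomness derives from the rig seed and the
repeat index, so outputs are bit-reproducible.  The default fixture SNR
is 80 dB, representative of a 24-bit recorder in an anechoic chamber;
at much lower SNR the band edges of the $-3$ dB/octave sweep run out
of excitation energy and the subtracted spectra degrade there first —
the dedicated averaging tests use a deliberately noisy rig (40 dB) to
exercise the $1/\sqrt{n}$ law.  `makeVoiceFixture()` generates a
harmonic pulse train filtered by the rig tract, a stand-in for a sung
vowel when demonstrating the removal filter.

What the rig does *not* emulate: loudspeaker electro-mechanics beyond
a memoryless polynomial, room reflections (the reference experiment was
anechoic), and microphone directivity.  Passing the recovery tests
therefore shows the *pipeline* is correct and transducer-independent at
desk scale; it does not certify behaviour against hardware
pathologies outside this model.

## Worked example

```{r example, eval = FALSE}
spec <- sweepSpec(duration = 2, fs = 48000)
ess <- applyFadeOut(applyFadeIn(generateESS(spec), spec), spec)
inv <- buildInverseFilter(ess, spec)

rig <- rigSpec(driverIr = 0.4 * as.numeric(signal::fir1(64, 0.85)),
               distortionCoeffs = c(1, 0.1, 0.03),
               tractIr = 1, noiseSnrDb = 80, seed = 7, fs = 48000)
recs <- lapply(1:3, function(r) simulateMeasurement(ess, rig, TRUE, r))
refs <- lapply(1:3, function(r) simulateMeasurement(ess, rig, FALSE, r + 10))
tf <- measureTransferFunction(recs, refs, inv, spec)

tube <- tubeSpec(142, 15, 2)
transcendentalModes(tube, airModel(5), 5000)
#> 551.7 1665.1 2796.5 3942.8
```

## Numerical choices and limitations

* Convolutions run in the frequency domain; they agree with direct
  convolution to ~1e-9 relative (tested), so the fast path is the only
  path.
* Root isolation in `transcendentalModes()` cannot produce ties:
  every root is a simple zero inside its own quarter-period bracket.
* The automatic isolation window assumes the linear response dominates
  its neighbourhood; for systems whose impulse response decays by less
  than 60 dB within the inter-harmonic gap, pass explicit bounds.
* Test and example problem sizes (2 s sweeps at 48 kHz, 2 Hz
  simulation grids, ~50-element tracts) are the package's scaling
  choice; every quantity checked is scale-free (lags scale with $T$,
  mode frequencies with geometry).
* The dB-magnitude driver subtraction discards phase by design; the
  resulting tract spectra support formant/trough analysis, not
  phase-sensitive resynthesis.
* 3-D effects — transverse modes, cavity eigenmodes above the
  plane-wave limit, viscothermal boundary layers — are not modelled;
  above ~5 kHz the 1-D results are indicative only, which is also why
  the analytic benchmark is run below that limit.
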