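# sweeptract

Transducer-independent measurement and 1-D simulation of vocal-tract
transfer functions, built around the exponential sine sweep (ESS)
technique, with analytic predictors for the antiresonance that the
piriform fossae — the paired closed side branches at the bottom of the
pharynx — carve into the voice spectrum between 4 and 5 kHz.

The package is for voice scientists and acousticians who want to

* measure the transfer function of a physical tract model (e.g. a
  3-D-printed replica) with an ordinary loudspeaker and probe
  microphone, without the transducers' own frequency response or
  harmonic distortion contaminating the result;
* predict tube resonances and side-branch antiresonances in closed
  form; and
* simulate a vocal-tract area function with piriform side branches and
  study the resulting spectral trough and formant shifts.

## The method in brief

The excitation is the exponential sine sweep
`x(t) = sin(2π f1 L (exp(t/L) − 1))`, `L = T / ln(f2/f1)`, whose
instantaneous frequency climbs exponentially from `f1` to `f2` and
whose spectrum falls at −3 dB/octave.  Convolving a recording with the
time-reversed, amplitude-modulated sweep (the *inverse filter*)
compresses the linear response to an impulse at lag `T`, while the
k-th-order harmonic distortion of the playback chain lands at
`T − L·ln k` — earlier on the time axis, where it is windowed away.
Sine-squared fade envelopes suppress the broadband bursts caused by
the sweep's abrupt start and end.  An FFT of the isolated linear
impulse response, complex-averaged over three repeats and subtracted
(in dB) from a driver-only reference, yields the transfer function of
the tract alone.

Resonances of a closed–open tube are the roots of the 1-D condition
`cot(kL) = k δ(k)`, with `δ(k)` the frequency-dependent open-end
correction (Dalmont fit, scaled by the open-end correction coefficient
for a finite flange); the piriform antiresonance follows the
quarter-wave formula `F = c / 4L_sinus`.  The 1-D waveguide simulator
propagates exact transmission-line chain matrices over the area
function, attaches closed side branches as parallel admittances, and
terminates in a flanged-piston radiation load.

## Worked example

```r
library(sweeptract)

air <- airModel(5)                    # anechoic chamber at 5 degC
#> AirModel: 5 degC, c = 334.32 m/s, rho = 1.2 kg/m^3

# Piriform antiresonance for a mezzo-soprano's measured sinus length
piriformAntiresonance(piriformGeometry(17.63, 3.47, 44.58), air)
#> 4741 Hz (rounded)

# Across one singer's five vowels (bundled MRI-derived geometries)
pg <- piriformGeometries()
antiresonanceSummary(pg$geometries[pg$table$singer == "Barnaby"], air)
#> mean 4182 Hz, sd 179 Hz

# Benchmark cylinder (142 mm long, 15 mm radius, 2 mm flange)
transcendentalModes(tubeSpec(142, 15, 2), air, 5000)
#> 551.7 1665.1 2796.5 3942.8

# 1-D simulation: a 19 mm closed side branch carves a trough ...
fg <- seq(100, 8000, by = 2)
tract <- areaFunction(c(0, 142), rep(pi * 15^2, 2))
tfW <- simulateTF(tract, list(sideBranch(25, 19, 180)),
                  wallModel(0.02, air), fg, flangeWidthMm = 2)
tfO <- simulateTF(tract, list(), wallModel(0.02, air), fg,
                  flangeWidthMm = 2)
findTroughs(tfW, prominenceDb = 20)
#> 4396        # Hz; quarter-wave prediction c/4L = 4399

# ... and repels the formants away from it
repulsionAnalysis(tfW, tfO, 4399)
#>   order fWithoutHz fWithHz shiftHz  side signConsistent
#> 1     1        552     534     -18 below           TRUE
#> 2     2       1664    1606     -58 below           TRUE
#> 3     3       2786    2662    -124 below           TRUE
#> 4     4       3908    3632    -276 below           TRUE
#> 5     5       5028    5284     256 above           TRUE
#> 6     6       6150    6266     116 above           TRUE
#> 7     7       7290    7344      54 above           TRUE
```

Formants below the 4.4 kHz antiresonance shift down, formants above it
shift up — the "formant repellent" signature of the fossae.  The
`fossaeRemovalFilter()` / `applyFilter()` pair turns the dB difference
of the two spectra into a zero-phase filter that makes a voice recorded
*with* fossae sound as it would *without* them.

A full synthetic measurement (driver with distortion → tract → noisy
microphone → deconvolution → driver subtraction) is available through
`rigSpec()` / `simulateMeasurement()` / `measureTransferFunction()`;
see the methods vignette (`vignettes/sweeptract-methods.Rmd`) for the
model details and design choices.

## Command line

A thin Rscript front end ships in `inst/scripts/sweeptract.R`:

```sh
Rscript sweeptract.R sweep    --duration 10 --fs 192000 -o sweep.wav
Rscript sweeptract.R measure  --rec r1.wav r2.wav r3.wav --ref d1.wav d2.wav d3.wav -o tf.csv
Rscript sweeptract.R tube     --length 142 --radius 15 --flange 2 --temp 5
Rscript sweeptract.R fossa    --table geoms.csv
Rscript sweeptract.R simulate --tract vt.csv --branch fossa.yaml --with-and-without -o tf.csv
Rscript sweeptract.R rig      --seed 7 -o fixtures/
```

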