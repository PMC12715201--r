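# odontoPulse

Detection and characterization of odontocete pulsed vocalizations and
whistles from calibrated passive-acoustic recordings.

Dolphins produce broadband **pulsed signals** — echolocation clicks,
burst pulses and buzzes, emitted in trains — and narrow-band
frequency-modulated **whistles**. odontoPulse implements, as a tested
and reusable R package, the automated part of a field processing
pipeline for such recordings:

* calibrated WAV I/O (ADC counts → µPa through the hydrophone
  sensitivity chain), 30-s segmenting and a zero-phase 5 kHz Butterworth
  high-pass pre-filter;
* pulse detection with the **Teager–Kaiser energy operator**
  (Ψ[xₙ] = xₙ² − xₙ₋₁xₙ₊₁), a matched pair of Gaussian (MAF1) and
  rectangular (MAF2) averaging filters of equal gain, and the
  amplitude-invariant **filter difference ratio**
  FDR(n) = (h₁(n) − h₂(n))/h₁(n), thresholded at 85% of the segment
  peak with a 10 dB SNR gate;
* train building with an adaptive inter-pulse-interval rule and
  classification by mean IPI (**buzz** < 4.9 ms, **burst pulse**
  4.9–15.5 ms, **echolocation click** > 15.5 ms);
* the six standard per-pulse parameters (IPI, SPLpp, 95%-energy
  duration, peak frequency, −3 dB and −10 dB bandwidths) and per-train /
  dataset summaries;
* the thirteen standard whistle contour characteristics, contour
  joining, rule-based typing into the six tonal classes, SNR grading and
  harmonic detection;
* a calibrated **synthetic-scene generator** (Gabor click trains, FM
  whistles, Gaussian noise) with exact ground-truth manifests, so every
  stage is testable without field data;
* batch reporting in the dataset layout: one `PulseTrain_NNN/` folder
  per train with per-pulse WAV clips and a tab-separated
  `PulseParameters.txt`, plus `ClickTrains.csv`, `BurstPulseTrains.csv`,
  `BuzzTrains.csv` and `Results.csv`.

## Worked example

Simulate a 20-s scene containing one train of each class, run the
detector, and score it against the ground truth:

```r
library(odontoPulse)

spec <- sceneSpec(20, noise_level_db = 110, trains = list(
  trainSpec(12, 0.060, f0 = 95e3, splpp_db = 168),   # click train
  trainSpec(20, 0.010, f0 = 55e3, splpp_db = 168),   # burst pulses
  trainSpec(40, 0.0025, f0 = 75e3, splpp_db = 168))) # buzz
scene <- genScene(spec, seed = 1)
writeSceneWav(scene, "scene.wav")

report <- runPipeline("scene.wav", "output")
report$train_table[, c("serial", "start_s", "NumP", "Mean_IPI",
                       "Mean_Fpeak", "Mean_SPLpp", "label")]
#>   serial   start_s NumP  Mean_IPI Mean_Fpeak Mean_SPLpp       label
#> 1      1  4.812936   12 60.000000   94.99219   168.0039       click
#> 2      2 10.186127   20  9.999817   54.98438   168.0062 burst_pulse
#> 3      3 15.089313   40  2.500000   75.05156   168.0059        buzz

evaluateScene(report, scene$manifest)
#> $recall                 : 1
#> $precision              : 1
#> $n_false_alarms         : 0
#> $median_timing_error_ms : 0
#> $max_timing_error_ms    : 0.00174
#> $n_trains_detected      : 3
#> $n_trains_truth         : 3
#> $class_agreement        : 1
```

All 72 injected pulses are recovered (recall 1, no false alarms) with a
worst-case timing error of 1.7 µs — one sample at 576 kS/s. The three
trains land in the intended classes, the mean IPIs reproduce the
generator settings (60 / 10 / 2.5 ms), the mean peak frequencies recover
the Gabor carriers (95 / 55 / 75 kHz within one spectral bin), and the
mean SPLpp matches the requested 168 dB re 1 µPa. `output/` now holds
`PulseTrain_001` … `PulseTrain_003`, each with its per-pulse clips and
`PulseParameters.txt`, and the three class CSV tables.

A thin command-line wrapper with `simulate` / `detect` / `evaluate` /
`summarize` subcommands is installed at `exec/odontopulse` inside the
package.

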