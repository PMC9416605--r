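---
title: "semgflex: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{semgflex: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgflex)
```

# The problem

Low-cost wearable forearm bands measure surface electromyography (sEMG)
with four dry-electrode sensors per arm, sampled at 1000 Hz by a 12-bit
ADC whose 0-3 V output is centered on a 1.5 V reference. A test protocol
records three cycles of six wrist/hand gestures (flexion, extension,
ulnar deviation, radial deviation, power grip, lateral grip; `M1`-`M6`),
giving 18 movement instances per arm and session. semgflex implements the
full offline path from the wire protocol to gesture classification:

1. **protocol** - 17-character datagram framing (start marker + four
   zero-padded 4-digit ADC fields), ADC/voltage conversion, and
   semicolon-separated session storage;
2. **synth** - a calibrated synthetic cohort generator;
3. **segmentation** - the five-stage division algorithm that cuts a
   session into labeled movement instances of exactly 13,000 samples;
4. **features** - two FFT-magnitude representations (full half spectrum;
   banded averages);
5. **classifier** - a two-layer sigmoid/softmax feedforward network over
   the six classes, with the mode x hidden-size experiment grid.

# The synthetic generator

Real multi-subject sEMG recordings of this protocol are not publicly
deposited, so the package ships a generator whose defaults *are* the
study conditions: 15 subjects x 2 forearms x 3 cycles x 6 movements =
540 movement instances, 90 per class.

**Signal model.** Each movement burst is zero-mean Gaussian noise
band-limited by a fourth-order zero-phase Butterworth filter and shaped
by a trapezoidal envelope following the protocol timing: 4 s cue at
baseline, a 3 s linear preparation ramp, a 3 s hold plateau, and a 0.5 s
release. Band-limited modulated noise is the standard sEMG surrogate: it
reproduces the amplitude and spectral structure the pipeline exploits
while making no claim about motor-unit physiology, electrode-skin
impedance or motion artifacts. Consequences for interpretation: passing
tests demonstrate the pipeline's correctness and its behaviour under the
assumed structure (burst-like activity, class-distinct spectra), not
performance on real recordings, where class spectra overlap heavily and
the printed real-data accuracies (85.2% banded, 76.5% full-spectrum at
their best hidden sizes) are the relevant reference.

**Amplitude calibration.** Per-sensor plateau peak amplitudes (volts,
centered) default to the printed calibration of the reference
recordings: sensor 1 peaks during extension (about -1 to 0.8 V, so
amplitude 0.90 V), sensor 2 during radial deviation (0.15 V), sensor 3
during power grip (0.21 V), sensor 4 during ulnar deviation (0.53 V).
The remaining entries of the 6 x 4 amplitude matrix are unprinted; they
are set to 0.05-0.15 V - roughly 10-25% of the column dominant - chosen
so that every one of the four printed dominant pairs stays dominant
(a flat 25%-of-dominant rule would let extension's crosstalk exceed
radial deviation's 0.15 V maximum on sensor 2). The realized hold peak
is normalized to the profile amplitude exactly, so the extension
peak-to-peak span lands in the printed 1.8 V neighbourhood.

**Spectral signatures.** Movement bands default to 60 Hz-wide passbands
centered at 70, 120, 170, 220, 280 and 340 Hz - inside the 20-450 Hz
sEMG range, distinct per class so the six classes are separable by their
spectra, which is precisely the assumption behind FFT features. A
per-(subject, arm) jitter (+-10% amplitude, +-10 Hz center) provides
between-subject variability. The hold plateau carries a mild quadratic
dome (30% droop at the edges) so the burst's realized maximum
concentrates near the plateau centre, as sustained contractions do.

**Slot length: 14 s.** The protocol nominally spans 10 s per movement
(4 + 3 + 3), yet homogenization targets 13,000 samples = 13 s; recorded
slots must therefore exceed 13 s. The generator reconciles this with a
14 s default slot (the 10 s protocol followed by release and rest), so
the trimming step is always exercised.

**Determinism.** One master seed; every burst, gap and jitter draws from
a substream derived by hashing (subject, arm, cycle, movement) indices,
so any single burst is reproducible in isolation and identical
specifications yield bit-identical cohorts.

# The division algorithm

Segmentation uses sensor 1 as the reference: extension produces its
largest bursts. The stages, with the numerical choices the algorithm
fixes where the procedure is underdetermined:

1. **Channel split** - codes to centered volts, one trace per sensor.
2. **Peak detection** - rectify, smooth with a 200 ms moving-RMS
   envelope, keep regions above 50% of the global envelope maximum
   (bridging sub-0.5 s gaps), require burst separation of at least 60%
   of the expected cycle length, and take the rectified-signal maximum
   inside each of the `nCycles` strongest bursts. A flat or sub-threshold
   trace is a hard error, not an empty result.
3. **Cycle windows** - the slot length is estimated from the span
   between the last burst anchor and the end of the record, which covers
   `6 - 1 - anchorFrac` slots and contains no inter-cycle rest gap. The
   often-suggested alternative - median inter-peak spacing divided by
   six - systematically overestimates the slot by one sixth of the rest
   gap (333 samples at defaults), enough to push late slots out of
   alignment; it is retained only as a cross-check and as the fallback
   when trailing data makes the end-anchored estimate inconsistent.
   Burst midpoints, where available, are used as anchors instead of the
   raw peaks: a thresholded interval midpoint is far more stable than
   the argmax of a noisy plateau. `anchorFrac` defaults to 0.56: under
   the protocol timing the sustained activity of a slot spans roughly
   seconds 5.5-10.25 of 14, so its midpoint sits at 56% of the slot
   (peak-at-slot-centre, `anchorFrac = 0.5`, is what the description of
   the procedure suggests but leaves a systematic 1.5 s bias).
4. **Six-way split** - each window divides into six contiguous
   near-equal slots in protocol order; remainders go to the last slots
   (lengths differ by at most one sample). The same ranges apply to all
   four sensors, so channels never drift apart.
5. **Homogenization** - symmetric trim to 13,000 samples:
   `floor(d/2)` dropped from the front, `ceiling(d/2)` from the back
   (the odd sample comes off the back). Shorter inputs error unless
   zero-padding is explicitly enabled.

All ranges in interfaces and sidecar files are 1-based and inclusive,
the R convention.

The generator's ground-truth sidecar records, per instance, the slot
range, the active range, and the *realized* position of the sensor-1
rectified maximum inside the extension slot. The peak-alignment checks
compare detected peaks against that realized maximum: when the detector
finds the right burst the two coincide, so the +-250 ms tolerance is a
right-burst test rather than a test of where noise happened to peak
within a 3 s plateau (the realized maximum of a noisy plateau is not
concentrated at its centre, so "distance to the plateau centre" would
not be a meaningful error measure at that tolerance).

# FFT features

Both representations start from the magnitude of the 13,000-point DFT of
each sensor (no windowing or detrending is applied before the
transform, and magnitudes are not normalized per instance - input
scaling is the classifier's responsibility).

**Full half spectrum:** positions 1-6,500 (bin resolution 1000/13000 ~
0.077 Hz) with positions 1-5 zeroed. The five lowest positions are the
DC region and carry no gesture information; zeroing them (rather than
dropping them) preserves the printed dimensions of 6,500 per sensor and
26,000 per instance. Four sensors are concatenated in order.

**Average of sequences:** in 1-based indexing, bin *i* of 50 is the mean
of `|FFT|` positions `5 + 130(i-1)` through `130 i` - 126 values per
bin, with the four positions between consecutive bins skipped exactly as
the band pointers advance, and bin 50 ending at position 6,500. Each bin
therefore summarizes one ~10 Hz band, 50 values per sensor and 200 per
instance. The banding is reproduced literally, including its inter-bin
gaps: a pure 50 Hz tone falls at 1-based position 651, inside the
skipped gap 651-654, and is invisible to the literal bands while a 49 Hz
tone (position 638) lands squarely in bin 5. Users who consider the gap
a pseudocode artifact can pass `cleanBins = TRUE` for contiguous
130-value bins (DC region zeroed); the default is fidelity to the
published banding, and the tests pin down both behaviours.

# The classifier

A two-layer feedforward pattern-recognition network: logistic-sigmoid
hidden layer (34, 49 or 63 units in the experiment grid), softmax output
over the six classes, cross-entropy loss. Choices the package makes
where the original toolbox defaults are unstated, all recorded in every
saved model:

* **Split**: stratified random 0.70/0.15/0.15 train/validation/test.
  Largest-remainder quotas per class with a parity-alternating tie-break
  give exactly 378/81/81 at the default 540 instances.
* **Preprocessing**: per-feature standardization fitted on the training
  partition, z-score by default (`scaling = "minmax"` and `"none"` are
  selectable). Min-max mapping to [-1, 1] is the classic toolbox choice,
  but FFT magnitudes are heavy-tailed: one large training maximum pins
  almost every scaled value near -1, and on the 540-instance full-mode
  matrix that offset drives full-batch training into the
  uniform-prediction stationary point of the softmax (training loss
  exactly log 6) from which it never escapes. Z-scoring centers the
  inputs and trains cleanly in both feature modes; the choice is
  recorded in every saved model.
* **Optimizer**: full-batch Adam (step 0.01, standard moment constants),
  deterministic given the seed; weights initialized Glorot-uniform.
* **Stopping**: `maxEpochs = 1000` cap; early stop after 6 consecutive
  epochs without a validation-loss improvement of at least
  `minDelta = 1e-4`, restoring the best-validation weights. The cap
  comfortably exceeds the 91-134 epochs reported for the reference runs.
* **Evaluation**: argmax decisions; per-partition confusion matrices
  with per-class sensitivity (diagonal / row sum) and precision
  (diagonal / column sum, defined as 0 for empty columns).

The real-data accuracies of the reference experiment are *not*
reproduction targets - the 15-subject dataset is not deposited. On the
synthetic cohort the classes are separable by construction, so the
meaningful checks are: average-mode test accuracy at least 0.90 (the
threshold itself validated against an independent nearest-centroid
baseline that must exceed 0.85), a label-shuffled control at chance, and
the ordering claim that banded 200-value inputs train much faster than
26,000-value full spectra. The chance control is reported as the mean
over several shuffle replicates: a near-initial network predicts almost
constantly within each (spectrally tight) true class, so a single
replicate's test accuracy behaves like ~6 correlated draws at p = 1/6
and has a standard deviation near 0.15; averaging 8-10 replicates brings
the estimate safely inside the 1/6 +- 0.08 band whenever the control
truly is at chance.

# Problem sizes and degenerate inputs

The test suite runs the full default cohort (540 instances) for the
end-to-end checks, a 180-instance cohort for classifier unit tests, and
a 36-instance cohort for everything structural; segmentation robustness
uses 20 independently seeded single-arm sessions. Full-mode networks in
timing comparisons run both modes for the same fixed number of epochs so
only per-epoch cost is compared; wall times are reported but never
asserted against absolute values.

Degenerate inputs are errors with named stages: flat traces (no
activity), fewer detected bursts than cycles, windows shorter than six
samples, segments shorter than 13,000 samples without padding enabled,
out-of-range ADC codes, malformed frames (wrong length, marker, or
non-digit payload), token counts not divisible by the channel count, and
validation-free configurations combined with patience-based stopping.

# Known limitations

* The generator's class separability is optimistic; real forearm sEMG
  has heavy spectral overlap between gestures. Accuracy numbers on
  synthetic cohorts characterize the pipeline, not the sensor.
* The cycle-window estimator assumes the recording ends near the end of
  the last cycle (true for the protocol's storage workflow); long
  trailing idle stretches shift it onto the inter-anchor fallback.
* Left/right streams are treated as independent sessions; no
  frame-level synchronization between bands is attempted.
* The live UDP path is a thin replay layer over connections; all tested
  I/O is file-based.
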