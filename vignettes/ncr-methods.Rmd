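---
title: "Neural code reliability: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural code reliability: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decoding model

`ncrtools` measures how *reliably* a neuron (or a group of neurons) encodes
a continuous complex sound. The premise is that with a reliable code,
similar stimuli elicit similar spiking patterns; reversing it, the stimulus
behind a spiking pattern should be predictable from the stimuli behind the
most similar other patterns. Concretely, for every query window of the
recording, the decoder

1. converts spike trains into per-window code vectors — either a *temporal
   code* (spike counts in 0.5 ms bins convolved with a peak-normalized 9 ms
   Hann taper, compared by Euclidean distance) or a *rate code* (the spike
   count within the window);
2. finds the `k = 100` candidate windows with the most similar code
   vectors, excluding every candidate that overlaps the query in time
   (without this exclusion the query would trivially retrieve itself);
3. averages the stimulus spectrogram segments behind those `k` patterns,
   overlaid at the stimulus-to-response lags (default −10 ms and 0 ms),
   into a predicted spectrogram;
4. scores the prediction by the Pearson correlation with the actual
   spectrogram over all covered pixels. The *neural code reliability* is
   `NCR = log10 |Corr|`: non-positive, higher is better, and the absolute
   value reflects that a consistently anti-correlated prediction carries
   the same information as a correlated one.

`Corr(t)` (across frequency, per time bin) and `Corr(f)` (across time, per
frequency channel) localize the performance in time and frequency; the
`Corr(f)` profiles are the substrate of the pair decomposition below.

Group decoding concatenates the per-unit code vectors, so a pair of units
lives in a doubled code space with no further changes. A unit concatenated
with itself scales every distance by √2 and leaves the decoding invariant
bit for bit — a property the test suite asserts, since it underpins the
pair analyses.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| window length | 0.1 | s | the analysis window holding a spiking pattern; NCR typically peaks or plateaus near 100 ms across stages |
| candidate stride | 0.01 | s | spacing of candidate windows; denser grids improve neighbor quality at linear cost |
| evaluation stride | 0.05 | s | spacing of query windows; controls how often the stimulus is re-predicted |
| k | 100 | – | neighbors averaged per query |
| lags | −0.01, 0 | s | stimulus offsets averaged in the reconstruction |
| temporal-code bin | 5e-4 | s | resolution of the smoothed spike trace |
| Hann support | 9e-3 | s | temporal-code smoothing; 19 taps at 0.5 ms |
| exclusion halfwidth | = window | s | overlap exclusion for candidates |
| null percentile | 95 | % | upper percentile of the pooled null NCR defining significance |

The candidate/evaluation strides (10/50 ms) are a cost–accuracy
compromise: the distance search is a dense matrix product over all
candidate–query pairs and the defaults keep a full 300 s calibration
tractable on one CPU while leaving ~30 000 candidates per query pool.

## The synthetic stimulus

The random double sweep (RDS) emulates a 5-minute, two-voice stimulus in
which each voice is a pure tone whose frequency wanders over 2–90 kHz with
all frequency-modulation power below 10 Hz. Each voice is generated as a
*reflected integrated process*: white noise is low-pass filtered at the FM
cutoff (zero-phase, in the Fourier domain), scaled to an RMS FM speed of
10 octaves/s, integrated from a random starting frequency, and reflected
at the band edges. Two properties motivated this construction:

* a reflected random walk has a **uniform stationary distribution**, so the
  voices cover the whole band evenly, as a band-covering sweep stimulus
  must — a low-passed noise *position* process (the more obvious choice)
  concentrates mid-band;
* the trajectory spectrum falls as 1/f² below the cutoff, so the
  derivative kinks introduced by reflection leave far less than 1% of the
  FM power above the cutoff (asserted in the tests).

The RMS speed of 10 oct/s makes a voice traverse the 5.5-octave band on a
~3 s timescale, matching the pace visible in published excerpts of this
stimulus class; it also sets the stimulus correlation time and thereby the
effective number of independent pixels behind every correlation.

Rendering places a unit-peak Gaussian ridge (SD 0.15 octaves) per voice on
a 45-channel log-spaced axis; coincident voices are combined by maximum so
they do not double the energy. By default each channel row is then divided
by its long-run mean (`equalize = TRUE`), emulating the flat-spectrum
speaker calibration of the protocol. This step matters more than it looks:
band-edge channels otherwise collect systematically less ridge mass, and
finite-realization band occupancy is never exactly flat. Any average of
stimulus segments — including the reconstruction obtained from
stimulus-*independent* Poisson spike trains — inherits that static channel
profile, which puts a duration-independent floor of roughly −1.4 under
every NCR value. Equalization removes the shared static profile, so null
reconstructions score at the level of their genuine dynamic structure
(median null NCR near −2.2 under the reference conditions). The equalized
grid is rescaled by its pre-equalization grand mean so that RDS and tone
renderings share an energy scale and one encoder gain means the same thing
in both protocols.

What the generator does *not* emulate: amplitude modulation of the voices,
harmonics, filterbank temporal envelopes, and background noise. Passing
tests on this stimulus therefore demonstrate the decoder's behavior on an
idealized two-ridge spectrogram, not performance on arbitrary natural
sounds.

## Model neurons

Two encoder families provide ground truth. Homogeneous Poisson units are
the stimulus-independent null. Linear–nonlinear–Poisson (LNP) units filter
the spectrogram with a separable Gaussian kernel (SD `bandwidth` octaves ×
`kernelWidth` s, unit sum in each dimension), half-wave rectify, apply a
latency, scale by a gain over a baseline rate, and draw spikes by per-bin
Bernoulli sampling at 0.5 ms (warning if rate·dt exceeds 0.1), followed by
Gaussian spike-time jitter and absolute-refractory thinning (delete any
spike closer than the refractory period to its predecessor — the simplest
reproducible choice). Rectification is half-wave because the fixture must
guarantee non-negative rates. The encoders deliberately omit adaptation,
synaptic depression and cortical state fluctuations; they are controllable
ground truth, not a biophysical auditory-nerve model.

## The null calibration

Decoding a stimulus-independent spike train still yields a nonzero
|Corr| by finite sampling. `calibrateNull()` therefore decodes ≥100
homogeneous Poisson trains (rates log-spaced over 2–40 sp/s) under both
codes against the same stimulus and takes an upper percentile of the
pooled null NCR distribution as the significance threshold. The
threshold published for this framework (−2.12) is reported without the
rule deriving it from the null distribution; this package defaults to
the 95th percentile, keeps the percentile configurable, and records it
in the result. The regression of null NCR on firing rate is flat (asserted), so
one pooled threshold serves all rates and both codes.

## Pair synergy and redundancy

For a pair, the per-frequency absolute profiles `c1(f)`, `c2(f)` (each
unit alone) and `c12(f)` (concatenated pair) are decomposed as

* `redundancy(f) = min(c1, c2)(f)` — the information obtainable from
  either unit alone (the minimum rule);
* `synergy(f) = c12(f) − max(c1, c2)(f)` — what the pair adds beyond its
  better member.

The identity `c12 = synergy + c1 + c2 − redundancy` then holds bin-wise by
construction. The decomposition is stated verbally through the minimum
rule; adopting it forces the synergy definition above, and this pair is
the unique choice that reproduces all three normalization limits exactly:
normalized synergy — `100·synergy(f)/max(c12, c1, c2)(f)` averaged over
valid bins — reaches +100% when both individual profiles vanish while the
joint one does not, −100% when the joint profile vanishes while both
individual ones do not, and 0 when the joint profile equals the better
individual one. Normalization is applied per bin *before* averaging; the
printed limits are only attainable this way. Bins where all three
profiles are zero (or any is missing) are excluded and counted.

Restricted variants decode the pair on masked windows only — spikes-only,
silence-only, or the combinatorial code (one unit firing while the other
is silent; evaluated for both role assignments) — while `c1` and `c2`
always come from the unrestricted single-unit decodes, so restricted
synergy is measured relative to the whole spike train. The reference is
ambiguous about whether restricted analyses also restricted the candidate
pool; this package restricts both the query and the candidate sets, the
reading under which "decoding from silence" uses only what silence can
retrieve.

## STRFs

`buildSTRF()` follows the tone-protocol recipe: per-frequency PSTHs at
1 ms bins averaged over eight repetitions, 5×5 uniform smoothing
(reflective edges — the choice is not stated in the protocol), baseline
statistics from the first 10 ms, and a significance mask at baseline mean
plus six baseline SDs. The baseline SD is taken from the *raw* PSTH bins:
it carries the per-bin counting noise, which is the scale a genuine
response must beat. (Taking the SD of the already-smoothed grid instead
makes the criterion ~5× more liberal and marks ~30% of untuned Poisson
units significant; with the raw-bin SD the false-positive rate in the test
suite is zero.) A silent baseline falls back to the Poisson SD of the
baseline rate floored at one expected spike. First-spike latency (first
smoothed bin at best frequency above the criterion) and response duration
(total significant extent at best frequency) are package conventions for
features the field names without formulas. Tones are rendered as
rectangular-duration ridges (50 ms), without gamma-tone envelopes.

## Numerical choices

* Distance ties at the k-th neighbor are resolved by seeded uniform
  sampling among candidates within a *relative* tolerance (10⁻⁹ of the
  k-th distance) — a relative tolerance keeps tie membership invariant
  under a uniform rescaling of all distances, which the self-pair
  invariance requires.
* Neighbor segments are accumulated in candidate-index order so the
  floating-point average does not depend on how equal distances were
  ordered.
* A constant (zero-variance) prediction is a defined no-information
  sentinel: `corrSigned = NA`, `ncr = −Inf`; it is never silently dropped.
* The proximity complexity trace floors the octave distance at 10⁻³
  octaves before the log; the floor is recorded in the trace metadata.
  The trace reports the log-distance itself (smaller = closer); the sign
  convention is left to the user.
* The dissimilarity window (100 ms) matches the analysis window by
  default; it is a package default, not a stated protocol value.
* Complexity traces are block-averaged onto the reliability time grid
  before correlating.

## Problem sizes

The test suite and the acceptance script run the full-scale null
calibration exactly as specified (300 s stimulus, 100 Poisson trains, both
codes, k = 100) — about 12 minutes on one CPU. Encoder-recovery and
code-transition checks use a 60 s stimulus with 20 seeds each; these sizes
give stable medians while keeping a complete run within half an hour.

## Known limitations

* The stimulus generator produces an idealized two-ridge spectrogram;
  conclusions about natural-sound decoding require real recordings.
* The LNP fixture has no adaptation; trends that depend on
  adaptation-driven reliability changes along the pathway are outside its
  reach.
* Decoding cost grows linearly in candidate-pool size and code dimension;
  populations much larger than pairs are feasible but slow on one CPU.
* The significance threshold is calibrated against the synthetic stimulus
  actually decoded; thresholds are not transferable across stimuli with
  different correlation structure.
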