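---
title: "Sparse coding of auditory-nerve responses as a model of pitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse coding of auditory-nerve responses as a model of pitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`sparsepitch` treats pitch extraction as a three-stage readout of the
auditory-nerve (AN) population response.

**Periphery.** A pressure waveform in pascals (sampled at 100 kHz,
calibrated as `20e-6 * 10^(dB/20)` Pa per component) is filtered by `N`
fourth-order gammatone filters with unit gain at their characteristic
frequency (CF) and bandwidth `1.019 * ERB(CF)`, where
`ERB(f) = 24.7 (4.37 f/1000 + 1)` Hz. CFs are uniform on the ERB-number
scale `21.4 log10(4.37 f/1000 + 1)` between 125 Hz and 20 kHz, so channel
density matches cochlear frequency resolution. The inner-hair-cell stage is
half-wave rectification followed by a first-order low-pass at 1 kHz: fine
structure is preserved at low CFs and progressively replaced by the envelope
above the cutoff, reproducing the gradual loss of phase locking. In
`"saturating"` mode a memoryless `knee * tanh(x / knee)` compression
(knee 0.01 Pa ≈ 54 dB SPL) precedes rectification, so a 30 dB SPL tone stays
essentially linear while a 90 dB SPL complex saturates and spreads across
the array. Of a 15 ms simulation only the last 5 ms are kept — the discarded
prefix doubles as filter settling time (filters are causal; no zero-phase
trickery) — and the time-by-CF matrix is divided by its global maximum.
This periphery is a deliberately simple, fully documented front end with
the three properties the model actually exploits: tonotopy, loss of phase
locking with CF, and high-level compression/spread. It is *not* a
biophysical cochlea; the interface (`simulateAN`) isolates it so a richer
model could be substituted.

**Sparse coder.** The vectorized response is approximated as `D h` with
`h >= 0` sparse, where the dictionary columns are the periphery's own
(peak-normalized, vectorized) responses to probe stimuli: pure tones of one
frequency per atom (`"sine"` family), or six-harmonic complexes with `1/k`
amplitudes (`"stack"` family, fundamental capped at 20 kHz / 6 to keep all
components inside the CF range). Atom frequencies are ERB-spaced — linear
spacing would waste most atoms above 5 kHz. For stimuli of unknown phase
(rippled noise, recordings) each frequency is represented by `g` atoms with
probe phases `2 pi k / g`; their coefficients do not compete and are summed
after solving, a simplified group lasso. The solver is plain ISTA from
`h = 0`: `h <- soft(h + (1/alpha) D'(v - D h), lambda/(2 alpha))` with
`alpha` a 1.05-inflated power-iteration bound on the top eigenvalue of
`D'D`. This update minimizes `1/2 ||v - D h||^2 + (lambda/2) ||h||_1`; the
`lambda/2` is kept as stated in the update rule rather than "corrected" to
the textbook `lambda`, and all oracle tests target the matching objective.

**Harmonic sieve.** The collapsed coefficients are linearly interpolated
onto `P = 15 M` ERB-spaced candidate pitches (zero outside the dictionary
range, clipped at zero) and scored by the template matrix
`G[i, j] = sum_n exp(-(f_j - n f_i)^2 / (2 sigma_i^2))`, one row per
candidate pitch, harmonics up to 20 kHz, `sigma_i = 0.2 ERB(f_i)` (ERB
argument in kHz — the Glasberg–Moore convention). `pdf = G h~ / sum(G h~)`
is a genuine unit-sum density (L1 normalization; the normalization norm is
otherwise arbitrary, and a density is the most useful convention). The
pitch estimate is the grid argmax, optionally restricted to
`[f 2^-1/2, f 2^1/2]` — the ±0.5-octave readout used throughout
psychoacoustics, which this package also adopts for experiment readouts.
Salience is the height ratio of the two tallest local maxima within that
octave; a unimodal density reports `Inf`.

## Design choices that were genuinely open

* **Scale of the L1 penalty.** With raw peak-normalized atoms the columns
  of `D` have Euclidean norms of order 10–30, so an absolute penalty of
  0.01 would be invisible next to the quadratic term and every solution
  would collapse onto least squares. Reference LASSO implementations
  sidestep this by standardizing the design matrix. The pipeline does the
  equivalent: `solverConfig(normalize = TRUE)` rescales the target and the
  atom columns to unit Euclidean norm before iterating, which makes
  `lambda` dimensionless and comparable across stimuli, levels and preset
  sizes; `lambda = 0.01` is the default throughout. The solver itself
  remains exact for raw inputs (`normalize = FALSE`), which the unit tests
  exercise against an independent coordinate-descent oracle.
* **Nonnegativity.** The iteration runs signed (the soft operator as
  defined); negatives are clamped to zero at exit, before group collapsing.
  A `"onesided"` mode applies `max(0, x - t)` throughout for users who want
  a nonnegative path; the default reproduces the plain-LASSO behaviour.
* **Stopping.** Relative objective change below `1e-6` (for `lambda = 0`,
  relative gradient norm), cap 5000 iterations; a capped run is flagged and
  warned, not hidden. `h = 0` initialization.
* **Phases** of all stimulus components default to 0 (sine phase), matching
  the zero-phase atoms; configurable per component.
* **Ties and plateaus.** Exact pdf ties return the lower frequency (and
  message); local maxima are strict 3-point maxima, plateaus take their
  left edge; maxima are read on the raw grid, unsmoothed.
* **Degenerate inputs.** An all-zero waveform yields an unnormalized zero
  response; an all-zero coefficient vector yields a uniform density flagged
  `noPitch` rather than an error or an arbitrary pitch.
* **Sieve truncation.** Template Gaussians are dropped beyond 5 standard
  deviations (relative weight `< 4e-6`), keeping `G` sparse; `P = 15 M`
  grids up to `P = 15000` fit comfortably.
* **Transposed tones** use a causal fourth-order Butterworth at
  `0.2 f_c` on the rectified modulator; the rectifier's DC is retained (a
  physical filter would pass it, and the construction does not remove it).
* **IRN levels.** Noise is scaled so its RMS equals that of a calibrated
  tone of the same nominal level, keeping tone and noise levels comparable;
  generation is bitwise reproducible from `(seed, spec, duration, rate)`.

## What the synthetic stimuli do and do not emulate

The generators produce exactly the stimulus classes of the psychoacoustic
literature the model addresses: harmonic complexes with arbitrary harmonic
subsets and common shifts, transposed tones (low-frequency timing imposed
on high-CF places), delay-and-add/subtract IRN, and synthetic notes with
decaying envelopes. They are noiseless (except IRN), perfectly calibrated,
and phase-locked to the frame — real recordings add room acoustics,
microphone coloring, vibrato and onset transients. Passing the test battery
therefore shows that the *model* reproduces the qualitative psychoacoustic
phenomena under clean conditions; it does not certify performance on real
audio, for which only the framed-note pipeline plus the WAV/AIFF loader is
provided (16/24-bit PCM and float WAV; PCM AIFF; polyphase resampling to
100 kHz; RMS recalibration to a chosen dB SPL, since recordings carry no
absolute pressure scale).

## Preset sizes

Experiments default to two presets, recorded in every runner's output:

* *desk*: `M = 250` atoms, `N = 100` channels, sieve `P = 3750` — used for
  the missing-fundamental/level-invariance battery, transposed tones
  (dictionary floor lowered to 100 Hz so the 100–500 Hz modulator grid
  stays inside it), and IRN (`g = 4` phase groups, atoms at 45 dB SPL;
  50 seeded stimuli per condition).
* *full*: `M = 1000`, `N = 200`, `P = 15000` — used for the
  resolved/unresolved and pitch-shift batteries, where dictionary
  resolution at high frequencies decides whether closely spaced unresolved
  components are separable. At coarser resolution the interpolated
  coefficient peaks are wide relative to the low-pitch template widths and
  a broad "spectral locus" candidate near the component cluster can win the
  global argmax; at `M = 1000` the ±0.5-octave readout agrees across all
  five spectral locations. (A `M = 1500 / N = 300` dictionary would be
  denser still, but its dense atom matrix alone is ~5 GB and exceeds the
  intended footprint.)

The test suite additionally uses a tiny `M = 72 / N = 48` preset for
module-level properties where absolute accuracy is not at stake.

## Known limitations

* The periphery is a stand-in: no middle ear, no dual-resonance
  nonlinearity, no adaptation, no spontaneous rates, no spiking noise.
  High-CF behaviour above ~12 kHz is only qualitatively right.
* Salience falls from resolved to unresolved spectral locations in the
  coarse sense, but is not strictly monotone across all five standard
  locations: rational-ratio template peaks (e.g. a 3:4 subharmonic matching
  two of four components) can locally inflate the second peak for some
  component placements.
* The global (unrestricted) argmax for strongly unresolved complexes can
  sit at the spectral locus rather than the fundamental at feasible
  dictionary sizes; restricted readout is the supported convention there.
* Atoms are fixed model responses; no dictionary learning is provided.
* Monaural only; no masking noise, no adaptive procedures.
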