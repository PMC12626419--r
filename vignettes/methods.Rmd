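---
title: "Methods: models, parameters and design choices in songpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in songpheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

songpheno turns raw zebra finch song recordings into interpretable,
per-bird phenotypes. This vignette documents the models behind each stage,
the tunable parameters and their defaults, the numerical choices made where
the design was genuinely open, what the synthetic song generator does and
does not emulate, and the package's known limitations. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Amplitude segmentation

The segmenter operates on the per-frame root-mean-square energy of the
bandpassed (200 Hz–9 kHz) waveform, with a frame of 2048 samples and a hop
of 512. Frames are centered and the signal reflect-padded, so frame *k* is
timestamped *k*·hop/rate seconds; onset timestamps inherit this convention.
The RMSE trace is min–max normalized to [0, 1] **per file**. Normalization
by range (rather than, say, z-scoring) was chosen so that one global
threshold pair is meaningful across recordings of different gain — the
design premise of shared-threshold segmentation.

A syllable onset is a positive crossing of the onset threshold by the first
difference of the normalized trace (units: normalized energy per frame).
Segmentation is onset-to-onset: a segment extends to the next onset, which
means it includes the silent gap after the syllable; only when no onset
follows within 300 ms is the offset placed at the first downward crossing
of the offset threshold by the RMSE itself. Segments shorter than 2 frames
are discarded as degenerate crossings. The zero-phase bandpass is a
4th-order Butterworth applied forward and backward (`signal::filtfilt`), so
filtering adds no group delay to the timestamps.

**Sub-frame onset refinement.** A 2048-sample window centered on frame
times biases detected onsets of impulsive syllables early by up to half a
frame (~30 ms at 32 kHz) — far larger than the 10 ms evaluation
tolerance. The refinement exploits a property of centered windows: for a
sharp onset, the windowed signal *energy* reaches exactly half of its local
plateau at the true onset time, independent of syllable duration. Each
`amp_trace` therefore carries an auxiliary fine energy trace (frame 256,
hop 64); the reported onset is the linearly interpolated half-rise crossing
of that fine trace near the detection frame. Detection itself — which
crossings count as onsets — still happens exclusively on the 2048/512
trace. The refinement is a default-on flag (`refine`); with it, onsets on
clean synthetic song are recovered with a median error near 3 ms, the
residual being the raised-cosine attack of the synthetic syllables.

**Matching and threshold selection.** Evaluation matches onsets one-to-one
within 10 ms (offsets within 20 ms). Because events live on a line, a
maximum matching always exists that is non-crossing, so the matcher is an
exact dynamic program over the two sorted lists (maximizing matches, then
minimizing total |Δt|); a brute-force assignment oracle backs it in the
tests. Threshold optimization evaluates a user grid and returns the pair
maximizing mean onset-F1 across birds. The optimization criterion is
*maximum* mean F1; ties break toward the lower onset threshold
(conservative: fewer missed quiet syllables).

## Syllable labeling

Per-syllable spectrograms are computed from 500 Hz–15 kHz bandpassed audio
(upper edge clamped below Nyquist at low sample rates), amplitude
normalized per rendition, STFT window 512 / hop 128, dB-scaled against the
per-syllable maximum, clipped at 870 ms, padded to the longest syllable and
flattened. Two open choices and their resolutions:

* **dB reference.** Per-syllable (not per-file) maxima, consistent with
  per-rendition amplitude normalization: cluster identity should not depend
  on how loudly a rendition was sung.
* **Dynamic range** (`dynamic_range = 40` dB). Values below −40 dB are
  clamped to the floor. With an unlimited range, the pixel distance between
  two renditions of one type is dominated by where the silent padding
  begins — i.e. by duration quantized to the 4 ms frame grid — which
  fragments types into duration modes. Limiting the range keeps the
  harmonic structure that identifies a type dominant. The value is
  overridable.

The 2-D embedding is the package's own UMAP implementation (exact
k-nearest neighbours from the Gram matrix, the standard fuzzy simplicial
set with per-point connectivity radius and log2(k)-calibrated bandwidth,
PCA initialization scaled to a 10-unit extent, and batch cross-entropy
layout optimization with negative sampling). All randomness flows from
`seed`. Clustering is the package's own HDBSCAN (mutual-reachability
single-linkage hierarchy, condensation at `min_cluster_size`,
excess-of-mass selection); points outside every selected cluster carry the
reserved `"noise"` token and are retained downstream as their own
category. If no cluster other than the root is selectable, the root is
returned as a single cluster (the pragmatic reading of "one coherent
repertoire"); the cost is that a perfectly uniform point cloud can also
come back as one cluster.

**The shared hyperparameter set.** The labeling contract is one parameter
set for all birds, not specific numbers. The shipped defaults were
calibrated on synthetic fixtures by v-measure against truth labels —
mirroring how such parameters are selected against manual annotations in
practice:

| parameter | default | rationale |
|---|---|---|
| `n_neighbors` | max(30, min(100, n/2)) | the neighbourhood must span a type's duration modes, which scale with type size |
| `min_dist` | 0 | density-based clustering downstream, not display |
| `min_cluster_size` | max(10, 0.15 n) | a zebra finch repertoire rarely exceeds a handful of types; override for richer repertoires |
| `min_samples` | 10 | moderate density smoothing; tying it to `min_cluster_size` bridges distinct nearby types |

Labeling agreement uses homogeneity = 1 − H(ref | cluster)/H(ref),
completeness = 1 − H(cluster | ref)/H(cluster), and their harmonic mean
(v-measure), with natural logs (the base cancels) and 0/0 cases defined
as 1. Alignment of predicted to reference segmentations matches onsets
within 100 ms; unmatched predictions receive the reserved reference
category `"x"`, unmatched references the reserved cluster `"1000"`.

## Syntax features

Bouts are runs of ≥ 2 syllables separated by gaps ≤ 200 ms; isolated
single syllables are dropped as putative calls (file bounds count as long
silence for this rule). The transition matrix inserts a silence state at
gaps > 200 ms, ignores transitions to and from file bounds, and
row-normalizes counts; occupancies π count all in-scope state occurrences,
silence included (a config choice; the alternative excludes silence from
π). The entropy rate −Σ π p log2 p is normalized by log2(N) with N = number
of syllable types + 1 and clipped to [0, 1]; rows without outgoing
transitions are excluded from the sum.

Putative introductory notes must (1) be within 5 percentage points of the
top silence-exit probability and (2) have a single dominant transition:
the largest outgoing probability, renormalized over non-self, non-silence
targets, above 0.5. The renormalization is deliberate — an introductory
note repeats itself a variable number of times, so its *raw* transition
probability to the motif onset rarely clears one half even when that
transition is essentially certain once the repetition ends. Putative calls
are non-intro types produced in isolated utterances of one or two
syllables more than one third of the time. Repetition-bout statistics use
maximal runs within bouts; CVs use the population standard deviation
(ddof = 0) throughout the package. The bird-level repetition features come
from the non-intro, non-call, non-noise type with the highest mean
repetition-bout length.

## Timing features

Syllable durations are log10-transformed and binned into 50 bins over
[−2.5, 0]; gaps (capped at 200 ms) use 20 untransformed 10 ms bins; values
outside the ranges are dropped. The normalized entropy is −Σ p ln p / ln N
with N the bin count, so it spans [0, 1].

The rhythm spectrum of a file takes the amplitude envelope (the normalized
2048/512 RMSE trace; the envelope normalization makes the spectrum
gain-invariant), cuts it into 3-s windows every 0.2 s, keeps the three
highest-energy windows, and per window mean-centers the first difference,
applies a Hann window, zero-pads to 100 000 envelope frames and takes the
magnitude of the Fourier transform; a 1–500 Hz band limit is applied by
bin masking (exact, no filter design) — at envelope sampling rates of
rate/512 only the 1 Hz high-pass is active. The file spectrum is the mean
over the three windows, retained over 0–30 Hz. Files shorter than
3 + 3 × 0.2 = 3.6 s are skipped. The magnitude (not the literal real part)
of the transform is used; rhythm identity should not depend on the phase
of the window placement. Rhythm entropy is the Wiener entropy
mean(ln power) − ln(mean power) of the squared mean spectrum, with the
zeroed sub-1 Hz bins excluded (ln 0 is undefined); a rolling 10-file
average of the spectrogram exists for display only and feeds no feature.
Peak-frequency variability first locates each file's peak freely, then
re-locates it within median ± 1.5 Hz (a 3 Hz band) so jumps between
harmonic bands do not masquerade as tempo changes, and reports the
population CV.

## Acoustic features

Operational per-frame definitions (window 512, hop 128 by default):
amplitude = 10 log10 of frame power; Wiener entropy = mean(ln P) −
ln(mean P) over frequency with a spectral floor *relative* to the frame
maximum (so the feature is gain-invariant); mean frequency =
power-weighted centroid; pitch and goodness of pitch = location and height
of the largest cepstral peak within 350–6000 Hz, computed from the
log-power spectrum after a 3-bin moving average (single-taper spectra have
chi-squared speckle whose extreme value otherwise inflates the cepstral
peak of noise frames); AM = summed time-derivative of spectral power; FM =
arctan of the ratio of root-summed-squared time to frequency derivatives.
These definitions are frozen by golden-value regression tests; parity with
external acoustic toolboxes is explicitly not claimed. Amplitude and
amplitude-modulation columns are flagged recording-sensitive in the
summary's attributes, since they depend on recording conditions rather
than the bird.

Summaries: per-rendition frame means (plus duration as the eighth base
feature), per-type means and population CVs (CV requires ≥ 2 renditions),
then min / median / max across types. The median over an even number of
types is the lower median, keeping every reported value one that an actual
syllable type attained. 48 acoustic values + 3 syntax + 4 timing = 55,
with fixed names and ordering; missing components become explicit `NA`s,
never imputations.

## Similarity scoring

Inputs are per-syllable spectrograms at a uniform 180 ms (clipped or
zero-padded at the tail), 2–6 kHz band only, amplitude normalized per
syllable. The embedder is five convolutional layers (32 then 64 3×3
kernels, stride 2 on the frequency axis after the first) alternating with
four multiscale analysis modules — four parallel strands of 1×1, 1×1→3×3,
1×1→5×5, 1×1→7×7 convolutions (32 kernels each) concatenated to 128
channels — followed by global mean pooling, three fully connected layers
and an L2-normalized 8-D output, ReLU throughout. The full architecture is available as preset `"full"`; the `"desk"` preset
keeps the same layer pattern at reduced width and depth (three convolutions,
two modules, widths 8/16/4) and is the configuration exercised by the test
suite; forward and backward passes are hand-written im2col matrix code
verified against numerical gradients.

Training is dynamic triplet loss on plain (unsquared) Euclidean embedding
distances, exactly max(d_AP − d_AN + α, 0); a `squared` flag provides the
squared-distance variant common elsewhere. Hardness: hard if d_AP > d_AN;
semi-hard if 0 < d_AN − d_AP < α (the standard definition; a literal
reading of the printed inequality is self-contradictory and was not
implemented). Per batch all valid triplets are classified and sampled
75:25 semi-hard:hard; the margin starts at 0.1 and rises by 0.2 (to at
most 0.7) whenever an epoch averages fewer non-zero triplets per batch
than a threshold that defaults to a quarter of the per-batch triplet
budget — the desk-scale analogue of a fixed count at full batch sizes.
Optimization is Adam with L2 weight decay 1e-4; everything is seeded.

EMD between two embedding sets is the exact optimal-transport distance
with Euclidean ground metric and uniform weights, solved in C++ by
successive shortest augmenting paths with node potentials; masses are
reduced by gcd(n, m) so equal-size comparisons reduce to an assignment
problem with at most n augmentations. On the unit 8-sphere two orthogonal
point masses sit at distance √2 ≈ 1.41 — the point-mass maximum under the
normalization constraint (antipodal unit vectors, at distance 2, would be
the unconstrained extreme; the embedder's outputs are compared in
Euclidean, not angular, terms). MMD uses a Gaussian RBF kernel with
bandwidth σ equal to half the median pairwise distance among ≤ 1000
reference embeddings, the *biased* estimator including diagonal terms
(stable at small n, zero on identical sets), reported as √max(MMD², 0).

Comparison protocols: self-comparisons split a pool in half below 4000
syllables and otherwise draw two 2000-syllable samples; other comparisons
draw up to 4000 per bird (all sizes overridable for desk-scale work). The
sampling seed is reset per side, so identical pools under one seed compare
as identical, and is recorded in every report. Contrast indices are the
absolute ratio |x − cross| / (x + cross) with the cross term a mean over
three unrelated comparisons.

## The synthetic song generator

`render_song()` synthesizes syllables as additive harmonic stacks
(fundamental, harmonic count, rolloff) with optional linear frequency
sweep, a broadband-noise mix, 5 ms raised-cosine edges and per-rendition
duration jitter, arranged by a grammar of geometric introductory-note
repeats, 2 + Geom(0.6) motif passes per bout (bouts loop the motif),
probability-ε off-motif jumps, jittered intra-bout gaps (< 200 ms),
inter-bout silences of 0.45–0.8 s, an optional cage-noise process and a
Gaussian noise floor. One seed determines every byte: per-file RNG
substreams derive from it and waveforms are quantized to 16 bits in
memory. Presets: `adult` (ε = 0.01, small jitters), `juvenile` (duration
jitter × 5, ε = 0.5, looser gaps), `isolate_like` (reduced repertoire,
noisy, variable), `repeater` (geometric repeats of the first motif
syllable, expected run length 2.5).

What the generator emulates — stereotyped vs variable grammars, intro
notes, repertoire-distinct harmonic types, silence structure, cage noise —
is sufficient to exercise every algorithm in the package with known ground
truth. What it does not emulate: within-type acoustic drift across a
session, reverberation and microphone coloration, overlapping vocalizers,
amplitude variation with posture and distance, and the continuous
duration variability of real song (synthetic durations cluster tightly,
which is *harder* for the labeling stage than real data in one specific
way: types fragment into discrete duration modes, the motivation for the
40 dB dynamic-range default). Passing tests therefore demonstrate
correctness of the implementations and recoverability under clean,
known-truth conditions — not field performance on colony recordings.

## Numerical choices and degenerate inputs

* Spectrogram dB conversion floors magnitudes at 1e-10 of the file
  maximum; an all-zero signal yields a uniform finite floor.
* Entropy sums define 0·ln 0 = 0; single-class clustering scores define
  0/0 = 1; F1 and precision/recall define 0/0 = 0.
* `emd()`/`mmd()` tolerate identical sets (0 up to solver epsilon ~1e-8);
  a degenerate MMD bandwidth (all reference points identical) is an error
  suggesting an explicit σ.
* The problem sizes used in the test suite and acceptance script (4–14
  files per bird, a few hundred syllables, desk-preset embedder, ≤ ~600
  points per EMD side) were chosen to keep a full validation run in
  minutes; all are arguments, not constants.

## Known limitations

* The UMAP and HDBSCAN implementations are exact (O(n²) distances) and
  comfortable to a few thousand syllables per bird, not hundreds of
  thousands.
* Amplitude-segmentation offsets are onset-to-onset by design and should
  not be scored against tight offset annotations.
* The acoustic feature definitions are self-consistent operational
  choices; absolute values are not interchangeable with other toolchains,
  though rankings and CVs behave equivalently.
* The root-fallback in cluster selection returns one cluster for data
  with no density structure at all (a uniform cloud) rather than all
  noise.
* Onset refinement assumes onsets are the sharpest local energy
  transition; extremely gradual onsets fall back to frame resolution.
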