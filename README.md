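# songpheno

Automated, interpretable phenotyping of zebra finch song from raw
recordings. The package is aimed at birdsong and vocal-learning labs that
record large volumes of undirected song and need per-bird, per-day
behavioral measurements without manual annotation: it segments syllables
from the amplitude envelope, labels them by unsupervised clustering,
summarizes each bird into a fixed 55-dimensional feature vector spanning
syntax, timing and acoustics, and scores the similarity between two birds'
syllable repertoires with a metric-learning embedder.

## What it computes

**Segmentation.** Each file is bandpass filtered (200 Hz–9 kHz) and its
per-frame RMS energy computed (frame 2048, hop 512), min–max normalized per
file. Syllable onsets are positive crossings of an onset threshold by the
first difference of the normalized RMSE; segmentation is onset-to-onset,
with trailing offsets taken from a downward crossing of an offset
threshold. One shared threshold pair is used for all birds and can be
selected by grid search against reference annotations
(`optimize_thresholds()`). Evaluation uses one-to-one onset matching at
10 ms (offsets 20 ms) and
F1 = TP / (TP + (FP + FN)/2).

**Labeling.** Per-syllable dB spectrograms (window 512, hop 128, clipped at
870 ms, padded to the longest syllable) are embedded in 2-D with the
package's UMAP implementation and clustered with its HDBSCAN
implementation; unclustered syllables carry the reserved `noise` token.
Agreement with reference labels is scored by homogeneity, completeness and
their harmonic mean (v-measure), computed from the confusion-matrix
entropies.

**Syntax.** From labelled sequences: song bouts (gaps ≤ 200 ms, ≥ 2
syllables), a syllable transition matrix with a silence state
(p<sub>ik</sub>, occupancies π<sub>i</sub>), the normalized entropy rate

    −Σ_ik π_i p_ik log2(p_ik) / log2(N),   N = syllable types + 1,

repetition-bout statistics (for *abcaaabc*, syllable *a* has two
repetition bouts, lengths 1 and 3), and heuristics for putative
introductory notes and calls.

**Timing.** Normalized entropies of the syllable-duration distribution (50
bins over log10 duration in [−2.5, 0]) and the gap-duration distribution
(20 × 10 ms bins); rhythm spectrograms (spectrum of the first derivative of
the amplitude envelope, 3-s windows, 0–30 Hz band); the Wiener entropy of
the mean rhythm spectrum; and the CV of the per-file rhythm peak frequency
within a 3 Hz band about the median.

**Acoustics.** Per-frame goodness of pitch, mean frequency, Wiener
entropy, amplitude, amplitude modulation, frequency modulation and pitch;
per-syllable means, per-type means and CVs, then min / median / max across
types for each of the 8 base features × {mean, CV} — 48 values, joined by 3
syntax and 4 timing features into the 55-feature vector.

**Similarity.** Syllable spectrograms (180 ms, 2–6 kHz) are mapped to the
unit 8-sphere by a convolutional embedder trained with dynamic triplet
loss (margin schedule 0.1 → 0.7 in steps of 0.2, 75:25 semi-hard:hard
mining, Adam with weight decay 1e-4). Repertoires are compared with exact
Earth Mover's Distance (min-cost-flow solver in C++) and Gaussian-kernel
MMD (bandwidth = half the median pairwise embedding distance), and
summarized by contrast indices |self − cross| / (self + cross).

**Synthetic song.** A deterministic generator (`synth_preset()`,
`render_song()`) renders harmonic-stack syllables under a Markov grammar
with introductory notes, motif passes, silent gaps, cage noise, and
adult / juvenile / isolate-like / repeater regimes, together with
ground-truth segment tables — every algorithm above is validated against
it.

## Worked example

```r
library(songpheno)

# 4 synthetic song files with ground truth
songs <- render_song(synth_preset("adult", n_files = 4, bouts_per_file = 3,
                                  seed = 7))

# amplitude segmentation and its accuracy against truth
segs <- do.call(rbind, lapply(songs$recs, function(r) {
  trace <- compute_rmse_trace(bandpass(r, 200, 9000))
  segment_amplitude(trace, onset_thr = 0.04, offset_thr = 0.05)
}))
metrics <- seg_metrics(songs$truth, segs)

# unsupervised labeling of the true segments, scored against truth labels
truth <- songs$truth[songs$truth$label != "noise", ]
specs <- prepare_syllable_spectrograms(songs$recs, truth)
labels <- cluster_hdbscan(embed_umap(specs, seed = 42))
ev <- cluster_eval(unclass(table(labels, truth$label)))

# the 55-feature phenotype
labelled <- segment_table(truth$file, truth$onset, truth$offset, labels)
fv <- assemble_feature_vector(summarize_by_type(songs$recs, labelled),
                              syntax_features(labelled),
                              timing_features(labelled, songs$recs))
```

Output (95 detected segments across 4 files):

```
onset F1 1.000 (precision 1.000, recall 1.000)
clusters: 4
homogeneity 1.000, completeness 1.000, v-measure 1.000
feature vector length: 55
      entropy_rate_norm   syll_duration_entropy rhythm_spectrum_entropy
                 0.2189                  0.5651                 -0.5742
           peak_freq_cv
                 0.0215
```

Every true onset is recovered within the 10 ms tolerance, the four
syllable archetypes come back as four clusters in perfect agreement with
the truth labels, and the syntax/timing summaries sit where a stereotyped
adult grammar should: low transition entropy, multimodal (low-entropy)
syllable durations, a negative rhythm entropy from the motif comb, and a
stable rhythm peak.

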