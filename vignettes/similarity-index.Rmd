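---
title: "The similarity-index method: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The similarity-index method: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`songsim` scores how well a pupil songbird imitates a tutor motif. This
vignette is the package's account of the science: the model and its
assumptions, every tunable parameter, what the synthetic-song generator
does and does not emulate, and the numerical and design decisions made
where more than one reasonable choice existed.

## The model

The method rests on three ideas.

1. **Asymmetric treatment of tutor and pupil.** Tutor song is assumed
   stereotyped enough to be represented by a few manually annotated
   motif samples, segmented into syllables and silent gaps. Pupil song
   is assumed too variable to segment reliably, so it is kept as a
   continuous stream and never segmented. Tutor gaps are excluded from
   scoring (silent gaps are trivially similar to one another and would
   inflate any score); pupil "gaps" are simply frames that no tutor
   syllable ends up matched to.

2. **Calibration against unrelated songs.** Raw spectral-feature
   distances have no absolute meaning, so every distance is referred to
   the empirical distribution of distances between songs of unrelated
   adult birds. A bin of the tutor-by-pupil matrix belongs to a *region
   of similarity* when the probability of seeing so small a smoothed
   distance among unrelated songs is below `alpha` = 0.05 (strict
   inequality); inside such regions similarity is `1 − P(D)`, elsewhere
   zero. Smoothing (`L`) is an RMS along the diagonal, ±25 ms, because
   imitation shows up as sustained diagonal runs, not isolated cells.

3. **Whole-syllable greedy matching.** Each tutor syllable must be
   matched as one complete diagonal. The best-matching syllable claims
   its pupil fragment first; matched rows and columns are zeroed and all
   remaining partial scores recomputed. Matching whole syllables
   deliberately denies the flexibility (matching fragments of a
   syllable to scattered places) that makes island-based scores
   overestimate similarity between unrelated songs. The greedy order is
   part of the method, not an optimization shortcut: no globally
   optimal assignment is attempted.

The acoustic score is the length-weighted mean of partial similarities,
in [0, 1]. The sequence score asks whether the imitation of syllable
*k+1* directly follows the fragment matched to syllable *k*, inside an
area of interest with 50 ms of slack. The similarity index (SI) is
their product.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `window_ms` | 9 | ms | spectral analysis window |
| `step_ms` | 1 | ms | frame spacing; all matrices are on this grid |
| `band` | 500–8600 | Hz | analysis band (zebra finch song energy) |
| `nw`, `n_tapers` | 1.5, 2 | — | Slepian time-bandwidth product and taper count |
| `alpha` | 0.05 | prob. | region-of-similarity threshold on `P(L)` |
| `smooth_half_ms` | 25 | ms | diagonal RMS half-window for `L` |
| `slack_ms` | 50 | ms | extra width of the sequence area of interest |
| `features` | GC, SW, PG, WE | — | distance feature subset |
| `scale_method` | `"mad"` | — | normalization scale convention |
| `pitch_range` | 400–3000 | Hz | cepstral fundamental search band |
| `entropy_floor` | −10 | log units | Wiener entropy on degenerate frames |

The defaults are the published operating point of the method. The
feature default {gravity center, spectral width, pitch goodness, Wiener
entropy} is the subset that maximized self/cross contrast in the
original colony experiments; pitch and FM are excluded by default
because both are unstable on sounds that are neither harmonic stacks
nor pure tones. `feature_subset_sweep()` re-evaluates any subsets on
your own data, rebuilding the calibration per subset (the null
distribution lives in the feature space).

Two statements of the normalization convention exist: median absolute
difference from the mean, and standard deviation. We default to the MAD
form (the description of the algorithm as run) and expose `"sd"` as a
config option; the fitted statistics and their convention travel inside
the serialized reference file, so a comparison is always reproducible
from that file alone.

## Calibration details

`build_reference()` pools **all** D and L entries from every
cross-source pair of corpus songs (never self-pairs, which would bias
the null toward small distances). The pooled empirical distributions are
compressed to 1001-point quantile grids with linear interpolation;
against a brute-force strict-less count the interpolation error is
bounded by the inter-quantile spacing (~10⁻³), and the suite verifies
`P(L)` evaluated on its own pool is uniform (Kolmogorov–Smirnov at the
1% level). Pools larger than `max_pool` (default 5·10⁶ per matrix type)
are subsampled deterministically at even strides before the grid is
computed — at a 1001-point grid this costs no practical resolution.
"Probability of a smaller distance" is implemented with `ties = max` at
duplicated quantiles; strict-less and less-or-equal differ only on
atoms, which corpora with a recording noise floor do not produce.

A reference is only valid for matrices computed under the same spectral
parameters and feature subset; a canonical parameter signature is stored
in the reference and checked at scoring time, and a mismatch is a hard
error rather than a warning.

## Numerical choices

* **Slepian tapers** are computed from the classical symmetric
  tridiagonal eigenproblem and cached per `(n, nw, k)`; unit energy,
  deterministic sign convention.
* **FFT length** is twice the next power of two above the window length
  (1024 at 44.1 kHz / 9 ms). With minimal padding, spectral peak heights
  scallop by tens of percent as harmonics slide across the coarse bin
  grid; that scalloping leaks into pitch goodness as artificial
  rendition-to-rendition variability. The finer grid samples the taper
  mainlobe adequately and removes the artifact.
* **Dynamic-range floors.** The cepstrum is taken on the log band
  spectrum clamped 80 dB below each frame's peak (near-zero bins at
  `log ≈ −700` would otherwise dominate), and FM clamps 80 dB below the
  song's peak so frames stay comparable over time. The cepstral peak is
  refined by parabolic interpolation in both position (pitch) and height
  (goodness).
* **Degenerate frames** (digital silence): Wiener entropy is floored at
  `entropy_floor`, gravity center falls back to the band midpoint,
  pitch to the midpoint of the search band, and spectral width, pitch
  goodness and FM to zero; such frames carry a `silent` flag.
* **Border handling for `L`**: windows truncate at matrix borders and
  the RMS runs over in-bounds cells only — zero-padding would fabricate
  similarity at song edges.
* **Seconds to frames**: syllable onsets round down (`floor(onset)+1`),
  offsets round up (`ceiling(offset)`), so annotated sound is always
  covered and syllable lengths are reproducible integers.
* **Tie-breaks**: equal diagonal sums resolve to the smallest pupil
  offset; equal partial scores across syllables resolve to the longer
  syllable (with raw diagonal sums this also emerges naturally: of two
  equally well-imitated syllables the longer has the larger sum), then
  the lower index. All runs are deterministic given inputs.
* **Zero-score syllables**: when everything admissible has been zeroed,
  a syllable is placed at the offset overlapping the fewest
  already-matched columns (ties: smallest offset), scored 0, and
  flagged. The literal greedy procedure can otherwise place a later
  diagonal across zeroed columns; the overlapping cells contribute
  nothing, and the per-syllable table records exactly what happened.

## Open design points, decided

* **Sequence scoring uses the pristine matrix**, not the progressively
  zeroed one: the published illustration of the sequence computation
  shows intact similarity bands, and zeroing would punish a syllable
  twice for the acoustic stage's bookkeeping.
* **Vertical extent of the area of interest**: exactly the rows of
  tutor syllable *k+1*.
* **Partial sequence normalization**: each partial sequence score is
  divided by the length of the expected next syllable, the minimal
  choice that puts every partial in [0, 1] and makes the mean
  comparable with the acoustic score, so their product (SI) stays in
  [0, 1].
* **Exclusions**: the last syllable has no successor; a syllable whose
  area of interest has zero width inside the matrix ("matched too close
  to the segment end") is excluded with a recorded reason. If no
  syllable is applicable (e.g. a single-syllable motif) the SI is
  reported as the acoustic score with an explicit `acoustic_only` flag.
* **Segment selection**: one random offset per bout per run, seeded;
  the tail shorter than a full segment is discarded. Aggregation over
  multiple tutor-motif versions is the mean of comparison scores; a
  90th-percentile "best match" aggregation is a known alternative for
  birds with several motif variants and can be computed from the
  returned per-pair table.

## The synthetic-song generator

`make_colony()` emulates what the feature set is designed to separate:
motifs of 3–7 syllables drawn from harmonic stacks (all harmonics below
Nyquist under a smooth spectral rolloff near 8 kHz, amplitudes
∝ 1/√h), pure tones, linear sweeps, and 1–8 kHz noise bursts, with
integer-ms durations of 40–120 ms, gaps of 30–70 ms, 5 ms raised-cosine
ramps, rendition-to-rendition pitch jitter (±1%) and gap jitter
(±3 ms), bouts of repeated renditions, and a 30 dB SNR noise floor on
every "recording" (motif samples included — tutor motifs are recordings
too). Fundamentals are assigned from interleaved per-bird frequency
slots in 550–2800 Hz, so no two birds share a fundamental while each
bird's own syllables stay hundreds of Hz apart.

Three of these choices deserve emphasis because they were made for
principled reasons, not convenience. Integer-ms durations keep syllable
onsets aligned with the 1 ms frame grid, so re-orderings of the same
syllables are measured at the same window phases. The smooth spectral
rolloff replaces a hard harmonic-count cap whose discrete jumps under
pitch jitter have no counterpart in real vocal-tract filtering. The
noise floor both emulates real recordings and keeps the calibration
distributions continuous: two digitally silent gaps would otherwise be
identical in feature space and deposit an atom of exactly-zero
distances in the null.

What the generator does **not** emulate: biologically realistic
vocal-tract synthesis, amplitude modulation within syllables,
introductory notes and calls, cage noise transients, or juvenile
subsong. Passing tests therefore demonstrate the pipeline's mechanics
and its discriminative behavior under controlled perturbations — not
performance on any particular real colony, whose scores depend on
recording conditions and song repertoires.

## Problem sizes and verification

The test suite runs on an 11-bird colony with 4-syllable motifs: birds
1–10 contribute one short bout each to the calibration null (45
cross-source pairs, ~5·10⁵ pooled entries per pair) and bird 11 plays
the tutor/pupil roles; a second, three-rendition bout per bird feeds
segment extraction. Matching and smoothing are verified against
brute-force oracles (exhaustive diagonal scans, a literal step-by-step
greedy re-implementation, per-cell RMS loops) to 10⁻¹² or exactly;
feature closed forms are checked on hand-built spectra; end-to-end
properties (exact copy ≈ 1, band-limited noise ≈ 0, acoustic/sequence
dissociation under syllable-order reversal, monotone mean degradation
under 0–10% pitch jitter across 20 seeds, segmentation-offset
uniformity over 1000 seeds) run on the synthetic colony.

## Known limitations

* Cepstral pitch is ill-defined for pure tones and noise (the paper's
  criticism of pitch/FM as features is visible here too); it is
  computed for completeness but excluded from the default subset.
* The 1 ms framing means sub-millisecond misalignments between tutor
  and pupil renditions cost a little acoustic similarity; the ±25 ms
  diagonal smoothing and the calibrated threshold absorb most, not all,
  of it.
* Self-similarity of noisy, jittered renditions is well below 1 by
  design — scores are meaningful relative to a calibrated null and to
  each other, not as absolute percentages.
* With pupil segments twice the motif length, a perfectly matched motif
  occupies half the segment; scores compare tutor syllables against the
  best-matching fragments, so this does not halve the score, but very
  long segments dilute the sequence score's areas of interest.
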