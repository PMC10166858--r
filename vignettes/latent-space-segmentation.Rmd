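---
title: "Latent-space segmentation of multichannel time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space segmentation of multichannel time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Wearable biosignal sensors (EMG bands, IMUs) produce long multichannel
recordings in which the interesting structure is the sequence of *regimes* —
stretches generated by one activity or gesture — and the *change-points*
where one regime hands over to the next. Labels are rarely available, the
channel count is moderate to high with heavy redundancy, and for many
applications (e.g. myoelectric control) the change must be detected while
the data streams in. `latentseg` implements an unsupervised segmentation
stack for exactly this setting: a matrix profile computed on an
autoencoder's latent representation of the windows, turned into a
change-point likelihood curve by arc counting, with extractors for both the
known-count and the count-free case, plus classic raw-profile baselines.

# The model, step by step

## Subsequences and the matrix profile

A series of `n` steps and `NC` channels is cut into all `n - m + 1` windows
of length `m` (stride 1). The classic profile assigns every window the
distance to its nearest non-trivial neighbor, under the z-normalized
Euclidean distance applied per channel (each channel of each window is
standardized with the *population* denominator, the convention of the
widely used matrix-profile implementations; channels with standard
deviation below `1e-12` are degenerate and map to zeros so distances remain
finite). A trivial-match exclusion zone of `ceiling(m/4)` positions — the
field's standard default; the choice is exposed as `excl` — prevents a
window from matching its own overlapping neighbors. Equal distances are
broken towards the smallest admissible index, making every profile
deterministic and order-independent.

Two orthogonal restrictions matter for segmentation:

* a **temporal constraint** `tc` limits how far an arc may point
  (`|k - j| <= tc`). It is what makes *repeated* regime types segmentable —
  without it, a window of a recurring gesture happily points into another
  occurrence far away and the boundary signal washes out. A radius of
  roughly the maximum expected segment length works well and is not a
  sensitive parameter.
* a **forward** restriction (`k > j`) allows fully online maintenance:
  no arc ever points backwards, so extending the series never invalidates
  an old entry — entries can only improve as new data enters their band.

## From arcs to a change-point likelihood

Each window's nearest-neighbor link is an arc over the time axis; the arc
curve counts, per position, the arcs passing strictly over it (endpoints do
not count; the same convention is used everywhere, including the simulated
null model below). Inside a homogeneous regime arcs are plentiful; almost
nothing crosses a boundary. Raw counts are biased by geometry — no arc can
cross the edges — so they are divided by the *idealized* curve, the
expected count for a structureless series. Bidirectional and unconstrained,
this is the closed-form parabola `2k(L-1-k)/(L-1)` with height half the
curve length. For forward-only or temporally constrained arcs no closed
form is available, so the package estimates the idealized curve by
Monte-Carlo: each of `n_trials` (default 1000) trials draws one uniformly
random admissible partner per position with the same direction/constraint
geometry, and trials are averaged (seeded, cached per geometry). The
corrected arc curve (CAC) is `min(count/ideal, 1)`, in `[0, 1]`, low at
likely change-points.

Two guards keep the division honest. The idealized curve is clamped to at
least 1 before dividing. And positions whose idealized count falls below
`min_expected_arcs` (default 25) are reported as 1, i.e. "no evidence":
treating crossings as roughly independent, the null sampling deviation of
the ratio is about `1/sqrt(ideal)`, so 25 caps it at 0.2. For the
bidirectional parabola this affects only a dozen positions per edge; for
the right-skewed one-directional curve it protects the stream head and
tail, where we observed the bare ratio manufacturing deep spurious valleys
out of a handful of random crossings.

## The latent path

Averaging per-channel CACs (the FLUSS recipe, kept as the `fluss` method)
treats every channel as equally informative; redundant or pure-noise
channels dilute the boundary signal. The latent path instead learns a
compact representation of whole multichannel windows and computes the
profile there:

1. **Autoencoder.** Two architectures are provided. The *fully connected*
   model flattens the window to `d = NC * NW` inputs, halves twice
   (`d -> d/2 -> d/4`), and projects to a latent of `max(1, round(0.1 d))`
   units; activations are sigmoid and the decoder mirrors the encoder with
   *transposed (tied) weights* and its own biases — that weight tying is
   the defining feature of this small reference architecture. The
   *convolutional* model applies two stride-2 length-3 convolutions
   (`NC -> 2NC -> 4NC` channels, halving the temporal length twice),
   flattens back to `d` features, and reaches a latent of `round(d/6)`
   through three ReLU layers; its decoder mirrors the shapes with
   independently learned transposed convolutions and fully connected
   layers ("transposed convolution" being the layer type, not weight
   sharing) and a linear output. The printed description of this
   architecture has two internal inconsistencies: a reshape row whose
   dimensions do not multiply out, and decoder rows repeating encoder
   labels with one stride printed as 1. We read the reshape as a flatten
   to `NC * NW` (which makes the stated 1/6 feature ratio exact) and
   mirror the encoder exactly. Likewise the fully connected bottleneck
   ratio is printed as input/latent = 0.1; a latent ten times *larger*
   than its input is not a bottleneck, so we take latent/input = 0.1.
   Training minimizes mean squared reconstruction error with Adam
   (learning rate `1e-3`, batch 64 by default), early-stops on a held-out
   20% of the windows with patience 20, and is bit-reproducible given its
   seed. Inputs are scaled per channel with statistics fitted on the
   training data only; the scaler family (`standard`, `minmax`, `robust`,
   `maxabs`, `none`) is a configuration choice. A `train_stride` option
   subsamples training windows — stride-1 windows share all but one
   sample and are heavily redundant — while encoding is always stride 1.
2. **Latent-space matrix profile (LSMP).** One latent row per window;
   nearest neighbors under the *plain* Euclidean distance (the
   representation is already learned; no per-window normalization), with a
   mandatory finite temporal constraint. The banded computation scans
   inter-row offsets and never materializes the full distance matrix.
3. **Memory-bounded and online operation.** The *batched collapse*
   processes the latent rows in chunks of `t_lim` rows (precondition
   `t_lim > 2 tc`), extends each chunk backwards over the positions the
   merge re-derives (`2 tc - 1` bidirectionally, `tc` forward), and merges
   partial profiles by elementwise minimum — provably identical to the
   full computation, which the test suite asserts on a parameter grid.
   The streaming state appends new rows by incremental minimum updates
   over a trailing buffer (`2 tc - 1` rows bidirectionally, `tc` forward);
   because the minimum over a growing pair set equals recomputation, any
   chunking reproduces the offline result exactly. Accumulating
   `epsilon_batch` samples per append bounds the detection latency — the
   epsilon of epsilon-real-time; with forward arcs the default is 1.

## Extraction

Three extractors convert a CAC into change-points, all sharing an
exclusion radius that defaults to `5 * NW` (stated for the known-count
extractor in the source material; the local variants inherit it). That
default presumes the window length tracks the segment scale; when `NW` is
much shorter than a segment — as in our fixture, `NW = 32` against
segments of ~1600 — a CAC valley is far wider than `5 * NW` and the
iterative extractor can spend two picks on one valley. The exclusion
radius should then be set from the same prior that sets the temporal
constraint and the local window: a fraction of the expected segment
spacing (the packaged study uses half the local window).

* **REA** — `k` global minima, masking the exclusion zone after each pick;
  needs the true count.
* **LREA** — REA on the *locally scaled* curve
  `(CAC - mu_rolling) / sigma_rolling`, centered window `j ± local_window`
  truncated at the boundaries; valleys are judged against their
  neighborhood, which matters on long recordings with a drifting baseline.
  As the window saturates, LREA provably tends to REA (tested at a window
  of ten times the curve length). A practical `local_window` is the mean
  change-point gap of a training set.
* **LTEA** — count-free: scale, set everything above `threshold`
  (default -1, one local standard deviation) to 1, take each maximal
  sub-threshold run as one valley, report each valley's minimum, and drop
  minima within the exclusion radius of an accepted *deeper* one (the
  depth comparison is our pinned choice where the source is silent; ties
  in a valley go to the smallest index). Because a contiguous run is one
  valley, broad valleys yield one detection — which is why LTEA is the
  prescribed extractor for the online path, whose one-directional curve
  develops wider valleys than the bidirectional one.

The rolling scaling has a trailing mode (`[j - 2 local_window, j]`,
past-only) for emit-as-you-go consumers. Two caveats are documented rather
than hidden: rolling moments are computed by cumulative sums, whose
catastrophic cancellation on flat stretches is absorbed by a *relative*
degeneracy test (`sigma < 1e-7 * sqrt(mean square)` maps to 0 — scaled
into spurious structure otherwise); and on series only a few local windows
long, trailing statistics merge the curve's initial transient into one
giant sub-threshold run, so extraction over a completed replay defaults to
centered statistics and `scaling_mode = "trailing"` is an explicit choice.

A detected change-point is reported at the subsequence position of the
valley; position `j` indexes the window starting at step `j` (1-based
throughout, as is natural in R), and a change-point means "first sample of
the new regime". Valley minima sit within about half a window of the true
boundary, well inside the `±NW` tolerance used in validation.

## Scoring

With ground truth available, every ground-truth point is paired to its
nearest prediction (ties to the earlier prediction; predictions may be
reused — the only reading consistent with a sum over ground-truth indices).
`score_regimes` is the matched mean absolute error normalized by series
length; an empty prediction set scores the maximal penalty `mae = n` with
a warning. For count-free extraction the *prediction loss MAE* weights the
MAE by the deviation of `N_pred / N_GT` from 1. As printed in the source,
the combination `(1 - N_pred/N_GT) * MAE` is zero whenever the count is
right — contradicting the tabulated results it accompanies — so the
combination rule is a labeled configuration enum: `inflation_default`,
`(1 + |1 - ratio|) * MAE` (correct count gives exactly the MAE), and
`as_printed_abs` for the literal reading.

# The synthetic study conditions

Real benchmark recordings (activity recognition, long-term EMG, dance)
cannot ship with a package, so validation rests on a generator of
regime-switching multichannel series with *known* boundaries. Each regime
owns a set of latent sources — a sinusoid at a regime-specific frequency
with fresh random phase per segment, a resonant AR(2) process whose pole
angle moves with the regime, and a sparse burst source (random impulses
convolved with an exponential envelope, a crude muscle-activation
analogue). Sources are standardized per segment, mixed into the observed
channels by a fixed "virtual sensor array" matrix shared between training
clips and evaluation series (pass your own to break the link), pure-noise
channels are appended, and observation noise is added.

The default fixture emulates a continuous EMG-like recording: 10 channels
from 3 sources plus 2 pure-noise channels, 5 segments of 1200–2000 steps
(about 8,000 steps, so the expected segment length — and hence `tc` — is
about 1600), observation noise `sd = 0.3` against unit-variance mixed
signals, roughly 10 dB SNR. These sizes were chosen once as a realistic
desk-scale analogue of a gesture-holding protocol (segments many times the
window length, redundant channels, some useless channels); the companion
training set is 2 clips per regime of 600–1000 steps with no transitions,
mirroring the "concatenate isolated gesture recordings" construction.
The generator also supports non-adjacent regime repetition, which is the
case that *requires* the temporal constraint.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: physiological EMG statistics,
non-stationarity within a regime, gradual transitions, sensor drift and
artifacts, channel-dependent noise, or label noise in the ground truth.
The generator's boundaries are exact by construction; real annotations are
not.

# Numerical choices and degenerate inputs

* Ties everywhere go to the smallest admissible index; this single rule
  makes profiles, batched merges and streaming updates agree exactly.
* No-partner positions carry `p = Inf`, `i = NA`; arc counting skips them.
* The idealized-curve cache is keyed by (length, direction, constraint,
  trials, seed); simulation is seeded and reproducible.
* Windows with a constant channel z-normalize that channel to zeros;
  series with any non-finite value are rejected outright (no
  missing-data support).
* All randomness — generator, training shuffles and initialization,
  idealized-curve simulation — flows through explicit seeds via local RNG
  scopes; nothing touches the global random state.
* Problem sizes in the test suite: brute-force oracle comparisons run at
  `n <= 300` over 50 seeded series and all direction/constraint
  combinations; latent-profile equivalences at 500 rows; the end-to-end
  study at the full ~8,000-step fixture with the convolutional model
  trained at `train_stride = 4` for up to 80 epochs — sizes chosen so the
  whole validation is a desk-scale computation.

# Known limitations

* The autoencoder engine is deliberately minimal (two fixed architectures,
  Adam, early stopping); no variational variants, GPU paths, or
  architecture search.
* The forward (online) curve is intrinsically noisier than the
  bidirectional one — one-directional arcs and a simulated null model —
  and degrades gracefully rather than matching offline accuracy; the
  package documents rather than hides the head/tail evidence floor this
  requires. The zone within one constraint radius of the stream tail
  remains its weak spot: real data's arcs are shorter than the uniform
  null's, the mismatch concentrates where the forward band truncates, and
  on unlucky realizations the count-free extractor can trade a weakly
  dipping true boundary for a tail valley.
* Scores assume a single recording per call; cross-recording statistical
  comparisons (rank tests and post-hoc procedures) are left to standard
  statistics routines on the per-recording score tables the package emits.
* Segment durations shorter than about three windows violate the
  generator's own guidance (asserted when the intended window length is
  supplied) and are not a supported regime of the method.
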