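---
title: "Detecting nystagmus from eye videos with recursive filtered images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nystagmus from eye videos with recursive filtered images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vogdetect)
```

## The problem

Nystagmus — an involuntary, rhythmic oscillation of the eyes in which a slow
drift phase alternates with a corrective phase — is one of the most
informative bedside signs in acute dizziness: its presence and pattern can
separate dangerous central causes from benign inner-ear disease. Reading it
reliably from video, however, takes subspecialty training, and classical
automated approaches require calibrated eye tracking to extract a gaze
waveform first.

`vogdetect` implements an alternative that works directly on pixels: a
short monocular video-oculography (VOG) clip is converted into a stack of
*filtered images* — a motion-energy representation — a small per-image
classifier scores every filtered image, and a voting rule aggregates the
image scores into one video-level decision. The operational case
definition used throughout is: a clip is "nystagmus" when it contains at
least two consecutive beats (slow/fast alternations).

## The filtered-image representation

For a grayscale frame sequence $I_1, \dots, I_T$ the package maintains an
intermediate image $M$ that blends past frames with exponentially decaying
weights, and emits the absolute deviation of each new frame from it:

$$
M_1 = I_1, \qquad
M_t = (1-\beta)\,M_{t-1} + \beta\,I_{t-1}, \qquad
F_t = |I_t - M_t|, \qquad t = 2, \dots, T .
$$

A $T$-frame clip therefore yields $T-1$ filtered images (599 for a
10-second clip at 60 Hz). The single weight $\beta \in (0, 1]$ sets the
memory of the background image:

* $\beta = 1$ collapses the recursion to plain frame-to-frame differencing
  ($F_t = |I_t - I_{t-1}|$);
* $\beta \to 0^+$ approaches comparison against the first frame
  ($F_t \to |I_t - I_1|$);
* intermediate values leave a decaying "motion trail": after a step change
  in intensity the response decays geometrically with factor $1-\beta$.

Both limits and the geometric-decay closed form are asserted in the test
suite against a scalar unrolled-recursion oracle. $\beta = 0$ is rejected
at the API level: it degenerates to a constant first-frame comparison and
is no longer a recursive filter.

The displayed recursion is seeded with the first frame and emission starts
at $t = 2$. This indexing is the only reading consistent with the count of
599 images from 600 frames: a recursion that emitted from $t = 1$ would
have to reference a frame before the clip starts.

### Sliding windows

A sliding-window variant restarts the recursion on the last $w$ frames for
each end position $t = w, \dots, T$ and emits only the final $F$ of each
restarted run, yielding $T - w + 1$ images whose content provably depends
on nothing outside the window (a locality property the suite asserts by
perturbing frames outside the window). The window bounds the temporal
context to roughly one beat: at 60 Hz, $w = 30$ spans 500 ms. Because the
restarted recursion is a fixed geometric-weight combination of the window
frames, the implementation evaluates it in closed form rather than
re-running the recursion per window; the restart-per-window brute force is
kept as a test oracle. Windows overlap at stride 1; one image per end
position.

## The synthetic study generator

The clinical recordings this method was designed for cannot be
redistributed, so the package ships a simulator that generates labeled
clips with ground-truth gaze traces:

* **Waveforms.** Jerk nystagmus with linear (constant-velocity),
  velocity-decreasing, or velocity-increasing slow phases, and pendular
  (sinusoidal) oscillation. Slow-phase durations default to the
  physiological 150–350 ms range; fast phases are rendered as one-sample
  transitions, since saccadic velocities far exceed a 60 Hz sampling rate
  (a sampled jerk waveform is a sawtooth). Beat intervals are annotated
  exactly in the trace, and the video label follows the two-beat rule from
  those annotations. Pendular waveforms have no fast phase, so each full
  cycle is annotated as one beat; a sustained pendular oscillation is
  therefore labeled nystagmus under the same rule.
* **Distractors.** Blinks and lid closure (rendered as an occluding lid
  band), square-wave jerks (a saccade away from fixation, returning after
  150–350 ms), slow drift, and tremor-like position noise. Distractor-only
  clips never satisfy the two-beat rule, and at most one isolated beat is
  planted in negatives, so label soundness is structural.
* **Appearance.** A bright sclera, darker iris disk and dark pupil disk
  (the infrared ordering), drawn with antialiased edges so sub-pixel
  motion still modulates edge pixels — essential for the degradation
  experiments, where motion can fall below one pixel. A per-clip
  multiplicative illumination gradient, per-pixel Gaussian sensor noise,
  and per-patient geometry/intensity variation emulate heterogeneous
  recording quality. Eccentric-gaze clips are rendered with a fixed gaze
  offset and tagged, defaulting to the 44.3% fraction of the emulated
  study.
* **Composition.** Defaults mirror the emulated study: 435 ten-second
  60 Hz clips at 240 × 320 from 30 patients, an approximately 1:1 class
  ratio with every patient contributing both classes, and 95%
  linear-jerk / 5% velocity-decreasing waveforms among positives.

Everything is a deterministic function of one master seed (per-clip
sub-seeds are drawn once), which the suite asserts bitwise.

What the simulator does **not** model: iris texture and corneal
reflections, torsional movements, head/goggle slippage, compression
artifacts, or real eyelid deformation. Passing tests on synthetic data
therefore demonstrate the pipeline's mechanics and its relative behavior
across conditions (e.g. frame-rate degradation), not clinical performance.

The gaze-angle-to-pixel gain is fixed at 4 px/degree at 240 × 320 and
scales proportionally with resolution, so the same waveform legitimately
loses amplitude when rendered or degraded to smaller frames. Beat
amplitudes default to 0.6–2.2 degrees, spanning roughly 2.5–9 px at
240 × 320 — including barely-visible motion at degraded resolutions, which
is intended.

## Classifier and voting

Every filtered image inherits its video's label, so even a modest video
count yields a large image-level training set (300 ten-second videos give
$300 \times 599 = 179{,}700$ training images). The default backbone is
deliberately small. Its input is a two-part feature vector per filtered
image: (a) the image area-averaged to 15 × 20, flattened and scaled to
$[0,1]$; and (b) nine translation-invariant summaries of the
full-resolution motion image — the pixel fractions falling in seven
intensity bands (edges 2, 5, 10, 20, 40, 80, 160), the mean, and the
maximum. The band summaries matter because the informative motion pattern
(a crescent along the iris/pupil rim) moves around the frame with gaze
position; a pure pixel representation at this scale confuses
eccentric-gaze fixation with displaced nystagmus, while band fractions
see "how much faint vs. strong motion" regardless of where it sits. The
features feed a single-hidden-layer network (32 tanh units, logistic
output) trained by seeded mini-batch gradient descent with momentum
(40 epochs, batch 256, step 0.05). A square-root input transform is
available but off by default — motion *amplitude* carries class
information, and compressing it measurably hurt separation. A
penalty-free logistic regression backbone serves as a convex reference
implementation. Both are deterministic given their seed and serialize to
plain JSON with full-precision weights.

This backbone is not a stand-in for a convolutional network's capacity; it
is the point of the package's test bed — the representation and the voting
logic, not backbone scale, are what is under test.

Video-level aggregation offers the four rules of the original design:

* **soft** — mean per-image probability;
* **hard** — fraction of images whose probability reaches the per-image
  threshold (majority vote at the defaults);
* **temporal** — positive only if some `run_length` consecutive images are
  positive, the direct translation of "sustained consecutive beats"
  (50 frames at 60 Hz ≈ 750 ms);
* **ensemble** — average of two constituent video scores (canonically a
  soft vote from one model and a hard vote from another).

Ties binarize as positive and video labels use `score >= threshold`; both
conventions are documented and tested. Raising any per-image probability
can never flip a positive soft/hard/temporal decision to negative, and
longer required runs only make the temporal rule stricter — both proved on
randomized vectors in the suite.

## Evaluation

AUROC is computed by an explicit threshold sweep with trapezoidal
integration and is validated in the suite against both the
pairwise-concordance definition and an independent library implementation.
Sensitivity, specificity and accuracy are reported at an operating
threshold of 0.5 on the video score by default — the original report does
not define its operating point — with the Youden-J-optimal threshold
reported alongside. Cross-validation uses a stratified group k-fold
(k = 3 by default): class balance per fold is the hard constraint
(within one video of the global share), and each patient's videos of each
class are spread across folds best-effort, since exact patient balance is
generally infeasible with heterogeneous per-patient counts. Model
comparisons use the classical unpaired pooled-variance t-test on per-video
prediction probabilities, with degenerate zero-variance pairs
short-circuited to an exact-equality test; no multiple-testing correction
is applied, matching the convention of the report this design follows.

## Degradation experiments

`degrade_grid()` reduces the frame rate by pure decimation (every k-th
frame, no temporal interpolation — lower rates are *simulated* from a
60 Hz master, so the operation is exact) and the resolution by area
averaging (exact block means when dimensions divide; the kernel choice is
deliberate: deterministic, testable, and a constant frame maps to the same
constant). The canonical 3 × 3 grid over {60, 30, 15} Hz ×
{240 × 320, 60 × 80, 15 × 20} yields the original plus 8 degraded
variants. `run_degradation_experiment()` re-trains and re-evaluates the
full pipeline per cell with shared seeds.

## The bundled benchmark and problem sizes

The package's end-to-end check runs at desk scale on one CPU:
36 ten-second 60 Hz clips at 60 × 80 from 6 simulated patients (3:1
stratified split), β = 0.25, the tiny backbone, temporal voting with a
50-frame run requirement (~750 ms at 60 Hz — the shortest of the
canonical run criteria, and the most seed-stable rule on this benchmark;
soft voting remains the package-wide default elsewhere). Accuracy is
scored from the voting rule's own decisions, since a temporal run-ratio
score is not commensurable with a 0.5 probability cutoff. Note that a
run criterion fixed in *frames* becomes stricter in *seconds* as the
frame rate drops — part of why detection degrades at 15 Hz. One
deliberate choice needs stating: at 60 × 80 the fixed gain maps the lower
end of the default amplitude range to ~0.6 px, which no pixel-level
classifier of this size resolves reliably — by design that regime exists
for the degradation study. The benchmark is meant to be strongly
separable, so its config draws amplitudes from the upper half of the range
(1.5–2.5 degrees, ≥ 1.5 px at 60 × 80) via the generator's
`amplitude_range` argument; the generator's own default remains the full
study range. The directional degradation check compares 60 Hz against
15 Hz at matched resolution, averaged over five seeds of 24 videos each.
The training-corpus counting law is exercised at 15 × 20 — the smallest
canonical resolution — because the image-count law is
resolution-independent.

Reference configurations (`inst/configs/`): `smoke.yaml` (single β,
minutes), `beta-sweep.yaml` (the canonical 7-value β grid), and
`degradation-grid.yaml` (3 × 3 rate × resolution grid).

## Numerical and degenerate-input conventions

* Filtering arithmetic is double precision throughout; values stay in
  $[0, 255]$ by construction. `quantize_stack()` rounds to 8-bit only for
  image export; classification consumes the exact values by default.
* Clips must have ≥ 2 frames (≥ `window` frames for sliding variants);
  rate resampling requires divisible rates; upscaling is refused.
* PNG/TIFF round-trips are bitwise for integer-valued clips; loaders
  round off the 1/255-quantization float error.
* Empty score vectors, single-class training sets, single-class label
  vectors, and k = 1 folds are rejected with explicit errors.
* `hard_vote` with per-image threshold → 0 labels everything positive,
  → 1 only certainty; `temporal_vote` with `run_length = 1` is "any image
  positive". All three limits are tested.

## Known limitations

* The tiny backbone underperforms convolutional models on subtle
  (sub-pixel) motion; the backbone registry exists so stronger models can
  be plugged in where a deep-learning runtime is available.
* The simulator's noise and illumination statistics are plausible rather
  than calibrated to any instrument.
* Whether filtered images should be 8-bit quantized before classification
  is unsettled in the original design; both paths are exposed, exact
  values are the default.
* Video-container (AVI/MP4) import/export is not provided — no codec
  library is a package dependency; PNG frame directories and multi-frame
  TIFF stacks are the supported lossless interchange formats.
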