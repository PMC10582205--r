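---
title: "Organizing grouped-embryo microscopy videos: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organizing grouped-embryo microscopy videos: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The processing model

A conventional-microscope IVF observation session produces one video per
patient and day of development. The stream has a characteristic temporal
structure: a long blurry period while the microscope is set up, then for each
growth-medium drop a short blurry focus ramp, a clear evaluation phase
showing the drop's two embryos, and a blurry embryo-free transition while
the stage moves on. `embryovision` converts such a stream into a library of
clear per-embryo crops in four stages: downsampling, detection, organization,
and blur filtering; a fifth module scores detectors against ground truth.

### Downsampling

Clinical capture runs at 25 fps, far denser than embryo morphology changes.
The stream is thinned to a target rate (default 5 fps) by keeping every
`stride`-th frame starting at source index 0, with
`stride = round(source_fps / target_fps)`. Frame dropping (rather than
temporal averaging) is used deliberately: it is deterministic, introduces no
resampling artifacts, and keeps every retained frame a genuine sensor image.
A non-integer rate ratio is accepted with a warning and a rounded stride.
Input is a directory of numbered frames; decoding encoded containers is left
to external tooling (any frame extractor can produce the directory), which
keeps the package free of codec dependencies.

### Detection

Detection is a contract, not an implementation: any source of per-frame
boxes with confidences can drive the organizer. Two sources are built in.

* `readDetectionsDir()` ingests the normalized text dialect used by common
  single-stage detectors (one `class cx cy w h [conf]` line per object,
  coordinates normalized to [0, 1], one file per frame), so a trained model's
  output drops straight in. Missing confidence defaults to 1; malformed lines
  and out-of-range values are fatal with a line number, because silently
  skipping annotations corrupts evaluation.
* `detectClassical()` is a weight-free classical detector for testing and
  bootstrapping: grayscale → Gaussian smoothing (σ = 2 px) → local
  standard-deviation map (9 px window) → Otsu threshold → morphological
  closing (disc radius 5) → connected components, keeping components with
  area between 0.5% and 25% of the frame and circularity 4πA/P² ≥ 0.6.
  Confidence is the circularity clamped to [0, 1]. The area band and
  circularity floor encode what an embryo is in this imaging setting: a
  roughly circular textured object occupying a few percent of the field of
  view. The detector is deterministic for a fixed frame and settings.

### Organization

The organizer is a state machine over per-frame detection counts. A segment
(one growth-medium drop) opens at the first detected frame while none is
open and closes after `gap_frames` consecutive empty frames. Closure by
hysteresis is the key design choice: transitions between drops are blurred
*and* embryo-free, so a run of empty frames longer than the gap reliably
separates drops, while single-frame detector dropouts inside a drop do not
split it. The default `gap_frames = 5` (1 s at 5 fps) sits below the
typical between-drop transition length (about 2 s) with margin. Segments
shorter than `min_len_frames` (default 5) are discarded without consuming a
drop number — they are almost always spurious detections in transition
frames.

Within a segment, each frame's detections are assigned to the left/right
embryo slots: the top two detections by confidence are kept (the setting is
exactly two embryos per drop; extra boxes are detector noise) and ordered by
bounding-box x-center, ties broken by the smaller y-center. A frame with a
single detection is assigned to the side whose running-mean x-center over
the segment is nearer, defaulting to left with no history. Re-evaluating
sides every frame with a running-mean memory, instead of freezing them at
the first frame, tolerates jitter in either embryo's detection. The side
history is reset at each new segment, since the embryo pair changes between
drops.

Crops are cut from the full-resolution downsampled frames (box rounded
outward to integer pixels, clamped at frame edges, no resizing) and written
as quality-95 JPEG into
`Day_{day}/D{day}_{NNN}/Medium_{MM}/Embryo_{EE}/image_{KK}.jpg`, the
day/patient/medium/embryo hierarchy used for downstream training libraries.
Numbering is 1-based, zero-padded, and gapless per folder.

### Blur filtering

Crop sharpness is the population variance of the response of the 3×3
Laplacian kernel `[[0,1,0],[1,−4,1],[0,1,0]]` on the grayscale (BT.601 luma,
rounded) crop. Edges and high-frequency texture drive the response, so
defocused crops score low. Several conventions are unstated in common usage
and are fixed here for bit-stable scores: population (divide by N) rather
than sample variance; mirror padding that reflects across the edge without
duplicating the edge pixel; the −4-center sign convention. Scores are
computed on the crop as saved (8-bit, post-JPEG), since filtering runs after
organization.

A crop is *clear* iff its score lies inside the day's inclusive band:
[500, 2000] for day-3 (cleavage-stage) and [300, 900] for day-5
(blastocyst-stage) embryos. Inclusive bounds make the printed band edges
attainable. Note the band has an upper edge — abnormally high variance
(sensor noise bursts, debris) is rejected too, which departs from the common
one-sided variance test. `filterTree()` applies the band to every embryo
folder in delete, quarantine, or dry-run mode and renumbers survivors
gaplessly; a second pass removes nothing.

`calibrateBand()` reproduces the experimental procedure that set those
bands, on synthetic ground truth: the band is the 0.5th–99.5th percentile
range of clear-phase crop scores widened by a 20% margin, validated against
blurred (focus-ramp) crop scores; calibration fails loudly when fewer than
99% of clear crops or more than 5% of blurred crops would be classified
correctly, i.e. when the classes are not separable.

### Evaluation

Detections are matched to ground truth greedily in descending confidence
within each frame; a detection is a true positive when its best-IoU
unconsumed ground-truth box reaches the threshold. IoU is computed on
continuous box areas. Average precision uses the exact all-point
interpolation (area under the precision envelope over recall), rather than
11- or 101-point sampling, because it is reproducible and threshold-free;
with ten IoU thresholds 0.50–0.95 in steps of 0.05 this yields mAP@0.5 and
mAP@0.5:0.95. AP with zero ground-truth boxes is reported as an error, not
as 0. With a single "embryo" class, mAP equals AP.

## The synthetic generator

`generateVideo()` renders a seeded scene from a script of phases (setup,
per-drop focus ramp, clear, transition) and emits a per-frame manifest:
phase label, blur sigma, and the true boxes with drop index and side.

What it emulates: the temporal phase structure above; two embryos per drop
with the left one strictly left of the right one; embryos as rimmed disks
with granular internal texture (a thresholded smoothed-noise field), so
clear crops carry the high-frequency content that variance-of-Laplacian
scoring requires; slow positional drift; mild sensor noise; per-phase
Gaussian defocus, including a small optical-blur floor (σ = 0.7) even on
in-focus frames, as real optics never deliver ideal step edges.

Defaults, chosen once as the study conditions: 5 fps rendering at 256×192;
16 s setup; 2 s ramps with σ falling 6 → 2; clear-phase durations cycling
15 s, 4 s, 7.2 s (a thorough evaluation, a quickly dismissed pair, an
intermediate one); 2 s embryo-free transitions at σ ≈ 5; embryo radius
12–15% of the short frame side; texture amplitude ±50 gray levels for day 3
and ±28 for day 5, which places clear-crop scores mid-band (day 3 ≈
1050–1250, day 5 ≈ 500–620 at the default scale) while ramp crops score
below 50. All randomness flows through one seeded generator; identical
(script, seed) pairs are bit-identical.

What it does not emulate: real embryo morphology (blastomeres, zona
pellucida, fragmentation), morphological change across the session,
illumination drift, stage vibration, or occlusion between embryos. Passing
tests on this generator therefore demonstrate the correctness of the
pipeline's logic — segmentation, assignment, layout, scoring, evaluation —
under the stated temporal and photometric structure, not detector
performance on clinical imagery, where a trained model supplied through the
detection-file contract is the intended source.

## Numerical choices and degenerate inputs

* Grayscale: BT.601 luma with rounding, clamped to [0, 255].
* Boxes are continuous; rasterization happens only when cropping (outward
  rounding) — so IoU is exact and crops never lose covered pixels.
* Normalized detection lines may place a box edge fractionally outside the
  frame (`cx ± w/2` beyond [0, 1] jointly); boxes are clamped to the frame.
* Constant frames yield zero detections; constant crops score exactly 0.
* Images smaller than 3×3 are rejected by the Laplacian scorer.
* Zero-area crops after clamping are skipped with a warning, preserving the
  gapless numbering of what is actually written.
* An empty detection stream organizes to an empty report, not an error.

## Problem sizes

The test suite runs the full default-length scene (about 54 s of video for
three drops) for drop-count recovery across five seeds, and shorter scenes
(2–3 s phases) for unit-level checks; oracle equivalences use 1,000 random
box pairs and random images up to 32×32. These sizes exercise every code
path while keeping the suite fast enough to run routinely.

## Known limitations

* Embryo identity is not tracked across growth media or days; folder indices
  encode position within the session only.
* One patient per video; multi-patient batching is out of scope.
* The classical detector is tuned to the generator's imaging model; on
  clinical frames it is a starting point, not a replacement for a trained
  detector.
* Blur bands are day-specific constants; per-image adaptive thresholds and
  learned blur classifiers are out of scope, as is any deblurring.
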