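# embryovision

Turns microscopic observation videos of group-cultured IVF embryos into an
organized library of clear, per-embryo image crops.

In conventional (non-time-lapse) IVF monitoring, an embryologist moves a dish
of paired embryos under an inverted microscope and records one video per
session. The video interleaves blurry focus-adjustment frames, clear
evaluation frames showing two embryos in one growth-medium drop, and blurry
embryo-free transition frames while the stage moves to the next drop.
Preparing such videos for downstream deep-learning work requires isolating
each embryo, splitting the stream by drop, and discarding the blurred frames
— by hand, a slow and error-prone job. `embryovision` automates the whole
chain and ships a seeded synthetic video generator so every stage is testable
without clinical data.

## What it does

1. **Frame I/O** — reads numbered frame directories at a declared capture
   rate (clinical default 25 fps) and downsamples to an analysis stream
   (default 5 fps) by keeping every `round(source_fps/target_fps)`-th frame.
2. **Detection** — a pluggable contract: a built-in weight-free classical
   detector (Gaussian smoothing → local-standard-deviation contrast map →
   Otsu threshold → morphological closing → connected components filtered by
   area and circularity 4πA/P²), or a reader for external detector output in
   the normalized text format `class cx cy w h [conf]`, one file per frame.
3. **Organization** — a state machine over per-frame detection counts
   partitions the stream into growth-medium segments (a segment closes after
   `gap_frames` consecutive empty frames; runs shorter than
   `min_len_frames` are discarded), assigns the two embryos of each frame to
   left/right by bounding-box x-center, and writes crops into
   `Day_{3|5}/D{day}_{NNN}/Medium_{MM}/Embryo_{EE}/image_{KK}.jpg`.
4. **Blur filtering** — scores each crop by the population variance of its
   3×3 Laplacian response and keeps it only if the score falls inside the
   day-specific inclusive band: day 3 → [500, 2000], day 5 → [300, 900].
5. **Evaluation** — greedy confidence-ordered IoU matching, precision,
   recall, all-point-interpolated average precision, mAP@0.5 and
   mAP@0.5:0.95.

## Worked example

Simulate a two-drop day-3 session, organize it with the built-in classical
detector, then filter blurry crops with the default day-3 band:

```r
library(embryovision)

cmdSimulate("demo/frames", drops = 2, day = 3, seed = 42)
rep <- cmdOrganize("demo/frames", "demo/library", day = 3, patient = 1,
                   detector = "classical")
rep$segments
#>   drop_index first_frame last_frame duration_s
#> 1          1          80        164       16.8
#> 2          2         175        204        5.8
rep$folder_counts
#> Day_3/D3_001/Medium_01/Embryo_01 Day_3/D3_001/Medium_01/Embryo_02
#>                               85                               85
#> Day_3/D3_001/Medium_02/Embryo_01 Day_3/D3_001/Medium_02/Embryo_02
#>                               30                               30

fr <- cmdClassify("demo/library", day = 3, mode = "delete")
sprintf("kept %d, removed %d (band %g-%g)", fr$kept, fr$removed,
        fr$band[1], fr$band[2])
#> "kept 190, removed 40 (band 500-2000)"
```

The two recovered segments are the two drops: the first spans 85 frames
(a 2 s focus ramp plus a 15 s clear evaluation at 5 fps), the second a short
4 s evaluation. Each drop produces two embryo folders; the blur filter
removes exactly the focus-ramp crops (40 = 2 embryos x 10 ramp frames x
2 drops) and keeps the 190 clear-phase crops.

The same stages are available from a shell via the bundled entry point:

```sh
Rscript inst/exec/embryovision.R run-all --out demo --drops 2 --day 3 --seed 42
```

Evaluation of a detector against ground truth (both in normalized text
format):

```r
cmdEvaluate("preds/", "gts/", width = 256, height = 192)$map50
```

## Documentation

The methods vignette (`vignettes/embryovision.Rmd`) describes the processing
model, the synthetic scene generator and its defaults, parameter choices, and
known limitations.
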