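# cancelr

Quantitative analysis of **cancellation tasks** — the multitarget visual
search tests used in neuropsychology to diagnose hemispatial neglect after
stroke and to measure executive control over search. A participant marks
("cancels") every target embedded among distractors; the spatial spread of
omissions and the geometry of the cancellation path carry the diagnostic
signal. cancelr is for clinicians who need a printable per-session report
and for researchers who need batch scoring of event logs from computerized
or digitized pen-and-paper administrations.

## What it computes

From a task layout and a raw log of pointer-down events `(t, x, y)`, the
package resolves each event to the nearest stimulus and reports:

**Spatial bias**

- Omissions: total and per half of the array, split at the midline between
  the leftmost and rightmost target.
- Center of cancellation (CoC), per axis: the mean cancelled-target
  position standardized so the leftmost target is −1 and the rightmost +1
  (topmost/bottommost vertically).
- First marking: the first cancelled target in standardized array space,
  top-left `(0,0)` to bottom-right `(1,1)`, plus its quadrant.

**Search organization**

- Revisits: immediate (same target twice in a row) and delayed (return
  after cancelling others), with intervening-cancellation counts.
- Mean and standardized inter-cancellation distance (ICD): the mean
  Euclidean step length, and that mean divided by the mean nearest-neighbor
  distance among targets, making it comparable across tasks.
- Intersections: the number of proper self-crossings of the cancellation
  path, and the intersection rate
  `N_intersect / (N_cancellation − N_immediate_revisit)`.
- Best R: `max(|R_hor|, |R_ver|)`, the strongest absolute Pearson
  correlation between cancellation rank and either axis position.
- Standardized angle: per step `γ = arcsin(|Δy|/d)`; the mean of
  `|2γ/90 − 1|` is 1 for axis-aligned movement and 0 for 45° diagonals.

**General performance**

- Duration, mean inter-cancellation time (latency index), cancellation
  rate, search speed `mean(s_i/t_i)` (px/s), and the Q score
  `N_cor² / (N_tar · t_tot)`.

It also generates Landolt-C style task layouts (jittered grid, targets
spread evenly over columns), imports scanned-task coordinate files,
simulates synthetic participants (search strategy, lateralized omission
gradient, revisiting, lognormal timing), renders cancellation-path plots,
best-R rank plots, Gaussian-kernel heatmaps scaled to optimal performance,
and a single-page A4 PDF summary.

## Worked example

```r
library(cancelr)

task <- generate_landolt_task(1280, 1024, n_targets = 64,
                              distractor_ratio = 2, seed = 1)
log  <- simulate_session(task, simulation_config(seed = 2,
                                                 pointer_noise_px = 0,
                                                 time_limit_s = NULL))
report <- analyze(task, assign_events(task, log))
report
```

```
<measure_report> landolt_c
  omissions_total        0
  revisits_total         0
  coc_horizontal         0.00159258
  duration_s             72.189
  mean_ict_s             1.12029
  q_score                0.886562
  mean_icd_px            202.558
  standardized_icd       2.3323
  search_speed           198.406
  standardized_angle     0.838264
  best_r                 0.989614
  intersections_count    0
  intersections_rate     0
  first_quadrant         top-left
  ...
```

A noiseless serpentine sweep of a 64-target array cancels everything
(omissions 0, Q ≈ 0.89), never crosses its own path (intersection rate 0),
and progresses almost perfectly monotonically down the array
(best R ≈ 0.99) with predominantly horizontal steps (standardized angle
0.84). A simulated leftward-neglect gradient instead drives
`omissions_left` up and `coc_horizontal` toward +1.

Write outputs with `write_summary(report, "summary.tsv")`,
`plot_path(task, seq, "path.png")`, `render_pdf(report, task, seq,
"report.pdf")`, or score a whole directory with `batch_analyze()`. The
same workflows are available from a shell via `inst/cli/cancelr`
(`generate-task`, `simulate`, `analyze`, `batch`).

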