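---
title: "Measuring spatial bias and search organization in cancellation tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatial bias and search organization in cancellation tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cancelr)
```

## The measurement problem

A cancellation task presents an array of targets among distractors and asks
the participant to mark every target. Two clinically distinct signals live
in the resulting data. The first is *spatial bias*: hemispatial neglect
after (typically right-hemisphere) stroke shows up as lateralized
omissions and a cancelled-target centroid displaced toward ipsilesional
space. The second is *search organization*: how systematically the
participant traverses the array, which indexes executive control and
spatial working memory rather than lateralized attention.

cancelr works entirely in screen pixel coordinates — origin at the
top-left, y increasing downward — because that is what pointer hardware
reports and it makes the vertical center-of-cancellation convention
(topmost target = −1) fall out without a sign flip.

## From events to a cancellation sequence

A session is an ordered log of pointer-down events `(t, x, y)`. Each event
is assigned to the nearest stimulus within a hit radius; events on
distractors (false alarms) or on empty space are retained but excluded
from every measure, because the cancellation path is defined by cancelled
targets only. The default hit radius is **half the mean nearest-neighbor
distance between stimuli**: it adapts to stimulus density and guarantees
two neighboring stimuli can never both claim a click halfway between
them. An exact distance tie goes to the lower stimulus id, so assignment
is deterministic.

Repeated cancellations of one target are *revisits*: **immediate** when
the same target is cancelled twice in a row, **delayed** when the
participant returns after cancelling others. Both are genuine behavior
(working-memory accounts of neglect rest on them), so delayed revisits
stay on the path; immediate revisits collapse onto the previous point and
would create zero-length path steps, so they are excluded from all path
geometry. The number of cancellations intervening before a delayed
revisit is recorded per cancellation.

## The measure roster

With `s_i`, `t_i` the length (px) and duration (s) of the step between
consecutive path cancellations:

* **Omissions** — uncancelled targets, split at the vertical midline
  halfway between the leftmost and rightmost target centers. A target
  exactly on the midline counts left (a fixed, documented tie-break).
* **Center of cancellation** — each cancelled target's coordinate is
  mapped linearly so the extreme targets sit at −1 and +1; the measure is
  the mean over all non-immediate-revisit cancellations. Averaging over
  cancellations (not unique targets) was a genuinely open choice; we keep
  delayed revisits in because they re-express the attentional pull of
  that location, and expose `unique_targets = TRUE` for the other
  reading.
* **Standardized ICD** — `mean(s_i)` divided by the mean
  nearest-neighbor distance among targets. The denominator is the natural
  unit of one "minimal" search step, which is what makes the ratio
  comparable across arrays with different spacing; a uniform rescaling of
  all coordinates cancels exactly.
* **Search speed** — `mean(s_i / t_i)`: the per-step speeds are averaged,
  not total distance over total time, so one long pause does not swamp
  the estimate.
* **Q score** — `N_cor^2 / (N_tar * t_tot)`: accuracy enters squared so
  that, at equal accuracy, Q reduces to cancellations per second scaled
  by accuracy.
* **Intersections** — every unordered pair of path segments is tested for
  a proper crossing: the pair's determinant must be nonzero and the
  crossing point strictly interior to both segments (parametric
  coordinates in the open interval (0, 1), with a 1e-9 relative
  tolerance). Consecutive segments share an endpoint and therefore never
  count; collinear overlapping segments have no single crossing point and
  count zero. The rate divides by cancellations minus immediate
  revisits.
* **Best R** — the larger absolute Pearson correlation of cancellation
  rank against x or against y. An axis with zero positional variance is
  skipped; if both axes are degenerate the measure is missing.
* **Standardized angle** — per step `γ = arcsin(|Δy| / d)` in degrees;
  using the magnitude of Δy keeps γ in [0°, 90°] (the signed form is
  ambiguous under the screen's y-down convention and changes nothing
  after the fold). The summary `mean(|2γ/90 − 1|)` maps horizontal and
  vertical steps to 1 and 45° diagonals to 0. It complements best R:
  an inward spiral is organized (axis-aligned steps, high standardized
  angle) yet shows low rank-position correlation.
* **First marking** — the first cancelled target mapped into the target
  bounding box as the unit square; quadrant labels split at 0.5
  (boundary counts left/top, mirroring the midline rule).

Any measure that is undefined for a session — no cancellations, fewer
than 3 for best R, zero duration, all targets on one coordinate — is an
explicit `NA` carrying a reason string that propagates into summaries and
the PDF report. Nothing degenerates silently to zero.

## Task generation

The Landolt-C generator lays `n` stimuli on an `r × c` grid chosen by
enumeration: minimize unused cells, break ties by the cell aspect ratio
closest to the display aspect ratio, then prefer more columns. Targets
are spread evenly over columns (per-column counts differ by at most one;
rows within a column drawn without replacement) so no horizontal band of
the array is target-poor — essential when the left/right omission split
is the diagnostic. Each stimulus is jittered uniformly within ±`jitter` ×
cell size per axis; the default 0.2 keeps stimuli visually irregular
while guaranteeing non-overlap for jitter < 0.5. The margin default is
2 % of each dimension. Even spread is constrained over columns only; row
occupancy is left random, matching how such arrays are described and
pictured.

## The simulator

`simulate_session()` is the package's synthetic participant. It emulates,
under one seed:

* **strategy** — serpentine sweeps (row- or column-wise boustrophedon),
  an inward spiral (repeatedly peeling the convex boundary ring of the
  remaining targets, clockwise from the top-left-most, with collinear
  boundary points kept on the ring), or a random permutation;
* **lateralized omissions** — each target is skipped with probability
  `base + slope · x_std`, clamped to [0, 1]; a linear gradient over
  standardized horizontal position is the simplest form consistent with
  the attentional-gradient view of neglect;
* **revisits** — immediate revisits duplicate the current click;
  delayed revisits insert a return to a uniformly chosen
  earlier-cancelled target;
* **timing** — inter-click intervals are lognormal (default meanlog 0.1,
  sdlog 0.35, i.e. a median near 1.1 s and a mean near 1.2 s, the scale
  reported for healthy adults), chosen for positivity and right skew;
* **pointer noise** — isotropic Gaussian scatter (default SD 5 px,
  a realistic touch/mouse scatter) around the target center;
* **time limit** — default 120 s, the conventional 2-minute
  administration.

What it does **not** emulate: memory decay or any cognitive process model,
eye–hand coupling, fatigue drift, or stimulus-similarity confusions.
Passing tests therefore demonstrate that the measures recover *known
generative structure* (gradient direction, strategy organization,
determinism), not that they are clinically valid on real patients —
validation against patient data is outside what synthetic sessions can
show.

## Heatmaps

For cancellations, omissions and path intersections, an isotropic
Gaussian kernel is added at each location on a binned field (default bin
8 px, kernel SD = half the mean nearest-neighbor target distance, the
same adaptive scale unit used elsewhere). The field is then scaled to the
field an *optimal* performance would produce — a kernel on every target —
so heatmaps are comparable between individuals and tasks. "Scaled to"
admits two readings; we divide by the scalar maximum of the optimal field
(the all-targets map then peaks at exactly 1), and offer elementwise
division as a switch for users who prefer a per-location completion
ratio. The unnormalized cancellation and omission fields of complementary
target sets sum exactly to the optimal field, which the tests assert.

## Numerical and testing choices

Writers format floats to 6 significant digits, making every output file
byte-deterministic. All randomness (generator, simulator, CLI) flows from
explicit integer seeds through a scoped RNG so library calls never
disturb the session's RNG state.

The intersection counter is verified against an independently coded
brute-force oracle that uses the orientation (CCW) predicate rather than
the parametric solve, over a thousand random paths, alongside worked
four-point crossing and non-crossing examples. Property suites use
problem sizes chosen to exercise the geometry at desk scale: arrays of
12–64 targets, 50 seeded runs for the omission-gradient/CoC monotonicity
check, and 100 seed pairs for the random-vs-serpentine intersection
contrast.

## Known limitations

* Published group values for these measures come from real participants;
  the package's simulations reproduce the *structure* of such data, not
  its norms, and none of its outputs are norm scores.
* Hit-testing is nearest-within-radius on pointer-down events only; drag
  gestures and multi-touch are not interpreted.
* Importing a scanned task takes a coordinate file (with the marking done
  elsewhere); only PNG backgrounds are drawn under path plots.
* The qualitative path-pattern taxonomies from the literature are
  deliberately not implemented; the quantitative organization measures
  and the plots cover that ground.
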