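---
title: "Models and methods behind astrotile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind astrotile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astrotile)
```

## The problem

Protoplasmic astrocytes organize into *tiled* territories: each cell ramifies
into a dense multi-order arbor, yet its branches rarely touch or cross the
branches of a neighbouring astrocyte. Quantifying this behaviour from 2-D
culture images requires a chain of operations — binarize, thin to a skeleton,
decompose the skeleton into branches, attribute branches to cells, compute
per-cell morphometrics (branch counts, total length, topological branch order,
bounding-rectangle coverage), and flag *tiling violations*, branches of one
cell that touch or override branches of another. `astrotile` implements that
chain, together with a synthetic-culture generator that provides ground truth
for validating every stage, and the statistical tools used on the resulting
tables (mean ± s.e.m. time courses, reference-normalized series, per-image
Pearson correlation matrices, one-way ANOVA with Tukey / Tukey–Kramer
post-hoc comparisons).

No imaging data are redistributed with the package; all tests and the
acceptance script run on synthetic cultures generated in code.

## The growth model

The generator is an agent-based tip-extension model. Its rules are
deliberately minimal and encode one idea: **branches grow where other
branches are not**.

* Somata are placed on a jittered grid (the layout of a confluent culture)
  with a guaranteed minimum spacing; for sparse configurations a
  rejection-sampling fallback is used. Placement failure names
  `soma_min_spacing` in its error.
* Each cell seeds `primaries_per_cell` tips at its soma with evenly spaced
  initial headings.
* Per step, an active tip draws up to `n_candidate_dirs` candidate headings
  (previous heading + Gaussian noise, s.d. `angle_noise_sd` radians) and takes
  the first whose new segment of length `step_length` stays inside the field
  margin and passes the avoidance tests. If every candidate fails, the tip
  stalls *permanently* — stalling keeps the simulation monotone and
  reproducible.
* **Contact repulsion** (`repulsion = TRUE`): a candidate segment is rejected
  if it passes within `avoid_radius` of any segment, or the soma, of a
  different cell. This is a hard constraint, so a repulsive culture has
  essentially zero tiling violations by construction; the measured violation
  percentage on rendered skeletons stays far below the 5% ceiling reported
  for mature cultures.
* **Self-avoidance** (`self_avoidance = TRUE`, default on in both regimes):
  the same test against the cell's own segments, excluding segments incident
  to the tip's node, its parent and its grandparent. The exclusion window is
  what lets a branch take its next step and lets freshly spawned siblings
  separate; it implies the usable `avoid_radius` is at most roughly twice
  `step_length`, which is why the sparse configurations used for image
  round-trip checks raise `step_length` together with `avoid_radius`.
* After a successful extension the tip splits with probability `branch_prob`
  into two tips whose headings diverge by `divergence_angle`.

Proximity queries run against a uniform spatial hash grid with cell size
`avoid_radius`; the growth loop is compiled (Rcpp) and draws all randomness
from R's RNG, so a culture is a pure function of `(params, seed)`.

Because nodes are only appended, a run with fewer steps is an exact prefix of
a longer run with the same seed: `snapshot_culture()` recovers earlier
developmental time points (DIV analogues) from a single simulation by
filtering nodes on their creation step.

### Presets and calibration

The biology constrains only the phenomenology — tiled territories, deep
branch orders, retraction phenotypes — not the growth rules, so all parameter
values are calibration choices of this package, fixed once and documented
here:

* `"tiled-DIV15"`: 9 cells on a 900×900 px field, soma spacing ≥ 200 px,
  5 primaries, step 3 px, noise 0.4 rad, branch probability 0.35, divergence
  1.2 rad, avoid radius 4 px, 8 candidates, 200 steps, repulsion and
  self-avoidance on. Growth saturates before 200 steps at roughly 2,000
  branches and 20,000 px of arbor per cell; territories tile the field and
  maximum topological branch order lands well above 20, matching the
  qualitative description of a mature (DIV15) culture (orders beyond 20,
  violations below 5%).
* `"neutral"`: identical except `repulsion = FALSE` and 60 steps. Without
  repulsion growth is space-filling and unbounded, so the preset stops at the
  territorial-overlap horizon; branches freely cross neighbouring arbors and
  violation percentages in the tens of percent result.

### Excitotoxic retraction

`apply_retraction()` emulates the glutamate-excitotoxicity phenotype. Each of
`n_rounds` rounds deletes every *terminal branch* (the chain from a tip back
to, but excluding, the nearest branch point) independently with probability
`terminal_prune_prob`; branch points left with a single child fuse into
pass-through chains at the next branch decomposition. With
`exploration = TRUE`, surviving tips then extend a few short segments with no
avoidance test. The defaults (prune 0.5, 2 rounds, 4 exploration steps)
reproduce the reported direction of every summary: branch count, total length
and maximum order fall; the bounding-rectangle territory changes only
marginally (terminal branches are short relative to the territory); and the
violation percentage rises, because boundary tips now regrow blindly into
neighbouring territories. With exploration off the operation is provably
monotone (count, length, order never increase), which the tests assert.

## Image pipeline

* **Binarization** is strict (`intensity > threshold`); Otsu's threshold is
  computed from a 256-bin histogram and errors on constant images.
* **Skeletonization** is homotopic thinning: a pixel is deleted when its
  Yokoi connectivity number (8-connectivity) is 1 and it has 2–7 foreground
  neighbours (endpoints are preserved; a fully interior pixel is never
  simple). Deletions are applied over the four
  (row mod 2, col mod 2) colour classes; same-colour pixels are never
  8-adjacent, so each parallel pass equals sequential simple-point removal:
  component counts are preserved and iteration to a fixed point makes the
  operation idempotent. One irreducible case remains: the homotopic skeleton
  of an even-width X crossing is a 2×2 plateau whose four pixels all classify
  as junction pixels; deleting any of them would disconnect an arm.
  `extract_graph()` fuses such plateaus into a single junction node — the
  same behaviour as ImageJ's AnalyzeSkeleton — while genuinely non-thin
  input (any filled 2×3 block) raises an error.
* **Graph extraction** classifies pixels by neighbour count (1 endpoint,
  2 path, ≥3 junction), fuses 8-adjacent junction pixels into one node, and
  traces pixel chains into branches whose length is the step sum — 1 per
  orthogonal, √2 per diagonal step, the ImageJ convention. Components that
  are pure cycles get an anchor node of kind `"loop"` and one self-loop edge.
* **Despurring**: thinning a 3-px-wide line leaves 1–2 px side spurs whose
  junction clusters swallow centerline length. `prune_spurs()` removes the
  pixels of terminal edges shorter than 3 px (configurable), re-thins and
  repeats — the deterministic stand-in for the manual skeleton editing that
  an expert would perform. After despurring, the render → binarize → thin →
  extract → assign round trip recovers per-cell total length to within a few
  percent at line width 3 (tip erosion and junction clusters account for the
  small negative bias).
* **Cell assignment** snaps each soma seed to the nearest skeleton pixel
  (≤ 5 px; mid-edge snaps split the edge), then assigns every branch to the
  cell whose soma is geodesically nearest along the graph, weighted by branch
  length. Geodesic rather than Euclidean assignment keeps a branch that
  threads between somata with its own tree. Ties break toward the lower cell
  id and are flagged; unreachable or soma-disconnected branches are reported
  unassigned rather than guessed.

## Morphometry conventions

* **Topological branch order**: soma-incident branches are order 1; crossing
  a junction increments the order. (The alternative convention that primaries
  are order 0 exists; order 1 is used consistently here, so a tip reached
  after one branching event has order 2.) Orders are assigned by a
  bucket-queue traversal; on the rare skeleton cycle, the edge reached from
  two directions receives the minimum order and a flag. Tests verify the
  traversal against independent path enumeration on every cell of randomly
  grown cultures.
* **Branch count** counts skeleton edges (the AnalyzeSkeleton notion of a
  branch), not only terminal segments.
* **Coverage area** is the axis-aligned bounding rectangle of the cell's
  rasterized skeleton pixels, `(max_row − min_row + 1) × (max_col −
  min_col + 1)` — the "bound rectangle" proxy for territory size; rotated
  minimal rectangles are deliberately not used.
* **Tiling violation**: a branch violates when any of its pixels lies within
  Chebyshev distance ε of a pixel of a different cell; ε = 1 means overlap or
  8-adjacency ("touch or override"). ε is exposed as a parameter because any
  manual touch/override judgement depends on magnification and annotator. A branch is counted once regardless of the
  number of partners; same-cell overlaps are tallied separately and excluded.
  Detection uses sorted-key lookups over (2ε+1)² offsets and is tested for
  exact agreement with an all-pairs quadratic reference.

## Statistics

* `mean_sem()` uses the sample s.d. over √n; n = 1 returns s.e.m. 0 with a
  flag.
* `anova_tukey()` computes the one-way ANOVA F and all pairwise comparisons
  with `q = |mᵢ − mⱼ| / √(MSW/2 · (1/nᵢ + 1/nⱼ))` — Tukey's HSD for balanced
  groups, the Tukey–Kramer form otherwise. Adjusted p-values come from the
  studentized range distribution via R's `ptukey` (the Copenhaver–Holland
  algorithm); the test suite checks it against an independent numerical
  integration of the classical double integral (agreement better than 1e−6)
  and against published 5% critical values at k = 3–5, df = 10, 20, ∞.
  With two groups the statistic reduces to the pooled t test via q = t√2.
* `correlation_matrix()` computes Pearson correlations per image and averages
  them unweighted across images — the convention for reporting average
  per-image correlation coefficients across independently prepared samples.
* `normality_report()` (Shapiro–Wilk per group) is informative only and never
  gates any computation, mirroring how normality assessment precedes but does
  not alter the ANOVA pipeline.
* `generate_marker_table()` draws lognormal marker intensities through a
  Gaussian copula (symmetric matrix square root of the target correlation).
  The default target uses the five reported transporter-pair correlations
  (GLAST–GLT1 0.23, GLAST–GAT3 0.46, GLAST–AQP4 0.27, GLT1–GAT3 0.46,
  GLT1–AQP4 0.39) and 0.30 for the unreported GAT3–AQP4 pair — a value chosen
  inside the reported "weak correlation, below 0.5" band that keeps the
  matrix positive definite. At n ≥ 1000 the Gaussian-score sample correlation
  recovers the target to within ±0.05; the lognormal marginals attenuate the
  Pearson correlation of the intensities themselves slightly, which is why
  recovery is asserted on the scores.

## What the generator does and does not emulate

It emulates: multi-order arbors radiating from somata; exclusive territories
under repulsive growth and overlapping arbors under neutral growth;
development as monotone accretion (snapshots); terminal retraction with
exploratory regrowth; weakly correlated per-cell marker intensities; and
rasterization with controllable line width and Gaussian noise.

It does not emulate: sub-resolution spongiform processes, intensity
heterogeneity along branches, anisotropic or out-of-focus optics, soma
morphology (somata are points), branch thickness variation, or any molecular
mechanism. Passing tests therefore validate the *measurement chain* and the
qualitative regime contrasts, not any quantitative claim about real
astrocytes: absolute branch counts and lengths of the presets are calibration
artifacts.

## Numerical choices and problem sizes

Coordinates are continuous during growth and rounded to a 0-based, row-major
(row, col) pixel grid at rasterization; SWC export writes x = col, y = row
with `%.17g` precision so round trips are lossless. Chebyshev ε is floored to
an integer because pixel distances are integers. All stage seeds derive from
one root seed by a multiplicative congruential split (`derive_seed`), and
every generator is a pure function of `(params, seed)`.

The test suite exercises the full `tiled-DIV15` preset for the headline
checks (20 cultures for the tiling bound, 20 seed pairs for the retraction
contrast) and deliberately smaller cultures (3–4 cells, 200–500 px fields,
20–120 steps) for property checks and brute-force equivalences, where the
quadratic references are feasible; these sizes are stated in the tests
themselves.

## Known limitations

* The violation statistic depends on ε and on line width through
  rasterization; comparisons are meaningful only at fixed settings.
* Junction clusters absorb a pixel or two of length at every crossing, giving
  image-derived total lengths a small negative bias relative to ground truth.
* Neutral-regime growth is space-filling; long neutral runs are expensive and
  biologically uninformative, hence the short neutral preset.
* Geodesic assignment cannot recover ownership where two cells' skeletons
  merge into one connected component at line widths comparable to the
  inter-branch gap; the repulsive regime avoids this by construction.
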