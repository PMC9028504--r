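# astrotile

Quantitative analysis of astrocyte branching and territorial **tiling** in
2-D microscopy-like images, plus an agent-based synthetic-culture generator
for validating every stage of the measurement chain.

Protoplasmic astrocytes ramify into dense multi-order arbors that occupy
near-exclusive territories: branches of one cell rarely touch or cross
("violate") branches of a neighbour. `astrotile` is for researchers who want
to measure that organization from skeletonized images — and for method
developers who need ground-truth benchmarks for skeleton-based morphometry.

## What it computes

Given a grayscale image plus soma seed coordinates (or SWC trees directly),
the pipeline runs

1. **binarize** — fixed or Otsu (256-bin histogram) threshold, strict `>`;
2. **skeletonize** — homotopic thinning to a 1-px, 8-connected skeleton
   (component counts preserved, idempotent), plus despurring of sub-3-px
   terminal artifacts;
3. **extract** — AnalyzeSkeleton-style graph: endpoint/junction/path pixel
   classification, fused junction clusters, branch polylines with length
   = 1 per orthogonal + √2 per diagonal step;
4. **assign** — each branch goes to the cell whose soma is geodesically
   nearest along the skeleton;
5. **measure** — per cell: branch count, total branch length, axis-aligned
   bounding-rectangle coverage area, and **topological branch order**
   (soma-incident branches are order 1; each junction crossed adds 1, so a
   branch of order *k* lies beyond *k − 1* branching events);
6. **tiling violations** — a branch of cell *i* violates when any of its
   pixels lies within Chebyshev distance ε (default 1 = touch/overlap) of a
   pixel of a different cell; summarized per branch, per cell and per
   culture;
7. **statistics** — mean ± s.e.m. time courses, series normalized to a
   reference timepoint, per-image-averaged Pearson correlation matrices of
   marker intensities, and one-way ANOVA with Tukey / Tukey–Kramer post-hoc
   comparisons (studentized range distribution via `ptukey`),
   `q = |mᵢ − mⱼ| / √(MSW/2 (1/nᵢ + 1/nⱼ))`.

The synthetic generator grows branch trees by candidate-rejection **contact
repulsion** — a tip proposes noisy headings and takes the first whose new
segment stays clear of other cells' arbors — which reproduces tiled
territories; switching repulsion off gives the overlapping "neutral" control.
An excitotoxic-retraction perturbation (prune terminal branches, then
exploratory non-avoiding regrowth) reproduces the reported glutamate
phenotype: fewer/shorter/less complex branches, unchanged coverage area, more
violations.

## Worked example

```r
library(astrotile)

params  <- growth_preset("tiled-DIV15", n_cells = 4, field_size = c(500, 500),
                         soma_min_spacing = 150, n_steps = 120)
culture <- generate_culture(params, seed = 1)
cells   <- culture_to_skeletons(culture)

culture_metrics(cells)
#>   cell_id branch_count total_length bounding_rect_area max_order
#> 1       1         1237         8133              87080        42
#> 2       2         1279         8061             102941        44
#> 3       3         1137         7368              74562        36
#> 4       4         1371         8541              89544        42

detect_violations(cells, epsilon = 1)
#> Tiling violations (epsilon = 1): mean 0.00% of branches per cell, 0% of cells affected

# glutamate-excitotoxicity analogue: terminal retraction + exploratory regrowth
glu <- apply_retraction(culture, retraction_params(), seed = 2)
glu_cells <- culture_to_skeletons(glu)
culture_metrics(glu_cells)
#>   cell_id branch_count total_length bounding_rect_area max_order
#> 1       1          360         7539              90746        19
#> 2       2          407         7866             108192        19
#> 3       3          351         6930              71208        18
#> 4       4          398         7884              93288        19

detect_violations(glu_cells, epsilon = 1)
#> Tiling violations (epsilon = 1): mean 5.37% of branches per cell, 100% of cells affected

anova_tukey(list(control   = culture_metrics(cells)$branch_count,
                 glutamate = culture_metrics(glu_cells)$branch_count))
#> One-way ANOVA: F(1, 6) = 301.955, p = 2.328e-06
#> Tukey HSD post-hoc comparisons (alpha = 0.05):
#>  group_a   group_b diff    se     q     p_adj significant
#>  control glutamate -877 35.69 24.57 2.193e-06        TRUE
```

Reading the numbers: the repulsive culture tiles perfectly (0% violations)
while each cell's arbor branches more than 35 times along its deepest path;
after the retraction perturbation the branch count collapses (≈1250 → ≈380)
and the maximum order halves, yet the bounding-rectangle territory is nearly
unchanged and violations appear in every cell — the direction of every
reported excitotoxicity effect.

Image-based analysis takes the same objects through the raster route:

```r
rr     <- render_image(culture, line_width = 3, noise_sd = 0)
somata <- data.frame(cell_id = seq_along(culture$cells),
                     row = culture$somata[, "y"], col = culture$somata[, "x"])
cells_img <- cells_from_image(rr$image, somata)   # binarize -> thin -> extract -> assign
```

`simulate_experiment()` / `analyze_experiment()` wrap the whole chain behind
a validated JSON-able config (SWC trees, soma CSVs, 16-bit TIFFs, tidy CSV
tables, manifest with seed and parameter hash); `inst/cli/astrotile.R` is a
thin command-line front end over the same functions. See the methods
vignette (`vignettes/astrotile-methods.Rmd`) for the model, conventions and
their rationale.

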