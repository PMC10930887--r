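---
title: "Quantifying stromal invasion fronts, forks, motility, and gene-set module scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stromal invasion fronts, forks, motility, and gene-set module scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ansia)
```

# The assay and its geometry

A nanopatterned stromal invasion assay patterns a fluorescently labeled
epithelial monolayer against an unlabeled stromal monolayer along a
straight interface; anisotropic nanogrooves orthogonal to that interface
bias motion so the epithelium's advance into the stroma is effectively
one-dimensional. The package adopts one fixed coordinate convention for
every formula: image rows (axis 0) run in the invasion direction, with
increasing row index going *into* the stroma; columns (axis 1) run along
the initial interface; pixel indices are 1-based inside R functions
while CSV interchange uses the 0-based frame numbering of the source
movies. The interface reference is the *frame-0* interface row and stays
fixed over time — the normalization below divides by the *initial*
interface length, which only makes sense against a fixed reference line.

Time defaults mirror typical acquisition: 60 min between invasion
frames and 10 min between migration frames, both overridable.

# Normalized extent of invasion

With $A(t)$ the area of labeled epithelium strictly beyond the initial
interface line and $L_0$ the length of interface spanned by the
monolayer at frame 0,

$$E(t) = \frac{A(t) - A(t_0)}{L_0},$$

a length (pixels, or microns when `pixel_size` is set). Two estimators
of $A$ are provided and agree for single-valued fronts: pixel counts on
a segmented mask, and the shoelace area of a traced ROI polygon. A
uniform advance of $d$ pixels across the full interface gives $E = d$
exactly; a linear (triangular) advance profile gives $E = d/2$ up to
rasterization.

Cells that detach from the monolayer and sit ahead of the front are a
genuine ambiguity. The package counts *all* labeled pixels beyond the
interface toward area (keeping $E$ faithful to total invaded area), but
restricts the depth profile $d(x)$ to connected components touching the
monolayer (keeping $d(x)$ single-valued for fork calling). Both
behaviors sit behind the `detached` argument of `extract_front()`.

# Front profiles, smoothing, and the fork rule

`extract_front()` reads, per column, the furthest epithelium pixel
beyond the interface; columns the epithelium does not reach are *invalid*
(`NA`), never zero — a zero would silently count as "no invasion" in
every downstream mean.

`smooth_profile()` is a centered moving average of width `window`
(default 20 px). Design choices that matter numerically:

* **Edges truncate.** The window shrinks at the profile ends rather than
  padding by reflection or zeros; padding would invent mass where the
  monolayer simply ends.
* **Even windows are asymmetric.** A 20-px window covers 10 px to the
  left and 9 px to the right of the center. One consequence worth
  knowing: smoothing does not commute with mirroring the profile, while
  the *detection rule itself* is mirror-equivariant (the test suite
  checks exactly that separation).
* **Invalid positions are excluded** from each average; a position whose
  whole window is invalid stays invalid.

`detect_peaks()` implements the side-window rule: position $x$ qualifies
when the smoothed value at $x$ strictly exceeds the mean signal over the
40 px immediately left *and* (separately) the 40 px immediately right.
The flanking means are taken on the **raw** profile by default — the
rule contrasts flanking *signal* with the *smoothed* center value — with
`compare = "smoothed"` available for a smoothed-vs-smoothed reading.
Further conventions the rule needs but a one-sentence description leaves
open, fixed here once:

* **Strict inequality**: equality does not qualify, so a flat profile
  has no peaks.
* **Truncated flanks** near the edges must retain at least half the side
  window (20 valid px), otherwise the position cannot qualify. This
  means no position within 20 px of a profile end can ever be a peak —
  a structural property of the rule, not of this implementation.
* **Run collapse**: contiguous qualifying positions become one peak at
  the run's argmax of the smoothed profile, leftmost on ties.
* **Intervals**: consecutive peaks are separated at floor midpoints; the
  first interval starts at the profile start and the last ends at the
  profile end, so intervals always partition the profile. (For the
  degenerate case of adjacent integer peaks the floor midpoint places
  the boundary at the right peak; such peaks cannot come out of
  `detect_peaks`, which collapses contiguous runs first.)

Fork **depth** is not uniquely defined by a depth distribution figure
alone, so both conventions are exposed: from the *initial interface*
(default — the maximum $d(x)$ over the fork's interval, consistent with
the fixed-reference convention above) or above the *local baseline*
(subtracting the smaller boundary depth, i.e. the fork's prominence).

A property worth stating because it is easy to over-read detection
results: the side-window rule is invariant to adding a constant and to
positive scaling of the profile, so it has **no amplitude floor**. On
i.i.d. Gaussian noise profiles (any sd) it fires at a measured rate of
~53 qualifying peaks per 1000 px (1000-replicate measurement frozen into
the test suite as a ≤ 60/1000 px bound). On rendered assay images this
is harmless — flat fronts rasterize to integer-quantized profiles where
strict exceedance rarely fires, and the benchmark stacks below yield
zero false positives — but the rule should not be applied to continuous
noisy profiles without the smoothing/rendering context it was designed
for.

# Motility metrics

Per track with at least two points: displacement (start-to-end
distance), path length (sum of step lengths), velocity (path length over
elapsed time — mean speed, not net displacement rate, with the latter a
documented alternative), and directionality. "Directionality" is
implemented as the confinement ratio displacement/path ∈ [0, 1], the
common tracking-software reading; the mean cosine of successive turning
angles is available via `directionality = "mean_cos"`. Missing frames
contribute their actual time gap; no positions are interpolated, since
invented points would bias path length. Metrics are invariant to rigid
rotation and translation (tested).

# Gene-set module scores

The score of cell $c$ for gene set $S$ is the mean over $S$'s genes of
gene-wise z-scaled expression — a per-cell Z score for the set. The
processing chain is: optional library-size normalization to 10,000
counts per cell followed by `log1p` (the conventional treatment of raw
counts; `method = "none"` passes pre-normalized matrices untouched),
then each gene centered and scaled to unit variance across **all** cells
(zero-variance genes dropped with a warning — they carry no per-cell
information), then per-set means, then Pearson correlations between set
scores computed **within** cell groups (e.g. tumor subtypes), with
two-sided p-values from the $t$ distribution with $n-2$ df. Scaling
globally and correlating within groups follows the analysis design this
package reproduces; per-group scaling is a caller-side subset away. A
set with zero overlap with the matrix yields a *missing* score column
with a warning, never zeros. Groups need ≥ 3 cells for a defined
p-value.

# What the generators emulate — and what they do not

**`simulate_front_stack()`** evolves a true front height field
$h(x,t) = vt + \sum_k \text{bump}_k(x,t)$: uniform advance at $v$
px/frame plus invasive forks nucleating as a Poisson process (rate per
frame per 1000 px), each a Gaussian bump (sd `fork_width_sigma`, planted
depth $\sim N(\mu, \sigma)$ truncated at 0) ramping linearly to full
depth over `ramp_frames` = 3 frames. Frames render epithelium at
intensity 0.8, stroma at 0.2, plus i.i.d. Gaussian intensity noise
(sd 0.05 by default — a high-contrast fluorescence channel). The default
geometry, 512 × 512 px with the interface at row 256 and 25 hourly
frames, mirrors one field of view observed for 24 h; defaults of
2 px/frame advance, 0.2 forks/frame/1000 px, and 40 ± 5 px fork depth
produce fronts that look like the assay's. Ground truth ($h$, the fork
registry, and `true_front_mask()`) scores every downstream stage.

Not emulated: single-cell texture within the monolayer, uneven
illumination, photobleaching, curved or drifting interfaces, fork
retraction, and cell-scale mechanics. Passing benchmarks on these
synthetic stacks therefore demonstrates correctness of the
*quantification chain* under controlled conditions — not robustness to
every imaging artifact of real movies.

**`simulate_tracks()`** is a persistent biased random walk: headings
start along +x and turn by von Mises increments with concentration
$\kappa$ (sampled with a Best–Fisher rejection sampler implemented in
the package and tested against the analytic resultant length
$I_1(\kappa)/I_0(\kappa)$); per step the cell moves
`drift_speed * dt` along its heading plus isotropic Gaussian noise.
Limits used as oracles: $\kappa \to \infty$, zero noise gives straight
tracks with directionality exactly 1; zero drift, $\kappa = 0$ gives
pure diffusion whose mean displacement follows the Rayleigh form
$\sigma\sqrt{n\,\pi/2}$.

**`simulate_expression()`** draws per-cell latent module activations
from a multivariate normal with the planted per-group correlation
(eigen-factorized, so the boundary cases $|\rho| = 1$ are admitted and
indefinite structures rejected), shifts module genes' log-means by
0.8 × activation, and samples negative-binomial counts (mean 5,
dispersion 0.5) or Gaussian values directly on the log scale. Defaults:
1000 genes with two 50-gene modules — signature-sized sets occupying a
realistic ~10% of the simulated transcriptome.

One attenuation effect is worth understanding rather than hiding:
library-size normalization couples every gene to the cell's total
counts, so when module genes are a noticeable compositional fraction,
the correlation recovered between module scores is attenuated relative
to the planted latent correlation (measured: $r \approx 0.17$ recovered
from $\rho = 0.5$ at a 40% module fraction; $\approx 0.42$ at 10%). This
is a property of compositional normalization, not of the scoring code.
The recovery benchmark therefore runs the Gaussian-on-log model through
the pre-normalized path, which recovers the planted value directly,
while the count path is separately checked for sign and approximate
magnitude.

# Benchmark bookkeeping

Fork detection is scored against the generator registry by *coverage*
matching (a planted fork is recovered if any detected peak lies within
$2\sigma$ of its center, many-to-many) because overlapping planted
bumps merge into one physical protrusion with a single peak — demanding
one detection per registry row would count merged forks as misses. The
recall denominator contains *scorable* forks: those that have completed
their depth ramp by the scored frame and whose center lies more than
20 px (half a side window) from the profile edge, the rule's evaluable
domain as noted above. Immature and edge forks still absorb detections,
so they are never false positives. All of this is explicit in
`score_fork_detection()` arguments.

Problem sizes used by the benchmark suite and `scripts/acceptance.R` —
20 (suite) or 12 (script) default-geometry stacks for fork recovery, 200
random profiles for peak-rule oracle equivalence, 100 for smoothing, 2000
tracks for the Rayleigh check, 20–100 replicates of 2000-cell matrices
for correlation recovery — were chosen as the smallest sizes at which
the targeted tolerances are comfortably non-marginal.

# Degenerate inputs and numerical conventions

* Uniform frames refuse to segment ("degenerate segmentation") rather
  than returning an arbitrary mask; so do frames that threshold to
  all-foreground/background or empty after cleanup.
* A front reaching the interface nowhere yields an all-invalid profile
  with a warning, not zeros.
* `fold_change()` requires a positive control mean; with zero variance
  in both arms (possible in noiseless simulation) the ratio is still
  reported and the t-based p-value is `NA`.
* Fork-depth comparisons with n < 2 in either arm return descriptive
  quantiles only.
* Correlation of a score with itself is exactly 1; zero-variance score
  vectors give `r = NA` with a warning.
* TIFF stacks are written as 32-bit float pages: lossless for the
  simulator's clamped [0, 1] intensities to single precision (< 1e-9
  for unit-scale data).
* All generators are bit-reproducible given `seed`; the pipeline writes
  a provenance JSON (parameters, seed, package version, input hashes)
  from which a rerun reproduces every CSV byte-identically.

# Interfaces and scope

The package surface is R functions plus the numbered driver scripts
under `analysis/`; `run_invasion_pipeline()` and `make_report()` provide
the end-to-end orchestration, and no separate shell CLI is shipped —
the artifact is an analysis toolkit, not a command-line tool. The
shipped gene lists under `inst/extdata` are *synthetic, illustrative*
placeholders (so marked in their filenames and README): real analyses
must supply curated signature lists. Out of scope by design: nucleus
segmentation and tracking, optical-flow front tracking, curved-interface
geodesics, clustering/UMAP/differential expression of real single-cell
data, and mechanistic (vertex/Potts) simulation.

# Known limitations

* The fork rule's lack of an amplitude floor (above) makes it unsuitable
  for unsmoothed continuous noise; depth thresholds, if desired, must be
  applied downstream on the reported `depth_px`.
* `E(t)` assumes a straight initial interface; curved interfaces would
  need geodesic interface lengths, which are not implemented.
* Area-based `E` counts detached cells; the depth profile does not — for
  assays with heavy single-cell scattering the two diverge, and the
  divergence itself is informative but unmodeled.
* Physical units are attached only when `pixel_size` is supplied;
  otherwise every length is in pixels, flagged in the `units` attribute.
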