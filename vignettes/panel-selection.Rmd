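---
title: "Predictive marker-panel selection: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive marker-panel selection: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelpick)
```

# The problem

Multiplexed tissue imaging measures a fixed panel of protein markers, one
image channel per marker, and the panel size is bounded by chemistry and
acquisition time. Marker intensities are strongly inter-dependent — cell
types and tissue structures express coordinated programs — so a well-chosen
subset of channels carries most of the information of the full set.
`panelpick` formalizes "well-chosen" as: *the subset from which predictive
models reconstruct all remaining channels with the smallest validation
risk*, and searches for a small such subset greedily.

# The graph model

Markers are nodes of a complete directed graph. The loading `w[i, j]` of
edge `(i, j)` estimates how badly marker `j` would be predicted if `i` were
(part of) the observed set:

* At initialization, `w[i, j] = w[j, i]` is the mean absolute per-pixel
  difference between the two channels over the training images. This is the
  risk of the trivial predictor that outputs its input unchanged, hence an
  approximate upper bound on the unpredictability.
* An edge is *activated* when its origin marker is observed. A predicted
  marker's node cost is the minimum loading over its activated in-edges;
  observed markers cost 0. The objective is the total node cost.
* After each round's model refit, the validation risk of predicted marker
  `j` (same L1 measure, on held-out images) overwrites **all** of `j`'s
  activated in-edge loadings. The model predicts from all observed channels
  jointly, so no per-source attribution exists; assigning the joint risk to
  every activated in-edge keeps the node-cost minimum equal to the actual
  measured risk. Edges from predicted to observed markers are never
  updated (unpredictability is directional), and edges between two observed
  markers are zeroed.

The greedy step (`expected_improvement()`) evaluates, for each candidate
`k`, the hypothetical total node cost `psi(k)` with `k` treated as
observed, using current loadings only — no model is refit during the scan —
and adds the minimizer. `psi(k)` never exceeds the current total cost: the
hypothetical minimum runs over a superset of the activated edges and zeroes
`k`'s own cost.

Exhaustive search for a minimal predictive set is combinatorially hard; the
greedy heuristic with risk feedback is the method. Both the selection trace
and the final graph are first-class outputs (`tidy()`, `graph_edges()`,
`write_graph_json()`).

## Choices the formulation leaves open

* **The first marker.** Node costs are undefined while nothing is observed.
  We seed with the marker of minimal *weighted* out-degree (sum of outgoing
  loadings) — the only computable reading of "minimal degree" on a complete
  graph; an unweighted-degree variant is available for comparison
  (`choose_initial_marker(weighted = FALSE)`).
* **Tie-breaking.** Everywhere: the lowest marker index, for determinism
  across platforms.
* **Stopping.** Budget (default; panel sizes are an acquisition constraint),
  mean-cost threshold, or relative improvement (`stopping_*()`).

# Predictors

The selection procedure is independent of the predictive model family. The
reference backend is a per-pixel multi-output ridge regression fit in
closed form on all pooled training pixels (`lambda = 1e-6` purely as a
numerical stabilizer; the intercept is unpenalized). It ignores spatial
context by construction; its virtues are exactness on linearly mixed data,
determinism, and single-CPU speed, which makes every selection-logic claim
testable. The published training protocol for a convolutional
encoder–decoder (192x192 random patches, MSE loss, learning rate 1e-4,
best-validation checkpointing, round-to-round weight inheritance with fresh
input-layer weights for the newly moved channel) is specified in
`predictor_spec()` and `inherit_weights()`, but no deep-learning framework
is a dependency of this package, so `backend = "conv"` raises an
informative error rather than a degraded imitation. Patch tiling and
stitching (`tile_patches()`, `stitch_patches()`) implement the
whole-image inference path any patch-based backend needs: stride-sized
tiles, final row/column re-anchored to the border, overlaps averaged —
`stitch(tile(img))` is exactly `img`.

# Normalization

Three per-channel recipes, all ending in a z-score (population SD,
divide-by-n — matching the definition of a z-score as `(x - mean) / sd(x)`):

* **arcsinh (CODEX):** divide by `max(5 * q20, 15)`, arcsinh, z-score. The
  20th percentile `q20` is computed over **all** pixels by default; the
  printed formula is ambiguous about positive-only pixels, so
  `q_positive_only = TRUE` exposes the other reading.
* **clip/blur (IMC):** clip to `[0, 98th percentile of positive pixels]`,
  Gaussian blur with `sigma = 1.5` px, z-score. The blur uses *reflective*
  boundary handling to avoid darkened tissue borders; it is implemented as
  a separable truncated-Gaussian convolution because the available image
  packages offer only circular/replicate boundaries, and is verified in the
  tests against a brute-force 2-D convolution.
* **plain z-score** for weak, sparse signals.

Degenerate channels (SD below 1e-12) would make the z-score divide by ~0;
the sigma guard outputs zeros and warns instead. Percentiles use the
linear-interpolation convention. Coordinates are (row, col), 0-based patch
positions, half-open intervals.

# Multi-panel setting

When the marker set exceeds one sample's capacity, panels with nonempty
pairwise overlaps (a connected panel graph) are imaged separately. Edge
initialization has three cases: both markers in a shared overlap — average
of the two panels' dissimilarities; both in one panel — that panel's
dissimilarity; different panels — the minimal chained triangle-inequality
bound over connecting paths, `min over paths of sum of legs`, computed as a
shortest path over intra-panel edges (equivalent to enumerating paths
through overlap markers and keeping the minimum; each inferred edge stores
its witness path). Each round retrains only the panel model(s) whose panel
contains the newly selected marker, updates that panel's intra-panel edges
with its per-panel validation risks, and *re-derives* the cross-panel
bounds from the current loadings — frozen Round-0 bounds would ignore
everything the models have learned; `freeze_bounds = TRUE` restores the
frozen behaviour for comparison. When a pair of markers shares more than
one panel, the assembled loading is the per-panel average while all values
are initial dissimilarities and the per-panel minimum once any of them is a
model risk: node costs take the minimum over activated in-edges, so the
stored edge must carry the per-pair minimum. Markers predicted by several
panel models receive the unweighted pixel-wise mean prediction.

A one-panel layout reduces the whole machinery exactly to the single-panel
run (tested trace-for-trace).

# Panel design

Panels should group markers that are predictable from each other. From any
per-marker feature table (`marker, f1..fd`; the synthetic generator emits
ground-truth-correlated features), `reduce_features()` projects to the top
two principal components (deterministic sign: the largest-magnitude score
positive), `cluster_markers()` runs k-means with a fixed seed, and
`build_panels()` rebalances cluster sizes to differ by at most one (moving
highest-index markers from largest to smallest panel — a deterministic
stand-in for manual adjustment), assigns featureless markers uniformly at
random, and chains consecutive panels with `overlap_size` shared markers,
guaranteeing a connected panel graph. The default `overlap_size = 2`
matches a minimal two-marker overlap; parity experiments (below) motivate
larger overlaps.

# Evaluation

Pixel level: per-channel MSE and Pearson correlation (constant channels are
flagged undefined rather than propagating NaN). Single-cell level: a cells
x markers matrix of mean intensities within segmentation labels, and a
cells x marker-pairs matrix of within-cell Pearson correlations (pairs
ordered lexicographically; cells with under two pixels or constant channels
flagged undefined). Profile matrices are compared with the *normalized
Frobenius norm*; its normalization is not pinned down by convention, so
this package defines it as the entrywise root-mean-square difference
(`||A - B||_F / sqrt(#entries)`), with `||A - B||_F / ||B||_F` available
via `method = "relative"`. Undefined entries are excluded pairwise rather
than zero-filled — zero-filling would fabricate agreement in tiny cells.

# The synthetic generator

`generate_dataset()` emulates the statistical structure the method
exploits: `K` latent spatial factors built as sums of truncated-Gaussian
kernels around uniformly placed cell centers (radius jitter 0.8–1.2x of
`0.6 * sqrt(h*w / n_cells)`, giving blobby, tissue-like fields), mixed into
`N` channels by a known mixing matrix with unit-norm rows, plus optional
i.i.d. Gaussian channel noise and an optional softplus nonlinearity. Within
each image the latent fields are centered and whitened to exactly identity
population covariance before mixing. This choice is what makes per-image
z-scored channels an *image-independent* linear map of the latents: the
noiseless channels are exact linear combinations of any `K` markers whose
mixing rows are invertible (the "anchors", checked at generation), so exact
recovery is a provable target rather than an approximation. Masks label
pixels by nearest cell center within its disc radius. Three independent
seed streams (mixing / fields / noise) let experiments vary one factor at a
time; splits use disjoint derived seeds.

What it does **not** emulate: channel spillover, autofluorescence,
acquisition drift, segmentation errors, and the heavy-tailed intensity
distributions of real stains. Tests passing on this generator validate the
selection, completion, and evaluation machinery — not the biological
fidelity of any particular predictor backend.

**Noise floor.** With unit-norm mixing rows, z-scored channels satisfy
`Var(z) = 1`, `Cov(z_i, z_j) = a_i.a_j / (1 + sigma^2)`, so the
population-optimal linear predictor's risk given an observed set is
available in closed form (`synthetic_noise_floor()`). This is the reference
against which fitted models are judged: the naive floor
`sigma^2 / (1 + sigma^2)` ignores that the *observed* channels are noisy
too, and understates the attainable error.

# Study sizes and the parity experiment

The test suite and the acceptance script run the study at desk scale,
chosen so all structural claims are exercised in seconds: 12 markers, 3
latent factors, 64x64 images, 4/2/2 train/validation/test splits, 25 cells
per image, noise SD 0.1 (z-score units). Exact recovery uses budget 3 (=
K); noisy recovery compares budget-3 selection with the analytic floor over
5 seed triplets.

The single- vs multi-panel parity comparison uses 3 chained panels of 8
markers with consecutive overlaps of 6 and budget 9, paired seeds. The
sizing follows from how the two settings differ: with `n` observed channels
spanning `K` latents, input-noise averaging leaves an excess risk that
scales like `sigma^2 * K / n`, so the relative single-vs-multi gap behaves
like `(K/coverage - K/budget) / (1 + K/budget)` where *coverage* is the
observed count within a panel. Parity therefore requires every panel's
observed coverage to exceed `K` comfortably — large overlaps make observed
markers count toward several panels at once. Under-covered layouts (overlap
smaller than `K`, or panels left with a rank-deficient observed set) fail
parity, and correctly so: the graph scores a multiply-predicted marker by
its *best* in-edge while test-time merging *averages* panel predictions, so
one under-trained panel degrades markers that another panel predicts well.
This mirrors why panels are designed around marker similarity in the first
place.

# Numerical conventions and limitations

* Population SD everywhere a z-score or dissimilarity is computed.
* All randomness flows from one run seed via named substreams
  (per round / split / image); reruns are bit-identical, including the
  generator.
* Ridge solve falls back to an SVD pseudo-inverse on singular designs.
* TIFF pixels are stored at float32 precision via bit-packing into 32-bit
  samples, so write/read round trips are bit-exact at that precision;
  channel names travel in a sidecar `index,name` CSV.
* Dijkstra shortest paths replace explicit depth-first path enumeration for
  cross-panel bounds (identical results — loadings are nonnegative — and
  polynomial instead of exponential).
* The linear reference backend cannot capture nonlinear marker
  relationships (softplus-mixed synthetic data, real stains); it bounds
  what selection logic can be verified on CPU, not what the method can
  achieve with a convolutional backend.
* Alternative dissimilarities (correlation distance, SSIM) are a documented
  extension point of the graph module, not implemented.
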