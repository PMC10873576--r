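# panelpick

Multiplexed spatial-proteomics methods (CODEX, imaging mass cytometry)
measure a pre-chosen panel of protein markers, one image channel per marker
— but the number of markers that fit on one tissue sample is hard-limited.
`panelpick` selects a small *predictive* subset of markers such that the
full images of all remaining markers can be synthesized from the imaged
subset, so a panel of a few dozen antibodies can stand in for a much larger
one. It is aimed at groups designing CODEX/IMC panels and at anyone studying
in-silico labeling across image channels.

## The method

Markers `X1..XN` form a complete directed graph. Each ordered edge `(i, j)`
carries a nonnegative **loading** `w[i,j]`, an (approximate upper bound on
the) unpredictability of marker `j` from marker `i`:

* **Initialization:** `w[i,j]` is the pairwise L1 dissimilarity of the two
  channels over the training images, `E_S |Xi - Xj|` — the risk of the
  trivial "copy the input" predictor.
* **Node cost:** an edge is *activated* when its origin marker is observed
  (imaged). A predicted marker's cost `q(v)` is the minimum loading over its
  activated in-edges; observed markers cost 0. The objective is the total
  node cost — the current estimate of overall unpredictability.
* **Greedy step (expected improvement):** for each candidate `k`, `psi(k)`
  is the hypothetical total node cost if `k` were observed; the marker
  minimizing `psi` is added to the observed set.
* **Risk update:** after each selection a predictive model (reference
  backend: per-pixel multi-output ridge regression) is retrained to map
  observed channels to all predicted channels; each predicted marker's
  validation risk `E_P |X̂j - Xj|` overwrites all of its activated in-edge
  loadings, and edges between observed markers drop to 0.
* **Stopping:** a marker budget (default — panel sizes are fixed by imaging
  capacity), a mean node-cost threshold, or a minimum relative improvement.

When the full marker set cannot be imaged on one sample, markers are split
into overlapping **panels**. Intra-panel loadings are measured per panel
(overlap pairs average their two panels' values); loadings between markers
never imaged together are bounded by chained triangle inequalities
`w[i,j] <= min over paths of sum of intra-panel legs`, computed as shortest
paths through overlap markers. Each round retrains only the panel model(s)
containing the last-selected marker, and markers predicted by several panel
models get the pixel-wise average prediction. Panels themselves can be
designed from per-marker feature vectors (PCA to 2-D, k-means, balanced
chained overlaps): similar markers imaged together are the most predictable
from each other.

Evaluation covers pixel-level MSE and Pearson correlation, and single-cell
profiles (cells x markers mean intensities; cells x marker-pairs
within-cell correlations) compared by the entrywise-RMS normalized
Frobenius norm.

## Worked example

Everything is testable without downloads through the built-in synthetic
generator (latent spatial factors mixed into correlated, blobby channels —
see `vignette("panel-selection")`):

```r
library(panelpick)

cfg <- synthetic_config(n_markers = 12, n_latents = 3, noise_sd = 0.1)
gen <- generate_dataset(cfg)

res <- run_selection(gen$dataset, predictor_spec("linear"),
                     stopping_budget(4), seed = 42)
tidy(res)
#> # A tibble: 4 x 6
#>   round marker   psi total_cost mean_cost n_observed
#>   <int> <chr>  <dbl>      <dbl>     <dbl>      <int>
#> 1     1 M11    NA         11.1     0.922           1
#> 2     2 M03     4.49       4.49    0.374           2
#> 3     3 M04     2.16       2.16    0.180           3
#> 4     4 M02     1.01       1.01    0.0839          4

evaluate_selection(res)$overall_mse
#> [1] 0.02001334
```

Reading the trace: the run starts from `M11` (minimal weighted degree), and
each subsequent round adds the marker whose observation most reduces the
total node cost (`psi` of the winner equals the new total). The mean node
cost — the method's estimate of overall unpredictability — falls from 0.92
to 0.08. On this noisy rank-3 dataset the 8 unobserved markers are then
predicted with overall test MSE 0.020, close to the generator's analytic
noise floor (`synthetic_noise_floor()`), and far below the ~1.15 error
scale of random predictions on z-scored data. `autoplot(res)` draws the
node-cost trajectory; `glance(res)` summarizes the run.

Multi-panel runs mirror this via `panel_layout()`, `make_panel_datasets()`
and `run_multipanel_selection()`; `inst/cli/panelpick` exposes the
workflows (`simulate`, `select`, `select-multi`, `design-panels`,
`evaluate`) as a command line over YAML run configurations.

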