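---
title: "Methods: from CT texture series to fuzzy recurrence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from CT texture series to fuzzy recurrence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`georecur` implements a fixed analysis chain: masked per-slice
semi-variograms over a CT stack, a fuzzy recurrence plot (FRP) built from
the resulting series, recurrence quantification, an α-cut recurrence
network, and an eigenvalue summary of the convolution-pooled plot. This
vignette records the model, the parameter conventions, and every place
where the design was genuinely open and a choice had to be made.

## 1. The semi-variogram stage

For a slice with intensities `f` normalized to [0, 1], the lag-`h`
semi-variogram is

    γ(h) = 1 / (2 N(h)) · Σ [ f(i) − f(i+h) ]²

over `N(h)` included pixel pairs. Conventions, all configurable through
`variogram_config()`:

* **Pair geometry.** The flattened index `i + h` is ambiguous in raster
  order. We take pairs strictly along image rows — a horizontal lag of `h`
  true pixels, never wrapping across a row end. This keeps `h` in pixel
  units and makes the statistic a genuine horizontal autocorrelation
  measure.
* **Both-endpoint masking.** A pair contributes only when *both* pixels
  pass the intensity mask (`≥ intensity_min`, default 0.5 — bone on the
  normalized scale) and the row mask (`≥ row_min`). One-sided inclusion
  would mix background into the squared differences.
* **Row origin.** `row_min` is 1-based from the top edge, the common
  radiological display convention. Default 150 for 512-row slices.
* **Lag.** Default `h = 1`, the lag that maximizes the autocorrelation
  signal.
* **Missing slices.** A slice with `N(h) = 0` (mask excludes everything)
  returns `NA` from `slice_semivariogram()`; `semivariogram_series()`
  imputes it from the nearest valid slice (earlier slice on ties) and
  records the indices in `$imputed`, failing only when no slice is valid.
  The downstream embedding needs a complete series, and nearest-slice
  imputation is the least structured completion.
* **Series length.** The first `n_slices` (default 100) slices are used,
  so `T = 100` in the default chain.

Intensity normalization on read (`read_tiff_stack()`) defaults to
`dtype_max` — division by the pixel type's maximum — because a fixed
threshold like 0.5 only means the same thing across volumes if the mapping
is volume-independent. Min–max scaling is available but lets one extreme
background pixel move the bone mask.

## 2. Embedding and the fuzzy recurrence plot

The series is delay-embedded (`embed_series()`): dimension `m = 3`, delay
`τ = 1` by default, giving `L = T − (m−1)τ = 98` phase-space points for
`T = 100`. Fuzzy c-means (`fcm_partition()`, `c = 10` by default) assigns
each point membership grades to the cluster centres, and `frp()` infers
pointwise similarity through the fuzzy similarity relations: reflexivity
(`R(i,i) = 1`), symmetry, and max–min transitive composition

    R(i,j) = max_k min( μ(y_i, v_k), μ(v_k, y_j) ).

FCM hyperparameters are not part of the published analysis convention, so
field-standard values are used and exposed: fuzzifier 2.0, membership
tolerance 1e−5, at most 1000 iterations, random membership initialization
from a caller-supplied seed. Numerical details:

* A point coinciding with a centre (zero distance) gets its membership
  concentrated uniformly on the zero-distance centres — the limit of the
  update rule.
* Non-convergence or a non-finite fit triggers up to 5 fresh seeded
  restarts; the best objective is kept and `converged = FALSE` is flagged
  with a warning if none converged.
* A phase space whose points are all coincident (constant series) has no
  cluster structure; rather than report an arbitrary `1/c` plateau, the
  partition collapses to a single fully-assigned cluster (with a warning),
  which makes the FRP identically 1 — the natural "everything recurs"
  answer for a constant series.

Because initialization is random, FRPs are reproducible only per seed; the
pipeline threads a single seed through the clustering stage.

## 3. Recurrence quantification

`binarize()` turns R into B. The default is Otsu's histogram threshold
(256 bins) on R's values — the standard parameter-free segmentation of a
bimodal grayscale matrix; a fixed threshold is available. A constant R has
no histogram to split and falls back to a fixed 0.5 cut with a warning.

`line_histograms()` counts maximal runs of 1s along every diagonal and
every column. The main diagonal (line of identity) is excluded from the
diagonal statistics by default: the cap "maximum diagonal length = L − 1"
is only coherent with the identity line removed.

The six measures, with `p(·)` the run-length histograms normalized to 1:

* `fRR` — mean of R over all L² cells after zeroing values below `ω`;
  retained cells keep their fuzzy grade. `ω` is not part of the published
  convention; the default is the membership midpoint 0.5, recorded in every
  output. Results at other `ω` are not comparable.
* `fDET` = Σ_{L_D ≥ lmin_d} L_D p(L_D) / Σ_{L_D ≥ 1} L_D p(L_D), the
  denominator literally running over *all* runs; likewise `fLAM` for
  vertical runs.
* `fTT` — mean length of vertical runs ≥ `lmin_v` (units:
  recurrence-plot cells ≙ slices).
* `fDIV` = 1 / L_Dmax over observed diagonal runs; `NA` when B has no
  diagonal run at all.
* `fENT` — Shannon entropy (bits) of the diagonal run-length distribution.
  The defining sum starts at `lmin_d` while the histogram covers all runs;
  we read this as *restricted and renormalized* (a proper distribution over
  the admitted lengths, so a single admitted length gives exactly 0 bits).
  The alternative reading — the truncated sum over unrenormalized all-run
  probabilities — is available via `entropy_all_lengths = TRUE`.
* Empty numerators/denominators return 0 throughout (documented
  degenerate contract); minimum line lengths default to 5.

## 4. The recurrence network

`cluster_similarity()` applies the same max–min composition between cluster
pairs, over points: `S(k,q) = max_i min(μ(v_k,y_i), μ(y_i,v_q))`, `S(k,k) = 1`.
The floor parameter `β` (default 0.08) is defined in the source framework
only by its value; the only role consistent with a second cut parameter is a
pruning threshold, so memberships below `β` are zeroed *before* composition.
This interpretation is a declared assumption and `β` is recorded in the
output. `alpha_cut_adjacency()` then crisps S at level `α` (default 0.4) and
removes self-loops: `A = G_α − I`.

Graph properties follow the Watts–Strogatz conventions: characteristic path
length is the mean shortest-path length over reachable ordered pairs only
(0 for an edgeless graph), and the average clustering coefficient treats
nodes of degree < 2 as contributing 0. Published per-subject path lengths
of order 0.005 for c = 10 nodes are not reachable under any hop-count
definition (the minimum nonzero value is 1), so no external numeric check
exists for this stage; it is validated against an exhaustive BFS oracle
instead.

## 5. The largest recurrence eigenvalue

`reduce_recurrence_matrix()` loops *sharpen → ReLU → max-pool* while the
side exceeds `final_size` (default 70), then `largest_recurrence_eigenvalue()`
reports the largest eigenvalue modulus. Published convention fixes the 3×3
sharpening kernel, pool size 5 and final size 70 but not the stride or
boundary mode. With stride 5 a 98×98 plot would collapse to ~19×19 in one
iteration, far below the stated final size; stride 1 with `valid`
convolution is the smallest schedule consistent with it (each iteration
shrinks the side by 6: 98 → 92 → 86 → 80 → 74 → 68). Both stride and
boundary are configurable; trailing partial pooling windows are included
(max over the truncated window) rather than silently discarding edge rows.
The reduction is fully deterministic and the traversed sizes are recorded.

## 6. What the synthetic generator does and does not emulate

`gen_volume()` builds each slice as a flat background (default 0.1,
necessarily < 0.5 so the bone mask excludes it) plus a foreground "bone"
band from `bone_row_start` down: white noise smoothed by an isotropic
Gaussian kernel of width `corr_range` (σ = range/2), empirically
standardized, mapped to mean 0.75 and variance `sill`, clipped to [0.5, 1].
This gives a directly controllable variogram sill and range with no heavy
dependencies. Defaults state the emulated world: 100 slices of 512×512,
foreground from row 150, `sill = 0.005` (foreground SD ≈ 0.07 on the unit
intensity scale — visible but not saturating texture), `corr_range = 4` px.
`gen_cohort()` raises the `"high"` group's sill by `group_effect`
(default 0.003, a ~60 % elevation producing a clear but overlapping group
separation). An optional per-slice `drift` adds a linear sill trend, giving
the series the slowly-varying structure that makes recurrence plots
non-trivial.

Not emulated: mandible anatomy (no shapes, no teeth, no atrophy),
Hounsfield calibration, DICOM provenance, scanner noise spectra, or
between-slice anatomical continuity. A green synthetic test therefore
establishes that the *statistics are computed correctly* and that designed
group differences propagate through the chain — not that the pipeline
reproduces any particular clinical effect size.

## 7. Known limitations

* Published per-subject feature values depend on at least three unreported
  conventions (`ω`, the meaning of `β`, the pooling stride/boundary) and on
  random clustering initialization; they are not exactly reproducible even
  on the original data, and are used here only through the printed-table
  worked examples (group means ± SD).
* The sample SD (n − 1) is assumed for the published summary rows; one
  printed mean (male diagonal-entropy) appears truncated rather than
  rounded, and one (male determinism) appears misprinted outright.
* TIFF support is deliberately minimal: multi-page, grayscale,
  uncompressed, 8/16-bit. Compressed or multi-sample TIFFs are rejected
  with a clear error; conversion is expected upstream.
* No hypothesis testing or covariate adjustment is provided — the package
  stops at per-subject features and group descriptive statistics.
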