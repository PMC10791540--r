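# georecur

Geostatistical fuzzy recurrence analysis of CT image stacks.

`georecur` turns a stack of CT slices into a handful of interpretable
dynamical and network features. It was built for cohort studies of the
mandible on craniomaxillofacial CT — where per-slice spatial texture differs
systematically between groups (e.g. male vs. female subjects) — but applies
to any stacked grayscale volume whose slice-to-slice texture evolution is of
interest, and to plain numeric series.

## What it computes

1. **Per-slice semi-variogram.** For slice intensities `f` at lag `h`
   (pixels, along rows),

   `γ(h) = 1/(2 N(h)) Σ [f(i) − f(i+h)]²`

   over the `N(h)` pixel pairs where both pixels pass an intensity mask
   (bone: `f ≥ 0.5` on a [0, 1] scale) and a row mask (skipping background
   rows at the top of the frame). Small `γ` = high spatial autocorrelation.
   Applied slice by slice this yields a series `x = (x₁, …, x_T)` — the
   volume's spatial-variance profile.

2. **Fuzzy recurrence plot (FRP).** The series is embedded in phase space
   (dimension `m`, delay `τ`, giving `L = T − (m−1)τ` points), partitioned
   by fuzzy c-means into `c` clusters with membership grades
   `μ(y_i, v_k) ∈ [0, 1]`, and the L×L recurrence matrix is inferred by
   max–min fuzzy-relation composition:
   `R(i,j) = max_k min(μ(y_i, v_k), μ(v_k, y_j))`, with `R(i,i) = 1`.

3. **Fuzzy recurrence quantification (FRQA).** After binarizing R (Otsu
   threshold by default): recurrence rate `fRR`, determinism `fDET`,
   laminarity `fLAM`, trapping time `fTT`, divergence `fDIV = 1/L_Dmax`,
   and diagonal-line entropy `fENT` (bits).

4. **Fuzzy recurrence network.** Cluster-to-cluster similarities by the
   same max–min composition (after flooring memberships below `β`),
   crisped by an α-cut into an unweighted graph on the `c` clusters;
   characteristic path length and average clustering coefficient follow.

5. **Largest recurrence eigenvalue `λmax`.** R is repeatedly sharpened
   (3×3 kernel `[0 −1 0; −1 5 −1; 0 −1 0]`), rectified (ReLU) and
   max-pooled until its side is ≤ 70; `λmax` is the largest eigenvalue
   modulus of the reduced matrix.

A synthetic-data module generates CT-like volumes (Gaussian random field
"bone" with tunable variogram sill/range over a sub-0.5 background), labelled
two-group cohorts with an additive sill offset, and toy series, so the whole
pipeline is testable with no external data.

## Worked example

```r
library(georecur)

base <- volume_spec(n_slices = 100, height = 64, width = 64, bone_row_start = 20,
                    sill = 0.004, corr_range = 4, drift = 5e-5, seed = 1)
coh  <- gen_cohort(cohort_spec(n_per_group = 2, base = base,
                               group_effect = 0.003, seed = 42))
cfg  <- pipeline_config(variogram = variogram_config(row_min = 20, n_slices = 100))
feats <- do.call(rbind, lapply(coh, function(el)
  run_subject(el$volume, group = el$group, config = cfg, subject = el$subject)))
summarize_cohort(feats)
```

Output (printed by the code above):

```
<cohort_report>
group low (n = 2):
  fRR                              0.025 ± 0.000
  fDET                             0.181 ± 0.030
  fLAM                             0.252 ± 0.019
  fTT                              9.762 ± 0.455
  fDIV                             0.058 ± 0.007
  fENT                             1.941 ± 0.255
  characteristic_path_length       0.500 ± 0.707
  average_clustering_coefficient   0.000 ± 0.000
  lambda_max                       4420.685 ± 743.192
group high (n = 2):
  fRR                              0.024 ± 0.003
  fDET                             0.140 ± 0.198
  fLAM                             0.198 ± 0.018
  fTT                              6.767 ± 2.498
  fDIV                             0.175 ± 0.106
  fENT                             0.994 ± 1.406
  characteristic_path_length       0.500 ± 0.707
  average_clustering_coefficient   0.000 ± 0.000
  lambda_max                       4584.631 ± 116.994
```

Reading it: each row is a group mean ± sample SD over subjects. The designed
group signal sits in the semi-variogram scale itself — the `"high"` group was
generated with an elevated sill, and its mean series value recovers that
(0.00058 vs 0.00041 here, via `semivariogram_series`). The recurrence
measures describe the *shape* of each series: `fTT ≈ 9.8` says recurrent
states persist ~10 slices; near-zero `fDET` marks the series as mostly
non-deterministic at desk scale. `λmax` is much larger than on smooth
real-CT plots because sharpening amplifies the speckled recurrence structure
of short noisy series; it is comparable within, not across, designs.

Direct series analysis works the same way without any volume:

```r
x <- gen_toy_series("sine", length = 100, period = 10, noise_sd = 0.05, seed = 3)
R <- frp(fcm_partition(embed_series(x, m = 3, tau = 1), c = 10, seed = 1))
frqa(R)                  # the six measures, one data.frame row
largest_recurrence_eigenvalue(R)
```

## Command line

```sh
Rscript inst/cli/georecur.R simulate  --config cfg.txt --seed 4 --out cohort/
Rscript inst/cli/georecur.R variogram --in cohort/S1.tif --out S1_series.csv
Rscript inst/cli/georecur.R run       --in cohort/S1.tif --group low --out S1.csv
Rscript inst/cli/georecur.R report    --in features.csv --out summary.csv
```

`cfg.txt` is plain `key = value` lines; see the script header for keys.

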