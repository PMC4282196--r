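# dkimaps

Diffusional kurtosis imaging (DKI) of gray matter, end to end and fully
synthetic: multi-shell phantom simulation with Rician noise, per-voxel
fitting of the 22-parameter kurtosis signal model, mean/axial/radial
kurtosis maps, voxelwise two-group comparison with Monte-Carlo
cluster-extent correction, ROI–score correlation, and demographic/clinical
group tables.

The package emulates a typical case-control DKI study (patients with
internet gaming addiction vs healthy controls). Since raw scanner data
from such studies is not publicly deposited, every pipeline stage is
validated against phantoms with known ground truth instead: the claims
the package makes are about *recovery* — that the estimator, the maps,
the cluster correction and the correlation analysis each return what was
put in.

## The model

For gradient direction `n` and b-value `b`:

```
ln S(b, n) = ln S0 − b · nᵀ D n + (b²/6) · Σ_ijkl n_i n_j n_k n_l V_ijkl
```

with `D` the diffusion tensor and `V = MD² · W` the (rescaled) kurtosis
tensor, `MD = tr(D)/3`. The model is linear in its 22 parameters and is
fitted by weighted linear least squares on log-signals (one reweighting
pass with squared predicted signals as weights). Scalar maps:

* **MK** — apparent kurtosis averaged over a direction set (the acquired
  directions by default, or a 321-point sphere);
* **K∥**, **K⊥** — kurtosis along the principal diffusion eigenvector,
  and averaged over the two perpendicular ones, via the eigenframe
  transform of `W`.

## Worked example

```r
library(dkimaps)

scheme <- gradient_scheme()     # 1 b=0 + 25 directions at b = 1000 and 2000
scheme
#> Gradient scheme: 51 volumes; 1 b=0; 25 directions on shells b = 1000, 2000 s/mm^2

spec <- default_phantom()       # spherical "brain" + cubic lesion, SNR 46 at b=0
sim <- simulate_signals(spec, scheme, seed = 7)
fit <- dki_fit(sim$signals, scheme, mask = sim$mask)
fit
#> Diffusional kurtosis model fit
#>   grid: 24 x 24 x 24
#>   voxels fitted: 4224 of 13824
#>   volumes: 51 (b = 0, 1000, 2000 s/mm^2)

maps <- kurtosis_maps(fit)
maps
#> Kurtosis maps (MK averaged over acquired directions)
#>   valid voxels: 4224 of 13824
#>   mk        median 0.908  IQR [0.877, 0.935]
#>   k_axial   median 0.745  IQR [0.670, 0.813]
#>   k_radial  median 1.008  IQR [0.939, 1.071]
```

(The phantom's true isotropic kurtosis is 0.9; the axial/radial split at
median 0.75/1.01 reflects the mild anisotropy of the default diffusion
tensor.)

Group analysis on simulated cohorts (18 patients with lesion kurtosis
scaled to 0.5, 21 controls):

```r
cohort <- cohort_metric_maps(spec, effect_spec("lesion", 0.5),
                             scheme = scheme, seed = 1, metrics = "mk")
tmap <- two_sample_t_map(cohort$maps$mk[cohort$group == "patient"],
                         cohort$maps$mk[cohort$group == "control"],
                         cohort$mask)
k_min <- mc_cluster_threshold(cohort$mask, mc_null_spec(seed = 1), spec$voxdim)
clusters <- extract_clusters(tmap, k_min = as.integer(k_min),
                             voxdim = spec$voxdim)
effect_recovery_report(clusters, cohort$effect_voxels)
```

Clinical tables from the packaged 39-subject reference cohort:

```r
clinical_table(iga_cohort())
#>                      IGA              Control          p-value
#> Age (years)          20.50 ± 3.55    21.95 ± 2.40    0.138
#> Gender (M count)     15               18               0.837
#> Education (years)    11.39 ± 1.85    12.38 ± 2.13    0.133
#> CIAS                 74.44 ± 8.33    38.43 ± 9.10    3.65e-15
#> SAS                  53.67 ± 9.71    40.95 ± 8.45    9.54e-05
#> SDS                  54.33 ± 10.04   38.57 ± 6.67    9.95e-07
#> BIS-11 total         63.94 ± 8.26    50.81 ± 6.95    4.15e-06
```

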