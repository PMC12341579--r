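# woundring

Quantification of epithelial wound closure driven by a supracellular
actomyosin "purse string". When a circular wound opens in an epithelial
monolayer, the bordering cells assemble a contractile actomyosin cable
that constricts the wound over hours. Myosin II organizes into
micrometre-scale clusters on this cable, and their dynamics matter:
**radial** clusters hold a fixed angular position while the ring shrinks
(residual motion ~0.05 µm/min) and generate tension; **tangential**
clusters travel along the perimeter (~0.2 µm/min). The radial fraction of
a ring predicts how fast the wound closes, and laser ablation near radial
clusters recoils faster than near tangential ones.

`woundring` is for cell biologists and image analysts who need these
measurements as reproducible code rather than manual ImageJ sessions. It
provides:

* **ring tracking** — sub-pixel circle detection per frame, diameter and
  closure-velocity series (30-min steps), closure-time estimation, onset
  convention at 50 ± 2 µm;
* **kymographs** — fixed-angular-bin circumferential unwrapping so radial
  clusters appear as vertical ridges; cable concentration, total
  intensity and contrast statistics;
* **cluster analysis** — detection (contrast gate over the ring-perimeter
  mean), nearest-neighbour tracking with fusion events, the 6-min
  lifetime filter, and radial/tangential classification by mean arc speed
  `|R·dθ/dt|` against a 0.1 µm/min threshold;
* **ablation recoil** — least-squares fits of the viscoelastic model
  `L(t) = (T0/ζ)·τ·(1 − e^(−t/τ))`, where `T0/ζ` (tension over damping)
  is the initial recoil velocity, plus two-point initial velocities and
  group tension ratios with bootstrap CIs;
* **FRET analysis** — masked donor/acceptor ratio maps, 0.5 × 1 µm
  ring-perimeter sections normalized to the ring average, RhoA-activity
  vs myosin-density curves, and RhoA→myosin peak-lag estimation;
* **cohort statistics** — Pearson correlation of radial fraction vs
  closure velocity and an exact-enumeration Mann–Whitney rank-sum test;
* **a ground-truthed synthetic generator** — movies, recoil traces, FRET
  bursts and cohorts with the statistical structure the analysis assumes,
  so every stage is testable end-to-end without any raw data.

Everything is tidyverse-shaped: tabular inputs and outputs are tibbles,
fitted objects support `tidy()`/`glance()`, and result types have
`autoplot()` methods.

## Worked example

Simulate a closing 50 µm wound (0.2 µm/px, 1 min/frame, two radial and
two tangential clusters), then run the full measurement pipeline:

```r
library(woundring)

cfg <- sim_config(cluster_specs = cluster_layout(n_radial = 2L,
                                                 n_tangential = 2L),
                  seed = 3)
mov <- simulate_ring_movie(cfg)
ds  <- diameter_series(mov)             # per-frame circle fits
ky  <- build_kymograph(mov, ds)         # angle x time intensity table
cl  <- filter_and_classify(link_tracks(detect_clusters(ky), ds), ds)
attr(cl, "track_summary")
#> # A tibble: 4 × 6
#>   track_id n_det lifetime_min mean_intensity speed_um_min class
#>      <int> <int>        <dbl>          <dbl>        <dbl> <chr>
#> 1        1    61           60           205.       0.0474 radial
#> 2        2    61           60           205.       0.0389 radial
#> 3        3    61           60           205.       0.201  tangential
#> 4        4    61           60           205.       0.200  tangential
```

All four tracks survive the 6-min lifetime filter; the two clusters
generated as radial measure ~0.04–0.05 µm/min of arc speed and the two
tangential ones ~0.2 µm/min, so classification against the 0.1 µm/min
threshold is unambiguous.

```r
summarize_ring(cl, ds)
#> # A tibble: 1 × 7
#>   n_tracks n_radial n_tangential radial_fraction cluster_density_per_um …
#> 1        4        2            2             0.5                 0.0276 …

attr(closure_velocity(ds), "mean_velocity_um_per_min")
#> [1] 0.125
```

The measured constriction velocity (0.125 µm/min of diameter) matches the
generated closure of 50 µm over 400 min. Recoil fitting and the tension
ratio between cluster classes:

```r
fit_retraction(simulate_retraction_trace(6.2, tau_s = 5,
                                         noise_sd_um = 0.2, seed = 1))
#> Viscoelastic recoil fit  L(t) = (T0/zeta) tau (1 - exp(-t/tau))
#>   T0/zeta (initial velocity): 6.227 um/s
#>   tau:                        4.983 s
#>   residual RMS: 0.181 um over 26 samples

tension_ratio(c(6.6, 5.9, 6.1), c(3.6, 4.1, 3.9), seed = 1)
#> # A tibble: 1 × 5
#>   ratio ci_lower ci_upper   n_a   n_b
#> 1  1.60     1.49     1.74     3     3
```

A ratio of group-mean initial velocities of ~1.6 reads out a ~1.6-fold
tension difference between radial- and tangential-cluster cable portions
(assuming uniform damping).

## Vignette

See `vignettes/wound-ring-quantification.Rmd` for the model and
measurement conventions in detail: generator calibration, tracking and
classification choices, the recoil model, FRET sectioning, and known
limitations.
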