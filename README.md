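# shoalkit

Collective-motion analysis for small groups of individually tracked fish.

Shoaling fish coordinate their movement through local interactions, and the
degree of coordination is summarized by a handful of standard statistics.
shoalkit computes them from per-frame (x, y) trajectories — idTracker-style
exports or plain `frame,id,x,y` CSV — and runs the treatment comparison
around them. It was built for annular-arena experiments on groups of four
guppies observed in two 5-minute windows (just after release, and after
30 minutes of habituation), comparing shoals of familiar versus unfamiliar
fish, but every geometry, window and binning choice is configuration.

The quantities at its core:

- **Polarization** — the order parameter
  *P = ‖Σᵢ ĥᵢ‖ / m* over the *m* fish with valid unit headings ĥᵢ in a
  frame; 1 = perfectly aligned group, ≈0.45 for four independent random
  headings.
- **Nearest-neighbour distance (NND)** — per fish per frame, the distance
  (mm) to the closest group-mate; its time average measures cohesion.
- **Median speed** — per fish, in mm/s (median, because speed
  distributions are right-skewed).
- **Pairwise directional correlation** — *r = ĥₐ · ĥᵦ = cos Δθ* per pair
  and frame, averaged on a mutual-speed × distance grid (heat-map
  surfaces).
- **Focal alignment maps** — partner positions and heading differences in
  the frame of a focal fish at the origin heading +x; per spatial cell the
  circular mean direction (arrow field) and the mean resultant length *R*
  of the heading differences (alignment surface).
- **Repeated-measures mixed models** (nlme, REML, containment df) —
  response ~ familiarity × period with a random intercept per group, plus
  fish-within-group for the individual-level responses (log scale), and
  Benjamini–Hochberg FDR control across the model family.

An agent-based simulator of shoals in the annular arena (Rcpp core,
lognormal speeds, local alignment/attraction, tangent-following wall
avoidance, occlusion gaps, fully seed-reproducible) generates synthetic
studies so the whole pipeline can be exercised, power-checked and
calibrated without raw video.

## Worked example

Simulate one familiar-group trial, compute the three response variables,
then run a full 12-group study through the repeated-measures comparison:

```r
library(shoalkit)

ts <- simulate_trial(sim_config(duration = 60, seed = 42),
                     trial_id = "demo", treatment = "familiar")
ts
#> <trajectory_set> trial demo (familiar): 4 fish x 1500 frames @ 25 fps, 42 missing fixes

k <- compute_kinematics(ts)
mean_polarization(polarization_timeseries(k))
#> mean polarization: 0.693
sapply(1:4, function(i) median_speed(k, i))
#> median speeds (mm/s): 62.7 62.7 61.3 62.0
colMeans(nearest_neighbour_distances(ts), na.rm = TRUE)
#> mean NND (mm): 39.4 41.2 28.9 32.0
```

The polarization of 0.69 sits well above the random-heading baseline of
0.45: this simulated group is moderately aligned. Median speeds of ~62 mm/s
are about two body lengths per second, and NNDs of 30–40 mm mean the fish
swim within roughly a body length of each other.

```r
study <- simulate_study(study_design_config(seed = 1),
                        sim_config(duration = 60))
rec <- do.call(rbind, lapply(study$trials, function(tr)
  rbind(metric_records(tr$period1, "period1")$group,
        metric_records(tr$period2, "period2")$group)))
fit <- fit_group_model(rec)
fit[fit$term != "(Intercept)", c("term", "estimate", "std_error", "t_value", "df", "p_value")]
#>               term estimate std_error t_value df  p_value
#> 2      familiarity   0.1509    0.0198    7.64 10 1.76e-05
#> 3             time   0.0440    0.0198    2.23 10 5.02e-02
#> 4 familiarity:time  -0.0394    0.0279   -1.41 10 1.88e-01
```

The familiarity term is the familiar-minus-unfamiliar polarization
difference in period 1 (the generator injected a positive alignment
increment for familiar groups, and the model recovers it at df = 10, the
containment df for 12 groups); after Benjamini–Hochberg at q = 0.05 only
the familiarity term stays significant here.

For file-based runs, `run_simulation()` writes canonical trajectory CSVs
plus a `metadata.csv`, and `run_analysis()` turns an input directory (or a
simulation config) into metric tables, correlation grids, alignment maps,
a Table-style model CSV and a manifest — deterministically for a given
seed. A thin command-line wrapper over the same functions is in
`inst/scripts/shoalkit.R`.

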