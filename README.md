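# pairforage

Quantify **spatio-temporal coordination of provisioning parents** from
automated radio-tracking arrays.

When two songbird parents rear a brood together, each would do best if the
other worked harder — the classic sexual conflict over care. Theoretical
resolutions of that conflict require parents to *negotiate*: to monitor and
respond to each other's effort. Foraging together is a candidate mechanism,
and it leaves a measurable signature: the two parents' space use is most
similar when compared **at the same time**, and less similar when one
parent's movements are artificially shifted (lagged) in time.

`pairforage` implements the full measurement chain for that test, for
ecologists working with Encounternet-style receiver arrays (or wanting to
evaluate the design before fieldwork):

* **Synthetic field campaigns** — a central-place-foraging simulator with a
  37 + 1 receiver array (rings at 25/50/75 m), 5-s tag pulses, nest visits
  every ~2 min, ~73% of time inside the array, and four coordination
  scenarios (coordinated, leader–follower, cyclic, independent).
* **RSSI multilateration** — log-distance path-loss inversion
  `d̂ⱼ = d0·10^((P0−RSSIⱼ)/(10γ))` followed by weighted nonlinear
  least-squares over receiver positions; per-fix error estimates and
  per-window location availability.
* **Dynamic Brownian bridge UDs** — sliding-window maximum-likelihood
  motion variance σ²ₘ with BIC change points; bridge density
  `N(zᵢ + α(zᵢ₊₁−zᵢ), Tα(1−α)σ²ₘ + (1−α)²δᵢ² + α²δᵢ₊₁²)` integrated per
  segment and discretized on a 2-m grid, per hour and per 10-min window.
* **Earth mover's distance lag correlograms** — exact Wasserstein-1
  distance (transportation simplex, in metres) between every male × female
  UD pair with signed lag = female window − male window; EMD = 0 for
  identical UDs.
* **Weighted mixed-model inference** — `EMD ~ lag` with male-UD, female-UD
  (nested in nest) and nest random intercepts, availability-product case
  weights, Kenward–Roger F-tests, and Tukey-style post-hoc letter groups;
  covariate models with backward selection.
* **Secondary behaviour statistics** — circular correlation of foraging
  angles (Jammalamadaka–SenGupta, with one-per-minute thinning), pair
  distances, within-10-m proximity time binned by distance from the nest,
  and EMD versus hourly provisioning rate.

Everything is tibble-in / tibble-out with `tidy()`, `glance()` and
`autoplot()` methods, so results drop straight into dplyr/ggplot2
workflows.

## A worked example

Two simulated nests, fully coordinated parents, 4-hour sessions, the full
observation chain (RSSI → triangulation → UDs → EMD → mixed models):

```r
library(pairforage)

cfg <- run_config(scenario = "coordinated", n_nests = 2, seed = 1,
                  sim = list(session_hours = 4), grid = grid_spec(cell = 4),
                  motion_model = "global", write_figures = FALSE)
run <- run_pipeline(cfg)
run
#> <pf_run> coordinated scenario, 2 nest(s)
#>   broad scale: <pf_lag_fit> lag F(6, 4.5) = 6.839, p = 0.03284 [boundary random-effect variance]
#>   fine scale:  <pf_lag_fit> lag F(10, 107.4) = 13.009, p = 1.239e-14
```

The lag effect is significant at both time scales: shifting one parent's
windows away from real time makes the pair's space use measurably less
similar. The post-hoc letter display localizes the effect at lag 0 — the
hallmark of spatio-temporal coordination:

```r
run$hourly$posthoc
#> # A tibble: 7 × 4
#>     lag emmean    se group
#>   <int>  <dbl> <dbl> <chr>
#> 1    -3  18.5   8.26 ab
#> 2    -2  16.4   6.81 ab
#> 3    -1  22.9   6.37 ab
#> 4     0   8.41  6.02 a
#> 5     1  27.2   6.24 b
#> 6     2  20.9   6.75 ab
#> 7     3  29.5   7.63 b
```

Lag 0 (the two parents compared over the same hour) sits at 8.4 m of
transport distance, roughly a third of the lagged comparisons (16–30 m),
and shares no letter with the +1/+3 classes. `tidy(run$hourly$table)` gives
the correlogram table and `autoplot(run$hourly$table)` the correlogram
figure (mean ± SE EMD against signed lag, the dip at 0 marking
coordination).

`simulate_pair_tracks()`, `simulate_detections()`, `build_track()`,
`estimate_motion_variance()`, `compute_ud()`, `emd()`, `build_lag_table()`,
`fit_lag_model()` and friends expose every stage individually;
`ingest_real()` reads field CSV logs (detections, receivers, visits) in the
documented schemas, and `inst/scripts/pairforage-cli.R` wraps simulate /
analyze / run for shell use.

## Vignette

`vignettes/pairforage-methods.Rmd` documents the models, every tunable
parameter with its default and rationale, the numerical choices, what the
simulator does and does not emulate, and known limitations.
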