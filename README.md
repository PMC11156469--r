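# wingscaling

Growth of the *Drosophila* wing imaginal disc slows as the disc gets
bigger, and a central quantitative question is *how*: the average cell-cycle
time T<sub>CC</sub> of wing-pouch cells lengthens in proportion to pouch
volume, and the slope of that relationship — the **scaling coefficient**,
in hours per nanolitre — differs between genotypes (it collapses when the
atypical cadherins Fat or Dachsous are knocked down). `wingscaling`
implements the full quantitative pipeline behind this kind of analysis for
R users: morphometric volume measurement, mitotic-index-based cell-cycle
inference, scaling and allometry regressions with genotype comparisons, a
discrete-time growth simulator with uncertainty propagation, and
midline intensity-profile analysis for morphogen gradient scaling. A
synthetic-data module generates every input with known ground truth, so the
entire pipeline is testable without microscopy data.

## The model

* **Cell-cycle inference.** Under uniform asynchronous proliferation the
  fraction of cells in M phase (the mitotic index, *MI*, measured as
  PHH3-positive cells over total cells) equals the ratio of M-phase
  duration to cycle duration, so

  T<sub>CC</sub> = t<sub>M</sub> / MI,  with t<sub>M</sub> = 0.34 hr (20.5 min).

  Total cell number per pouch comes from a genotype-specific linear
  conversion, `cells = β₀ + β₁·V`, fitted from segmented subdomain
  densities.

* **Scaling regressions.** OLS of T<sub>CC</sub> on pouch volume gives the
  scaling coefficient; OLS on larval age gives `T_CC = T₀ + β₁·t`. Genotype
  differences in slope are tested with the interaction model
  `T_CC = β₀ + β₁·V + β₂·G + β₃·V·G` (G = 0/1 dummy; β₃ is the slope
  difference).

* **Growth simulation.** The cell-cycle time converts to an instantaneous
  exponential growth rate r = ln(2)/T<sub>CC</sub>, and pouch volume
  follows the discrete recursion V<sub>t</sub> = (1 + r<sub>t</sub>·Δt) ·
  V<sub>t−Δt</sub> (Δt = 1 hr by default), with slope uncertainty
  propagated onto the trajectory by Monte Carlo.

* **Allometry.** Organ-vs-body growth is fitted in log-log space as a
  continuous two-phase (hinge) regression; each phase's slope is classified
  against 1 (isometry) by t-test.

* **Gradient profiles.** Intensity profiles along the AP/DV midlines are
  extracted with orthogonal-transect averaging (50 px) and a sliding
  window (100 px), aligned at the pouch centre, axis-normalized, and
  scored for "collapse" — whether profiles from pouches of different sizes
  superimpose once positions are rescaled by axis length.

## Worked example

Generate a wildtype-like cohort (50 pouches over 36 hr of third-instar
growth), sample PHH3 counts, infer cell-cycle times, and fit the scaling
relationship:

```r
library(wingscaling)

gp       <- genotype_presets()$wildtype
pouches  <- gen_pouch_growth(gp, ages = seq(0, 36, by = 4), n_per_age = 5, seed = 42)
mitotic  <- gen_mitotic_counts(pouches, params = gp, seed = 43)
estimates <- estimate_cell_cycle(pouches, mitotic)

fit <- fit_tcc_vs_volume(estimates)
fit
#> Cell-cycle scaling fit (wildtype)
#>   scaling coefficient: 15.989 hr/nL (SE 1.904, 95% CI 12.161-19.816)
#>   intercept: 8.433 hr; R^2 = 0.595; n = 50
```

The recovered scaling coefficient (15.99 hr/nL) matches the generating
value of 16 hr/nL: the cell cycle lengthens about 16 hours for every
nanolitre of pouch growth. Comparing against a Dachsous-knockdown-like
genotype whose generating slope is halved:

```r
ds  <- gen_scaling_dataset(genotype_presets()$ds_rnai, n = 30, seed = 44)
wt  <- gen_scaling_dataset(gp, n = 30, seed = 45)
compare_scaling(wt, ds, labels = c("wildtype", "ds_rnai"))
#> Scaling-coefficient comparison: wildtype vs ds_rnai
#>   slope difference (beta3): -6.087 hr/nL (SE 1.198), p = 4.5e-06
```

The interaction term detects the flattened scaling. Finally, feed the
time fit into the growth simulator:

```r
tf   <- fit_tcc_vs_time(estimates)
tf
#> Cell-cycle vs age fit (wildtype)
#>   Tcc = 9.379 + 0.2463 x age (hr); slope SE 0.0332; n = 50
traj <- propagate_uncertainty(tf, growth_config(v0 = 0.1, t_start = 0,
                                                t_end = 36, seed = 46))
compare_to_observed(traj, pouches)
#> Growth-model goodness of fit
#>   timepoints compared: 10
#>   RMSE of timepoint means: 0.0363 nL
#>   fraction of means inside 95% band: 0.5
```

The simulated trajectory tracks the generated growth curve (RMSE
0.036 nL against timepoint means that span 0.1–0.7 nL). The 95% band
reflects only the fitted slope's uncertainty, so early timepoints — where
that uncertainty has not yet accumulated — can fall outside it while still
matching closely in absolute terms.

All fitted objects have `tidy()`/`glance()` methods, and
`autoplot()` works on fits, trajectories and profiles.

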