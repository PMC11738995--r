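# vasckinetics

Quantitative analysis of three image-derived readouts used to study how
endothelial cell populations expand and migrate around embryonic veins:

1. **Cell-cycle kinetics from dual-pulse EdU/BrdU labeling.** Two thymidine
   analogues given in sequence label cells that pass through S-phase at
   different times. From the scored tallies — `P` cells in the population of
   interest (e.g. PROX1⁺ nuclei), `S` EdU⁺BrdU⁺ double-positive cells (in
   S-phase at harvest), `L` EdU⁺BrdU⁻ cells (left S-phase during the
   injection interval `T_i`), and the KI67⁺ count — the package estimates

   ```
   T_S = T_i / (L / S)            S-phase duration
   GF  = KI67⁺ / P                growth fraction
   T_C = T_S / (S / (P × GF))     total cell-cycle duration
   ```

   with percentile bootstrap confidence intervals.

2. **Nucleus–Golgi polarity.** In migrating cells the Golgi sits ahead of
   the nucleus. Given 3D label masks of segmented nuclei and Golgi, the
   package pairs each nucleus with its Golgi by closest border-to-border
   distance (pairs farther than 5 µm excluded), computes the angle of the
   x–y nucleus→Golgi centroid vector against the dorsal body axis
   (θ = arccos(A·B), signed onto the compass 0° dorsal / 90° lateral /
   180° ventral / 270° medial), and summarizes the angular distribution
   with a rose histogram, the circular mean, the resultant length R, and a
   Rayleigh uniformity test.

3. **Inside/outside-vessel morphometry.** Cells (nucleus centroids) are
   classified against a segmented vessel mask by shortest anisotropic
   distance to the vessel surface, marker-defined populations are counted
   per compartment, and stage-to-stage expansion is reported as fold
   changes of per-embryo means.

A synthetic-data module generates both experiment types with known ground
truth — an asynchronous cycling population under a configurable analogue
schedule, and voxelized 3D vessel scenes with von Mises-distributed
polarity directions — so every stage is validated by parameter recovery.

## Worked example

Simulate 50,000 cells cycling with ground truth `T_C = 26.6 h`,
`T_S = 10 h`, `GF = 0.8` under the standard schedule (EdU available 0–6 h,
BrdU 6–8 h, harvest at 8 h, `T_i = 6 h`), then recover the parameters:

```r
library(vasckinetics)

sim <- simulate_pulse_labeling(
  cycle_sim_params(t_cycle = 26.6, t_s = 10, growth_fraction = 0.8,
                   n_cells = 50000, seed = 1),
  pulse_schedule())
sim$counts
#> Dual-pulse counts: P = 50000, S (EdU+BrdU+) = 15038, L (EdU+BrdU-) = 8865,
#>   KI67+ = 40013, T_i = 6 h

bootstrap_estimates(sim$cells, t_i = 6, n_boot = 1000, seed = 2)
#> Cell-cycle estimate:
#>   TS   =  10.18 h  (95% CI 9.90-10.45, 1000 bootstrap replicates)
#>   TC   =  27.08 h  (95% CI 26.59-27.60, 1000 bootstrap replicates)
#>   GF   =   0.80    (95% CI 0.80-0.80, 1000 bootstrap replicates)
```

The estimate recovers the generating `T_C` within 2% and its 95% interval
covers the truth. The polarity pipeline round-trips a synthetic scene the
same way:

```r
sc <- generate_vessel_scene(scene_params(mu_deg = 90, kappa = 4, seed = 3))
pairs <- compute_polarity_angles(
  pair_nuclei_golgi(extract_geometry(sc$nuclei),
                    extract_geometry(sc$golgi)))
summarize_angles(pairs$angle_deg[pairs$included])
#> Angular distribution: n = 14 (excluded 0, unmatched 0)
#>   circular mean = 77.3 deg, R = 0.899, Rayleigh p = 0 (approx)
```

All 14 generated cells are paired and included, and the concentrated
distribution around the generating 90° direction is detected as strongly
non-uniform. Expansion statistics work directly on per-embryo counts:

```r
reps <- data.frame(stage_label = c("E9.5", "E11"), value = c(351, 11510))
fold_change(reps, "E9.5", "E11")
#> Fold change E9.5 -> E11: 32.79
```

A thin command-line interface over these functions ships in
`inst/scripts/vasckinetics.R` (subcommands `simulate`, `cellcycle`,
`polarity`, `count`, `report`); `run_pipeline()` executes the whole
simulate → estimate → classify → summarize chain from one seeded JSON
configuration and emits a deterministic JSON report.

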