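# stereonav

Geometry, registration and targeting-accuracy analysis for **frameless,
camera-guided stereotactic electrode navigation** with a multi-guide-tube
microdrive.

In camera-guided neuronavigation for awake-primate electrophysiology, the
electrode microdrive hangs from an arch above the animal instead of being
bolted to a recording chamber. Infrared cameras track the microdrive and the
head; after co-registering the head to its MRI/CT-derived digital model, the
operator steers the tracked tool axis onto a pre-planned trajectory and
advances the electrode to depth. Accuracy is verified by electrolytically
depositing nanograms of iron from the electrode tip — an MRI-visible marker
of where the tip physically was — and comparing deposit and plan.

`stereonav` implements the computational core of that workflow for
methods-development and validation work:

* **Registration** — closed-form paired-point rigid registration
  (orthogonal Procrustes with a reflection guard,
  `R = V diag(1, 1, det(VUᵀ)) Uᵀ`) plus iterative-closest-point surface
  refinement, reporting RMS error (`paired_point_register()`,
  `surface_refine()`).
* **Geometry** — rigid transforms, point-to-line ("tool axis to target")
  distance, undirected axis angles in `[0°, 90°]`, and per-anatomical-plane
  rotational offsets with degenerate-projection flagging.
* **Device model** — the 5-guide-tube cross layout, the matrix-centred
  device frame (origin at the central guide-tube tip, penetration along
  −z), per-guide planned-target corrections, and deposit mass by Faraday
  coulometry, `m = (I·t / zF)·M`.
* **Alignment** — trajectory planning from entry/target pairs and a
  simulated rotate-then-translate-then-advance positioning workflow with
  quantised micromanipulator moves and an auditable move log (`align()`).
* **Synthetic experiments** — a seeded generator emulating the egg-white
  phantom protocol (5 electrodes × 2 deposits, with a mid-experiment
  re-registration) and the in-vivo protocol (3 deposits), composing
  registration, tracking, calibrated observation noise, outer-guide length
  bias, axial drift and MRI voxel quantization (`generate_experiment()`).
* **Evaluation** — per-axis offsets, 2D distance to the planned electrode
  axis, 3D deviation, angular error, per-guide grouping and depth–offset
  correlation, with broom-style `tidy()`/`glance()` and a ggplot2
  `autoplot()` (`evaluate_accuracy()`).

Everything takes and returns tibbles where data are tabular, so the pieces
chain with the pipe.

## Worked example

```r
library(stereonav)

ds <- generate_experiment(protocol_config("eggwhite"), seed = 42)
ev <- evaluate_accuracy(ds)
ev
#> <nav_evaluation> 10 deposit records
#> # A tibble: 9 × 6
#>   metric            unit     mean    sd     n insufficient_n
#>   <chr>             <chr>   <dbl> <dbl> <int> <lgl>
#> 1 deposit_offset_rl mm    -0.157  0.571    10 FALSE
#> 2 deposit_offset_ap mm    -0.0223 0.405    10 FALSE
#> 3 deposit_offset_si mm     0.272  1.09     10 FALSE
#> 4 deposit_dist_2d   mm     0.602  0.339    10 FALSE
#> 5 deposit_dist_3d   mm     1.16   0.534    10 FALSE
#> 6 mark_offset_rl    mm     0.0245 0.233    10 FALSE
#> 7 mark_offset_ap    mm     0.148  0.497    10 FALSE
#> 8 mark_dist_2d      mm     0.475  0.275    10 FALSE
#> 9 angular_error     deg    5.49   4.36     10 FALSE
#> depth-offset correlation (dist_3d_mm): Pearson r = 0.154 (p = 0.671); Spearman rho = 0.176 (p = 0.627)
```

One simulated 10-deposit phantom run: the deposits land on average 0.60 mm
from their planned electrode axis in the RL/AP plane and 1.16 mm from the
planned target in 3D — the SI component dominates because the outer guide
tubes are shorter than the central one and the digital model does not know
it. The per-axis rows are signed means (+SI = superior); `mark_*` rows are
the guide-tube penetration marks, which carry no depth information. The
depth–offset correlation is the check that targeting error does not grow
with penetration depth.

```r
deposit_mass(current_uA = 4, duration_s = 300)
#> [1] 347.2768   # ng of iron deposited as Fe2+ — the protocol's ~350 ng
```

A command-line surface over the same functions ships in
`inst/cli/stereonav` (`simulate`, `evaluate`, `align-demo`, `faraday`).

## Vignette

`vignettes/targeting-accuracy.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, and the numerical choices
(tolerances, tie-breaking, degenerate cases).
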