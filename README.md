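# geledge

Soft hydrogels (Matrigel, collagen, PEG gels) used for 3D cell culture
almost always sit on rigid glass or plastic. Near that support the gel is
apparently stiffer than in the bulk: a cell-sized probe indenting a thin gel
layer feels the substrate underneath. Cells sense this inherent interfacial
stiffness gradient — near the support they spread, elongate and migrate
fast; far from it they stay rounded and slow. `geledge` is an R package for
quantifying both sides of that story:

* **Contact mechanics.** An axisymmetric small-strain finite-element model
  of a frictionless rigid sphere (radius *R* = 5 µm, cell-sized) indenting a
  finite-thickness elastic gel (*E* = 450 Pa) bonded to a rigid base.
  Effective stiffness is the straight-line slope of the force–deflection
  record *F*(δ); the half-space limit is validated against the Hertz closed
  form *F* = (4/3)·*E*/(1−ν²)·√*R*·δ^{3/2} and the finite-thickness trend
  against the bonded-layer correction 1 + 1.133χ + 1.283χ² + 0.769χ³ +
  0.0975χ⁴, χ = √(Rδ)/h.
* **Cell analysis.** z-resolved morphometry (area, moment-ellipse aspect
  ratio, exponential height profiles m(z) = m_bulk + (m₀ − m_bulk)e^{−z/λ}),
  translation drift registration by FFT cross-correlation, nearest-neighbour
  track linking, path-length migration speeds, and the standard two-sample /
  rank-based / ANOVA comparisons.
* **Synthetic microscopy.** A seeded generator of image stacks and
  time-lapse movies with known ground truth (mixture populations of spindle
  and rounded cells, persistent random-walk migration, global gel drift), so
  the whole measurement pipeline is testable without real microscopy data.

## Worked example

Sweep the gel height at fixed indenter and material:

```r
library(geledge)
sweep <- height_sweep(c(12.5, 25, 50, 100, 200))
as.data.frame(sweep)
#>   height_um stiffness_N_per_m max_vm_Pa interface_vm_Pa n_elements n_contact
#> 1      12.5       0.005207810  294.7812     49.84151750       1525        10
#> 2      25.0       0.004178443  251.0981     11.27367190       2257         9
#> 3      50.0       0.003798411  235.1473      2.99248010       2501         9
#> 4     100.0       0.003630466  228.8682      0.77482400       2745         9
#> 5     200.0       0.003550538  226.1189      0.15511640       2989         9
```

Reading this: a 12.5 µm gel feels ~1.47× stiffer to a cell-sized probe than
a 200 µm gel of the same material, and the von Mises stress reaching the
gel–glass interface grows from ~0.07% of the contact-zone maximum (200 µm)
to ~17% (12.5 µm) — the edge effect is confined to roughly the lowest
50 µm.

Recover migration statistics through the full synthetic pipeline
(generate → drift → render movie → register → detect → link → speeds):

```r
rec <- recover_condition_speeds(preset_conditions("matrigel40_low"),
                                n_tracks = 45, persistence = 0.7,
                                drift_scale = 1.5,
                                seed_tracks = 1, seed_drift = 2, seed_movie = 3)
rec$summary
#> # A tibble: 1 x 4
#>   group              n  mean    sd
#>   <chr>          <int> <dbl> <dbl>
#> 1 matrigel40_low    42  28.3  11.0
```

i.e. 42 of 45 seeded tracks survive imaging, registration and linking, and
their mean path-length speed (28.3 µm/hr here) recovers the configured
population mean of 29.5 µm/hr within sampling error, while the bulk
condition recovers ~7.5 µm/hr — the ~4× interface/bulk contrast with
p < 0.001 in a pooled t-test.

An end-to-end run (`run_fem_sweep()`, `run_synthetic_experiment()`,
`reproduce_report()`) is scriptable via the thin CLI in
`inst/cli/geledge.R`; configuration is a flat YAML file documented in
`?read_run_config` with a commented example in
`inst/extdata/example-config.yaml`. The methods vignette
(`vignettes/gel-edge-effects.Rmd`) records the models, parameter choices
and numerical conventions.

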