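# pemscat

Monte Carlo study of **inter-crystal Compton scatter** in a large-area
dual-panel positron emission mammography (PEM) scanner, for detector and
image-reconstruction researchers comparing monolithic and pixelated LYSO
crystal configurations.

When a 511 keV annihilation photon interacts more than once in a detector
crystal, the detector assigns it the energy-weighted centroid of its
interaction points,

    EWP = Σᵢ Eᵢ rᵢ / Σᵢ Eᵢ ,

rather than the physically correct first-hit position (FHP). The in-plane
distance Δr_xy = ‖(X,Y)_EW − (X,Y)_FH‖ mispositions the line of response
and degrades reconstructed contrast. `pemscat` quantifies this effect end
to end:

* **transport** — back-to-back 511 keV photon pairs tracked through two
  3×3-block LYSO panels (60 mm gap; monolithic 57.4 mm crystals or 40×40
  arrays of 1.35 mm pixels), with photoelectric absorption and
  free-electron Klein–Nishina Compton scattering only;
* **digitizer** — per-panel singles, 13% energy resolution at 511 keV
  (FWHM ∝ √E), 6 µs non-paralyzable dead time, 6 ns coincidence window,
  350–750 keV energy window;
* **classification** — SI–SI / MI–SI / MI–MI coincidence classes by
  per-photon hit count, Compton-chain statistics, Δr_xy distributions;
* **reconstruction** — list-mode OSEM (2 iterations × 28 subsets,
  174×174×24 voxels of 1×1×2.5 mm³) with a Siddon line projector,
  virtual-crystal LORs and planar-source normalization, for a miniDerenzo
  resolution phantom;
* **metrics** — peak-to-valley ratios (PVR), per-rod 2D Gaussian FWHM and
  resolvability indices RI = FWHM/d (rods resolved when RI < 1).

The methods vignette (`vignettes/crystal-scatter-methods.Rmd`) documents
the physics models, defaults and numerical choices in detail.

## Worked example

A desk-scale crystal-scatter study of the uniform 15×10×6 cm³ cuboid
phantom with monolithic crystals:

```r
library(pemscat)
geom <- scanner_geometry("monolithic")
run  <- simulate_study(phantom_cuboid(), geom, n_events = 5e5, seed = 1)

classify_coincidences(run$coincidences)
#> Coincidence classification (54295 coincidences)
#>   SI-SI 20.2%  MI-SI 49.4%  MI-MI 30.4%
#>   single PE photons: 44.5%; CS->PE split (1,2,3,>=4): 0.651, 0.264, 0.069, 0.016
#>   randoms: 1.82%

positioning_errors(run$coincidences)
#> Positioning errors over 86654 photons of MI coincidences: mean 1.77 mm, 80th pct 2.80 mm
```

Reading: 500 000 emitted photon pairs yield 54 295 registered
coincidences. Only ~20% of them are "clean" events in which both photons
interacted exactly once (SI–SI, mostly single photoelectric absorptions —
44.5% of all accepted photons); in the remaining ~80% at least one photon
scattered before being absorbed. Over the photons of those
multiple-interaction coincidences, the energy-weighted position sits on
average 1.77 mm from the true first hit in-plane, and 80% of photons are
positioned within 2.80 mm.

The image-quality arm reconstructs a miniDerenzo phantom twice from the
same coincidence list — once with FHP endpoints, once with EWP endpoints —
and scores each sector:

```r
derenzo <- phantom_derenzo()
study <- simulate_study(derenzo, geom, n_events = 8e6, seed = 1, lean = TRUE)
norm  <- simulate_study(phantom_planar(), geom, n_events = 6e6, seed = 2, lean = TRUE)
img_f <- reconstruct_study(study$coincidences, norm$coincidences, geom, "fhp")
img_e <- reconstruct_study(study$coincidences, norm$coincidences, geom, "ewp")
sector_report(img_f, derenzo$layout, diameter = 2)$pvr$mean /
  sector_report(img_e, derenzo$layout, diameter = 2)$pvr$mean
```

which prints the FHP/EWP peak-to-valley contrast ratio for the 2 mm rods
(≈8–9 with monolithic crystals at this scale: crystal scatter costs nearly
an order of magnitude of hot-rod contrast even though the rods stay
resolved, RI ≈ 0.35 < 1).

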