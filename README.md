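# bmpheal

A mechano-chemical simulator of bone defect healing in the rat femur,
written in pure R. The model couples:

- **BMP-2 reaction–diffusion** — free growth factor with a 0.42-day in
  vivo half-life, Michaelis–Menten consumption by cells, homeostatic
  production, and an encapsulated pool released from a degrading
  alginate hydrogel carrier (in-gel half-life 3.25 days, release rate
  growing as the gel degrades);
- **alginate hydrogel dynamics** — slow bulk hydrolysis plus cell-driven
  degradation, with cell motility and chemotaxis gated by the remaining
  gel fraction;
- **MSC migration** — a conservative finite-volume
  diffusion–chemotaxis (Keller–Segel) scheme with a mineral-blocking
  rule for consolidated tissue;
- **dose-dependent BMP-2 modulation** — experimentally anchored fold
  curves for proliferation, chemotaxis, chondrocyte hypertrophy and
  bone-matrix production, all ≈1-fold across the physiological range
  (0.008–0.5 ng/cm³) and rising only at supra-physiological doses;
- **mechanoregulated differentiation** — a plane-strain Q4 finite
  element model of the fixated femur (14.4 N axial gait load, 277 N/mm
  fixator) provides the distortional stimulus ψ = √J₂ of the deviatoric
  strain, which selects the tissue fate (bone / cartilage / fibrous)
  that BMP-2-gated MSCs commit to.

The domain is a 2D longitudinal half-section of an idealized cylindrical
rat femur with a fracture gap or segmental defect at mid-shaft.

## Worked example

Simulate an 8 mm critical-size defect treated with an alginate implant
loaded with 5 µg BMP-2, for 12 weeks on the default 0.25 mm mesh
(runs in a few seconds):

```r
library(bmpheal)

sc  <- scenario(gap_mm = 8, gel_present = TRUE, bmp2_dose_ug = 5,
                horizon_days = 84)
sim <- simulate_healing(sc)
sim
#> <healing_sim> 8 mm gap, alginate gel, 5 ug BMP-2, 84 days
#>   defect bone fill: 87.5% (day 84)
#>   10% bone crossing: week 2.1
#>   alginate remaining: 12.0%

summary(sim)
#> final defect bone fill : 87.5 %
#> final cartilage        : 0.0 %
#> alginate remaining     : 12.0 %
#> 10% bone crossing      : week 2.1
#> peak mean BMP-2 (defect): 1.12 ng/cm3
#> final mean BMP-2 (defect): 0.00831 ng/cm3

plot(sim)                      # bone-fill and BMP-2 time series
plot(sim, "map")               # final bone-fraction map
report(sim, "out/")            # CSV series, JSON digest, VTK snapshots
```

Key comparison scenarios:

```r
simulate_healing(scenario(2, FALSE, 0, 42))   # 2 mm fracture: bridges (>90% bone)
simulate_healing(scenario(8, FALSE, 0, 84))   # untreated defect: non-union (0%)
simulate_healing(scenario(8, TRUE,  0, 84))   # gel alone: no bone, gel ~96% intact
```

Everything is configurable: `scenario()` accepts alternative geometry,
`rule_thresholds()`, `motility_params()`, `bmp_params()`,
`alginate_params()` and modulation curve sets (revisable from CSV via
`read_modulation_csv()`). The model is fully deterministic for a given
configuration.

A YAML-driven command line interface is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/simulate.R", package="bmpheal"))')" \
    --config run.yaml --out outdir
```

## Tests

```r
testthat::test_dir("tests/testthat", package = "bmpheal",
                   load_package = "installed")
```

The suite (≈25 s) covers exact closed-form oracles for every kinetic
law, FE patch and spring-series oracles for the mechanics, conservation
and positivity properties of the transport schemes, and the full
scenario-level acceptance criteria.

See `vignettes/mechanochemical-model.Rmd` for the model description,
numerical methods, and the calibration rationale behind the frozen
default parameters.
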