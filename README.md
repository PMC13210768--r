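# fibersense

A fully synthetic test bench for automated fluorescence-microscopy counting
of airborne asbestos fibers collected on membrane filters — for people
building or validating automated fiber-counting instruments and for anyone
who needs the counting statistics of filter-based fiber measurements.

Airborne fiber concentrations are measured by drawing air through a
membrane filter and counting deposited fibers under a microscope using the
standard morphological rule (length > 5 µm, width < 3 µm, aspect ratio
> 3:1, aggregates excluded). The count converts to a concentration via

```
C (f/L) = A · N / (a · n · V)
```

with `A` the effective filter area (mm²), `a` the field-of-view area, `n`
the number of fields counted and `V` the sampled air volume (L). The
package implements the full computational chain of an automated instrument
on simulated data, so that every stage can be scored against known ground
truth:

* **`sample_scene()` / `render_zstack()`** — seeded ground-truth fields
  (fibers, non-fibrous particles, membrane texture) rendered as 25-plane
  z-stacks with depth-dependent Gaussian defocus and Poisson–Gaussian
  noise;
* **`focus_stack()`** — extended-depth-of-field fusion by per-pixel argmax
  of local Laplacian energy, with provenance and an oracle-testable exact
  arithmetic specification;
* **`detect_fibers()`** — median-background segmentation, skeleton
  morphometry (geodesic length, distance-transform width), strict
  criteria-based classification with rejection reasons, logistic
  confidence scores, high-background flagging;
* **`fiber_concentration()`** — the count-to-concentration conversion and
  detection-limit arithmetic;
* **`relative_differences()` / `bland_altman()` / `loa_funnel()`** —
  relative-difference Bland–Altman agreement and Poisson
  counting-variability simulation;
* **`run_cycle()` / `run_monitoring()`** — end-to-end measurement cycles
  with machine-readable reports.

## Worked example

One simulated measurement cycle on a quarter-size field (234 × 156 µm,
with the sampling geometry scaled to match):

```r
library(fibersense)

cfg <- cycle_config(
  sampling = sampling_config(field_width = 0.234, field_height = 0.156),
  stack    = stack_spec(n_planes = 7, z_step = 2, z_origin = 4),
  detector = detector_config(pixel_size = 0.33),
  scene_params = list(fiber_mean = 6, particle_mean = 20,
                      field_size = c(234, 156), pixel_size = 0.33),
  seed = 7)
run_cycle(cfg, 1)
#> <cycle_report #1> N = 6 fibers, C = 145.2 f/L
```

Six detected fibers; each fiber represents
`A/(a·n·V)` = 176.7/(0.0365 · 1 · 200) ≈ 24.2 f/L at this scaled-down
field, hence 145.2 f/L. At the full instrument geometry a single counted
fiber is the familiar detection granularity:

```r
fiber_concentration(1)
#>   n_fibers concentration_fl concentration_raw single_fiber_equivalent
#> 1        1                3              3.04                    3.04
```

The Poisson counting funnel — limits of agreement between two simulated
instruments widening as the mean fiber count falls:

```r
sfe <- fiber_concentration(1)$single_fiber_equivalent
loa_funnel(c(1, 4, 16) * sfe, n_reps = 2000, seed = 3)
#>   lambda mean_count mean_rel_diff sd_rel_diff loa_low loa_high loa_width
#> 1      1        1.0           5.0       149.1  -287.1    297.2     584.3
#> 2      4        4.0           0.7        77.7  -151.6    152.9     304.5
#> 3     16       15.9           0.1        35.7   -69.8     70.0     139.8
```

A measurement averaging λ ≈ 1 expected fiber per field carries ±~290%
limits of agreement from counting noise alone; at λ ≈ 16 they shrink to
±70%, tracking the `100·√(2/λ)` % delta-method prediction. `autoplot()`
methods draw the Bland–Altman scatter and the funnel.

A thin command-line front end is included at
`inst/scripts/fibersense.R` (`run`, `demo`, `conc`, `ba` subcommands).

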