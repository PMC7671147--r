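# naupflow

Kinematic and hydrodynamic analysis of swimming nauplius larvae from
high-speed video derivatives: landmark digitizations (tpsDIG TPS files)
and gridded micro-PIV velocity fields.

Nauplii — the first free-swimming larval stage of crustaceans — propel
themselves with three pairs of head appendages (antennule, antenna,
mandible). How they beat those appendages determines how fast they swim,
how much backward slip they suffer each recovery stroke, how far their
hydrodynamic disturbance radiates to rheotactic predators, and whether
they can steer a feeding current onto the food-capture region. naupflow
turns digitized video into those quantities:

* **Swimming kinematics** (`measure_kinematics()`): appendage angles
  θ = cos⁻¹(CA·CT / ‖CA‖‖CT‖) against the tail vector CT; beat frequency,
  per-appendage amplitudes and mid-stroke angular speeds, percent of time
  appendage pairs move in phase, angular separations, swimming speed U
  (mm s⁻¹ and body lengths s⁻¹), Reynolds number Re = UL/ν, and the
  forward:backward displacement ratio from the sign of disp·CT.
* **Hydrodynamics**: vorticity ω and vortex circulation Γ = Σω·dx·dy
  (`vorticity()`, `find_vortices()`), the area of influence above a
  0.0005 m s⁻¹ detectability threshold (`area_of_influence()`), the
  spatial attenuation power n of ‖V‖ ∝ rⁿ by threshold-binning and
  log–log regression (`attenuation_fit()`), line fluxes Φ = Σ(v·n̂)dl in
  the laboratory and body frames (`flux_through_line()`,
  `relative_flux()`), and Lagrangian particle paths (`trace_particles()`).
* **A basic multi-pass PIV engine** (`mask_larva()`, `piv_multipass()`)
  for computing fields from raw particle-image frames when no commercial
  package is available.
* **Synthetic data with ground truth** (`make_landmarks()`,
  `make_field()`, `make_particle_images()`) so every estimator is
  validated against known parameters.
* **Group statistics** (`perm_t_test()`, `build_summary()`):
  permutational T-tests (9999 permutations by default) and mean ± SE
  summary tables.

## Worked example

Generate a planktotroph-like swimmer (beat 11.4 Hz, amplitudes
48.9/90.5/56.5°, speed 4.5 mm s⁻¹, forward:backward ratio 9.3, 0.5 px
digitizing noise) and measure it back:

```r
library(naupflow)

spec <- species_kinematics_spec("planktotroph", rng_seed = 1)
lm1  <- make_landmarks(spec)
measure_kinematics(lm1, run_config(body_length = 447.4))
#> <kinematics_result>
#>   speed       4.52 mm/s (10.1 BL/s), Re = 2.13
#>   frequency   11.4 Hz over 2 cycles; fwd:bwd = 8.99
#>   amplitude   ant1 50.1, ant2 90.8, mand 56.5
#>   % in phase  ant1_ant2 51, ant1_mand 22, ant2_mand 71
```

The recovered values sit on the generator's ground truth to within the
digitizing noise: ~4.5 mm s⁻¹ (≈10 body lengths s⁻¹, Reynolds number
≈2.1), the prescribed 11.4 Hz beat, and a forward:backward ratio near
9.3 — the larva slips back little during recovery strokes.

Fit the spatial attenuation of a radially decaying flow field
(80 × 64 cells, 25 µm pitch) with a known power:

```r
attenuation_fit(make_field(field_spec("power_decay", n = -1.47)))
#> <attenuation_fit> power n = -1.452 (r^2 = 1.000, 6 bins)
```

A power near −1.5 is the signature of a cruising swimmer; fast jumpers
attenuate nearer r⁻³ and are harder for predators to detect at range.

Compare two groups with the permutational T-test:

```r
perm_t_test(c(35.2, 37.1, 34.8, 36.0, 35.4),
            c(11.1, 11.9, 10.8, 11.6, 11.3), n_perm = 9999, seed = 1)
#> <perm_test_result> diff = 24.36, p = 0.0063 (montecarlo, 9999 permutations, n = 5 vs 5)
```

With n = 5 per group, the smallest attainable two-sided p is about
2 × (5!·5!/10!) ≈ 0.0079 under the add-one convention — the printed 0.0063
reflects the Monte-Carlo estimate of that floor.

File-based workflows mirror the same functions: `read_tps()` for tpsDIG
landmark files (the landmark digitizing order is supplied explicitly),
`read_field_sequence()` for velocity-field directories (delimited text
plus a JSON sidecar), `read_run_config()` for YAML/JSON analysis
configuration.

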