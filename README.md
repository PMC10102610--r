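# mammoshield

Desk-scale Monte Carlo photon transport for a question in mammography
radioprotection: how much does a transparent protective screen, standing
between the breasts during a mammographic exposure, reduce the scattered
dose received by the *unexposed* (contralateral) breast — and how does a
cadmium-oxide-rich tellurite glass screen compare with the conventional
lead-acrylic one?

The package is aimed at medical-physics researchers who want a small,
fully inspectable transport code for layered-phantom shielding studies:
every physics ingredient is exposed as a testable function, results come
back as tibbles, and a complete two-breast phantom study runs in minutes on
one CPU.

## What it computes

* **Analog photon transport** through axis-aligned box geometry:
  exponential free paths `s = -ln(ξ)/μ`, interaction channels drawn in
  proportion to the partial mass-attenuation components, photoelectric
  absorption, Klein–Nishina (free-electron) incoherent scattering sampled by
  Kahn rejection, Thomson coherent scattering, and the kerma approximation
  (secondary electrons deposit locally — their range at mammographic
  energies is far below the 2-mm voxel scale).
* **Materials** from an embedded per-element table of photoelectric,
  incoherent and coherent mass-attenuation components (1–150 keV, with
  K/L-edge resolution for Zn, Nb, Cd, Te and Pb), combined by the mixture
  rule μ/ρ = Σᵢ wᵢ (μ/ρ)ᵢ with log–log interpolation.
* **The phantom**: two three-layer breasts (glandular fractions 25/50/75 %
  from the top down, the published compositions and densities), 2-mm skin
  shells, a soft-tissue body block, a collimated source 65 cm above the
  image plane aimed at the right breast, and optionally a 20 × 20 cm²,
  12-mm screen (lead-acrylic or C40 glass) centred between the breasts.
* **Tallies**: per-region deposited energy per source photon with Monte
  Carlo relative errors, planar crossing counts, the transmission factor
  TF = secondary / primary intensity, total skin dose over the three
  modelled skin cells of each breast, narrow-beam lead equivalence
  t_Pb = μ·t / μ_Pb, and percent dose reductions with propagated
  uncertainties.

## Worked example

```r
library(mammoshield)

mu_rho("lead_acrylic", 30)
#> [1] 9.229164
lead_equivalence("lead_acrylic", thickness_cm = 1.2, energy_keV = 30)
#> [1] 0.5197233
```

The default lead-acrylic model (PMMA + 30 wt% Pb, 1.6 g/cm³) has a mass
attenuation coefficient of 9.23 cm²/g at 30 keV, and its 12-mm slab is
worth 0.52 mm of pure lead in narrow-beam attenuation — matching the
~0.5 mm Pb equivalence quoted for the physical screen.

```r
tf <- tf_pilot(c("lead_acrylic", "c40"), energies = c(30, 40),
               n_histories = 1e5, seed = 1)
tidy(tf)[, c("material", "energy_keV", "primary", "secondary", "tf")]
#> # A tibble: 4 × 5
#>   material     energy_keV primary secondary    tf
#>   <chr>             <dbl>   <dbl>     <dbl> <dbl>
#> 1 lead_acrylic         30   25656         0     0
#> 2 lead_acrylic         40   25498         0     0
#> 3 c40                  30   25656         0     0
#> 4 c40                  40   25498         0     0
```

The two-detection-zone pilot: identical seeds give identical primary
counts for every screen material, and at mammographic energies both 12-mm
screens are radio-opaque — none of the ~25,600 counted primaries emerges
behind either slab (lead-acrylic starts leaking a handful of photons per
10⁵ primaries only towards 40 keV).

```r
scn <- run_scenario(screens = c("none", "c40"), energies = c(25, 35),
                    n_histories = 1e5, seed = 1)
glance(scn)[, c("screen", "energy_keV", "right_total_eV",
                "left_total_eV", "left_se_eV")]
#> # A tibble: 4 × 5
#>   screen energy_keV right_total_eV left_total_eV left_se_eV
#>   <chr>       <dbl>          <dbl>         <dbl>      <dbl>
#> 1 none           25         13802.        140.        5.69
#> 2 none           35         11769.        232.        8.20
#> 3 c40            25         13804.          1.26      0.557
#> 4 c40            35         11761.          2.76      0.925
```

Reading the scenario summary: the exposed right breast absorbs ~12–14 keV
per source photon and is unaffected by the screen (13802 vs 13804 eV at
25 keV, well within one standard error). The unexposed left breast
receives 140–232 eV/photon of pure scatter without a screen; the C40
screen cuts that by about 99 % (to 1.3–2.8 eV/photon, at the edge of
statistical resolution). `autoplot(scn)`, `plot_layer_doses(scn)` and
`autoplot(tf)` draw the standard figures; `tidy(scn)` returns the full
per-region dose table.

A ready-made YAML configuration (materials, phantom, screens, source,
transport blocks) ships in `inst/extdata/default_config.yaml`, and
`inst/cli/mammoshield.R` wraps the same functions as `materials-list`,
`tf-pilot`, `run-study` and `lead-equivalence` subcommands.

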