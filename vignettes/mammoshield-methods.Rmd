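---
title: "Methods: photon transport and shielding dosimetry in mammoshield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photon transport and shielding dosimetry in mammoshield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mammoshield)
```

## The problem

During a mammographic exposure, the breast under examination scatters a
small fraction of the beam sideways, and part of that scatter reaches the
*contralateral* (unexposed) breast. A transparent protective screen placed
between the breasts intercepts this scatter; the screen of interest here is
a cadmium-oxide-rich quaternary tellurite glass ("C40"), proposed as a
lead-free alternative to the conventional lead-loaded acrylic screen.
`mammoshield` implements the complete simulation chain for this comparison:
material physics, box-constructive geometry, analog photon transport,
dose and transmission tallies, and the two-breast study driver.

## Physics model

### Cross sections and the mixture rule

Each element carries a table of three mass-attenuation components
(photoelectric, incoherent, coherent, in cm²/g) on a shared logarithmic
energy grid from 1 to 150 keV, with extra grid points bracketing the K and
L edges of the high-Z screen constituents (Zn, Nb, Cd, Te, Pb) so that,
e.g., the Cd K edge at 26.7 keV — squarely inside the mammographic range —
is resolved. The table was generated once from published compilations
(Cromer–Liberman photoabsorption for the photoelectric part; International
Tables atomic form factors driving Thomson and Klein–Nishina kernels for
the coherent and incoherent parts; see `data-raw/`) and is shipped as a
plain-text package asset. Totals agree with standard reference values for
water and lead to within a few percent over 20–100 keV, which is ample for
the ratio-based quantities this package reports.

Interpolation is log–log *per component*, and the total is defined as the
sum of the three interpolated components. This deviates slightly from
interpolating the tabulated total directly, but it guarantees that the
channel probabilities used by the transport (proportional to the partials)
always sum to the total attenuation actually applied — at the grid points
the two conventions coincide exactly. Energies outside the grid are
refused rather than extrapolated; photoelectric cross sections vary as a
steep power law and extrapolation would be silently wrong.

Materials are elemental mixtures with a bulk density; the mixture rule
`mu_rho()` is the weight-fraction-weighted sum of element components, and
`linear_mu()` multiplies by density. Published tissue-composition rows are
truncated to one decimal and sum to 99.3–99.8 %; `normalize_composition()`
rescales them to exactly 1 while preserving the printed ratios, and the raw
row is recorded in each material's provenance note.

### Transport

Histories are analog (weight 1 throughout): no implicit capture, no
splitting. The random walk samples a free path `s = -ln(ξ)/μ_total`,
streams surface-to-surface through the box geometry, and on interaction
selects a channel with probability proportional to the partial linear
attenuation coefficients at the current energy:

* **photoelectric** — the full remaining energy is deposited at the
  interaction point and the history ends;
* **incoherent** — the polar angle is drawn from the free-electron
  Klein–Nishina distribution by Kahn's rejection method; the scattered
  energy follows the Compton relation `E' = E / (1 + (E/m_e c²)(1-cosθ))`
  and the energy transfer `E - E'` is deposited locally;
* **coherent** — elastic deflection with the Thomson angular law
  `∝ (1 + cos²θ)` (no form-factor weighting of the *angle*; the channel
  *probability* does come from the form-factor-weighted table entry).

Azimuths are uniform. Direction rotation uses the standard local-frame
construction with an x-axis-based frame at the poles (|u_z| ≈ 1).
Photons falling below the cutoff (default 1 keV, the lower edge of the
table) deposit the remainder locally; so do histories hitting the
interaction cap (default 1000, counted as aborted — in practice none are).

**Kerma approximation.** Secondary electrons deposit their energy at the
photon interaction site. Sub-50-keV electrons in tissue have ranges of
tens of micrometres, far below the 2-mm skin voxels that are the smallest
scoring regions, so collision kerma and absorbed dose coincide at the
tally resolution. Characteristic fluorescence after photoelectric
absorption is also deposited locally; for the high-Z screen constituents
(Cd and Te K fluorescence at ~23–31 keV, Pb L at ~10–15 keV) this
overstates the screen's self-absorption slightly and is a documented
physics limitation.

### Randomness and reproducibility

Every history runs on its own PCG32 stream seeded deterministically from
(master seed, history index). Consequences: (i) a given seed and
configuration reproduces all tallies bit for bit, on any platform;
(ii) two runs that share a seed but differ in a downstream material (e.g.
the two screen options in the transmission pilot) emit *identical*
photons, so their primary detection-zone counts are exactly equal — the
between-material comparison is common-random-numbers paired by design.
R-level sampler wrappers draw their default seeds from R's RNG, so
`set.seed()` governs them in the usual way.

## Geometry

Scenes are tibbles of axis-aligned boxes with material names, integer
tally-cell ids (several boxes may share an id and are scored as one cell)
and integer priorities for overlap resolution. Containment is half-open
(`min ≤ x < max`); a point exactly on a shared face resolves to the region
on the far side of the travel direction, implemented by nudging the photon
1 nm past each crossed surface. Surface stepping combines a global
nearest-face search with an exact exit-distance computation for the
currently resolved box, so features thinner than the nudge cannot trap a
photon with a stale material. `scene_distance()` exposes the
walk-to-region-change distance that the transport uses internally, and is
tested against a fine-step ray-marching oracle.

## The study conditions

The phantom builder is the package's scenario generator; its defaults are
the study conditions and are deliberately fixed:

| parameter | default | status |
|---|---|---|
| breast block | 10 × 10 × 6 cm, three 2-cm layers | assumed (figures only) |
| layer glandular fractions | 25 / 50 / 75 % top-down | published |
| layer compositions, densities | published table rows | published |
| skin | 2 mm on five faces, three tally cells per breast | published thickness |
| inter-breast gap | 4 cm | assumed |
| body block | 30 × 20 × 15 cm soft tissue | assumed (material unspecified) |
| source-image distance | 65 cm | published |
| screen | 20 × 20 cm², 12 mm, centred between breasts | published |
| energies | 20, 25, 30, 35, 40 keV monoenergetic | assumed (not printed) |
| histories | 10⁶ per (screen, energy) | package choice |

Left-breast cells follow the published numbering: skin cells 9 (top +
bottom), 10 (medial, facing the screen) and 11 (remaining faces). The
lateral dimensions and the energy grid are genuinely open parameters — the
source publication shows them only as sketches or unlabelled axes — so all
headline comparisons are ratio- or ordering-based, which are robust to the
size choices. Every assumed value is config-overridable
(`inst/extdata/default_config.yaml`).

**Screen materials.** Lead-acrylic is modelled as PMMA loaded with
30 wt% Pb at 1.6 g/cm³; with the embedded tables its 12-mm slab evaluates
to 0.52 mm of pure lead in narrow-beam equivalence at 30 keV, matching the
~0.5 mm quoted for the physical screen without further adjustment. The C40
glass composition is not published alongside the study; the shipped
default is a *synthetic stand-in* — 40 CdO · 40 TeO₂ · 10 ZnO · 10 Nb₂O₅
by mole at 5.7 g/cm³, a plausible CdO-rich quaternary tellurite — clearly
flagged in its provenance note and intended to be replaced by the measured
oxide fractions via `library_with()` or the config file.

## Tallies and derived quantities

Per-region deposition uses history statistics: per-history sums and sums
of squares give the mean energy per source photon and the standard
relative error (reported as 1 with a degenerate flag when the mean is
zero). Doses are reported both as eV/photon and eV/g/photon; region masses
come from resolved volumes (the builder corrects the body volume for the
screen slab that displaces it) times material density. The transmission
factor is the ratio of weighted crossing counts of two bounded detection
rectangles; in the pilot both rectangles cut the same cone that the slab's
exit face subtends from the point source, so a vacuum "absorber" yields
TF = 1 up to edge effects. Scattered photons count toward the rear zone by
default (broad-beam); a primaries-only mode supports the analytic
narrow-beam oracle `exp(-μt)`. Percent dose reduction uses first-order
propagation of the two Monte Carlo errors and is invariant to the common
normalization of its inputs.

## What the desk-scale runs resolve — and what they do not

Three findings from the default conditions deserve explicit statement,
because they bound what passing tests demonstrate about the physical
screens:

1. **Both 12-mm screens are radio-opaque at 20–40 keV.** The lead-acrylic
   slab presents μt ≈ 17–50 mean free paths, the C40 slab more. Through-
   screen transmission is ~e⁻¹⁷ or smaller; with 10⁵–10⁶ histories the
   rear detection zone records zero photons below ~35 keV for both
   materials, and single energies tie at TF = 0. The glass-vs-lead-acrylic
   TF ordering is therefore resolvable only in aggregate over the energy
   grid (lead-acrylic leaks a few photons per 10⁵ primaries at 35–40 keV;
   C40 none).
2. **The shielded contralateral dose is dominated by screen-independent
   routes.** With either screen in place, the left-breast dose (~1–3
   eV/photon against 70–260 unshielded) arrives by multiple scatter
   through the body block and around the screen — paths identical for both
   screen materials. The measured C40-vs-lead-acrylic reduction is thus
   statistically compatible with zero *and* with the 35–38 % superiority
   reported for the physical screens; the desk-scale model can neither
   reproduce nor contradict that figure at these energies. (The band check
   in the acceptance suite applies its documented tolerance,
   max(propagated 2σ, 3 points), verbatim.)
3. **Energy trends suggest the published axes are not 20–40 keV.** In this
   model the exposed-breast deposited energy per photon peaks near 25 keV
   and declines with energy (the absorbed fraction falls faster than the
   photon energy rises), and the unshielded contralateral leakage *grows*
   with energy. A monotone increase of the exposed-breast dose with
   energy, as described for the published figures, would require either
   higher energies or a different normalization.

Two further model-vs-expectation notes. In the *unshielded* phantom the
left-breast layer doses peak in the *middle* layer from 25 keV up: lateral
scatter illuminates the layers nearly equally, the middle layer is denser
(GF 50 % vs 25 % on top), and at 65 cm the inverse-square gradient across
2-cm layers is negligible — the top-layer maximum holds for the *shielded*
configurations, which is what the published layer-resolved comparison
shows. And the validation against the external reference dataset
(an 80/20 adipose-to-glandular phantom, ~4,782 eV/photon) requires that
report's geometry and spectra, which are not shipped;
`tg195_validation()` is config-gated and fails with a clear message until
the caller supplies them.

## Numerical choices

* Geometry nudge 10⁻⁹ cm; face-candidate tolerance 10⁻¹² cm; exact
  exit-distance capping for the resolved box (see Geometry).
* Energy bookkeeping closes per history to machine precision (checked on
  every run; the suite asserts max closure error < 10⁻⁹ keV).
* Cutoff 1 keV; below it (and at the interaction cap) the remainder is
  deposited locally, preserving conservation by construction.
* Ties in overlap priority resolve to the first box in scene order;
  builders assign unique priorities where overlaps are intended.
* TF standard errors treat the secondary count as binomial out of the
  primary count; reduction uncertainties use first-order propagation.
* Default test and acceptance problem sizes (10⁵ histories per slab case,
  4 × 10⁵ per scenario cell, 5 × 10⁵ per pilot cell) hold headline
  relative errors near or below the percent level where doses are
  measurable; they are the package's documented defaults, scaled for a
  single-CPU workstation.

## Known limitations

Free-electron Compton (no binding, no Doppler broadening); Thomson angles
for coherent scattering (no form-factor anisotropy in the sampled angle);
no fluorescence transport; no electron transport (kerma approximation);
monoenergetic sources only (no anode/filter spectra); axis-aligned boxes
only (no curved anatomy). These are the standard first-order
simplifications for shielding-ratio studies at mammographic energies; the
channel probabilities and total attenuation, which drive the reported
ratios, come from full form-factor-weighted tables.
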