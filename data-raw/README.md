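# Data provenance

`make_element_xs.py` regenerates `inst/extdata/element_xs.tsv`, the embedded
per-element mass-attenuation component table (1-150 keV, shared log grid with
K/L-edge brackets for Zn, Nb, Cd, Te, Pb). It draws on published
compilations exposed by the `gemmi` library:

* photoelectric — Cromer-Liberman photoabsorption (f''), via
  sigma = 2 r_e lambda f'';
* coherent — Thomson scattering weighted by International Tables (IT92)
  atomic form factors, integrated numerically over angle;
* incoherent — Klein-Nishina kernel weighted by the standard
  incoherent-function approximation S(q) ~ Z (1 - (F/Z)^2), integrated
  numerically.

Totals agree with standard reference values (e.g. water and lead mass
attenuation coefficients) to within a few percent across 20-100 keV.
The table is regenerated only when the element set changes; it is a static
package asset, not rebuilt at install time.
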