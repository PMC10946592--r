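---
title: "Generating cone fundamentals: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating cone fundamentals: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conefund)
```

## The model

At photopic light levels, colour vision is determined by the relative
excitations of the L-, M- and S-cone photoreceptors. `conefund` represents
the three corneal cone spectral sensitivities as continuous functions of
wavelength built from a small set of closed-form ingredients:

1. **Photopigment absorbance templates.** Each cone class's log10
   absorbance spectrum is an 8th-order truncated Fourier series evaluated
   at an angle θ that runs linearly in *log10 wavelength* from 0 at 360 nm
   to π at 850 nm. Only half a period is used because the spectra differ at
   their two ends. The series coefficients are purely descriptive — they
   carry no biophysical meaning individually — but reproduce the underlying
   tabulated spectra to within a few thousandths of a log unit. A final
   additive constant `s` renormalizes each template so its *linear*
   absorbance peaks at 1 (to the nearest 0.1 nm). The log-wavelength axis
   matters: pigment spectra are approximately shape invariant on it, so
   templates can be translated along it to model pigments with different
   peak wavelengths (λ_max).

2. **Pre-receptoral pigment densities.** The macular and lens pigment
   optical density spectra use the same Fourier form on a *linear*
   wavelength axis (orders 11 and 9), with a multiplicative factor `d`
   pinning the standard anchors: macular density 0.350 at 460 nm, lens
   density 1.7649 at 400 nm. The macular spectrum is defined on 375–550 nm
   and the lens spectrum on 360–660 nm; both are identically zero outside
   their fitted support.

3. **The physiological chain.** For a cone with peak axial photopigment
   optical density OD and linear absorbance Ā(λ), the package computes

   * absorptance (self-screening): `1 - 10^(-OD * Ā(λ))`, which broadens
     the spectrum as OD grows without moving its peak;
   * corneal quantal sensitivity: absorptance times the pre-receptoral
     transmittance `10^-(k_lens*lens(λ) + k_mac*mac(λ))` — the exponent is
     negative, an attenuation, the only physically consistent reading;
   * energy-unit sensitivity: multiplication by λ (photon energy is
     inversely proportional to wavelength) followed by rescaling to a unit
     peak on the output grid, with the scaling constant α recorded.

The standard observers use OD = (0.50, 0.50, 0.40) for (L, M, S) with
k_mac = k_lens = 1 at 2 deg, and OD = (0.38, 0.38, 0.30) with
k_mac = 0.271 at 10 deg (foveal cones are longer than peripheral ones, and
macular pigment is largely confined to the central retina).

```{r standard}
cf2 <- cone_fundamentals(standard_observer("2deg"))
glance(cf2)
```

## Tunable parameters

| parameter | units | default (2 deg) | meaning |
|---|---|---|---|
| `od["L"]`, `od["M"]`, `od["S"]` | log10 | 0.50 / 0.50 / 0.40 | peak axial photopigment optical density; raising it broadens the fundamental (population range roughly 0.3–1.0 depending on method) |
| `k_mac` | — | 1 | scaling of the standard macular spectrum; equivalently `d_mac460` (density at 460 nm, population range about 0–1.2) |
| `k_lens` | — | 1 | scaling of the standard lens spectrum; equivalently `d_lens400`; young-observer variation is roughly ±25%, and density rises with age |
| `shift_nm` | nm | 0 / 0 / 0 | per-cone λ_max shift, applied as a log-wavelength translation |
| `l_variant` | — | `"mean"` | L-cone template: population mean, a single polymorphic variant, or an explicit ser/ala mixture |

Peak shifts are given in nm at the pigment's λ_max and converted internally
to log10 units via `log10((λ_max + shift)/λ_max)`, using the selected base
template's own peak as the reference. Genotype strings such as `"M[A285T]"`
are translated to nm shifts by summing tabulated per-codon effects for the
seven spectrally relevant codons (116, 180, 230, 233, 277, 285, 309; 233
and 309 are spectrally silent). Additivity across codons is an assumption —
the per-site shifts were measured largely one substitution at a time — but
it is the simplest rule consistent with hybrid-pigment peaks lying in steps
between the normal L and M peaks. Note the tabulated codon-180 effects
(+3 / −4 nm) differ slightly from the 2.7 nm separation built into the
dedicated polymorphic templates; the two pathways serve different purposes
(genotype arithmetic vs. template fits) and are deliberately not forced to
agree.

## The L-cone polymorphism and the common template

The population-mean L template averages the two common codon-180 variants,
so its shape is slightly broadened. For single-variant work,
`polymorphic_L("ser180")` is a dedicated fit peaking at 553.1 nm, and
`polymorphic_L("ala180")` is that template shifted by −0.002125 log10 nm
(550.4 nm, a 2.7 nm separation).

A separate *common* shape-invariant template (`builtin_template("L_common")`,
peak 557.5 nm) fits all three cone classes under pure log-wavelength
shifts: −0.024187 to M (527.3 nm) and −0.124549 to S (418.5 nm). It is
useful for exploring shape-invariance and for other species' pigments, but
it fits each individual human spectrum worse than the per-cone templates —
the M-cone absorbance is genuinely narrower than shape invariance predicts —
so it is kept out of the standard-observer pipeline.

Mixtures are always formed in **linear absorbance** and renormalized to a
unit peak. In the common-template construction the mixture reproducing the
mean L spectrum places weight 0.56 on the component shifted by −0.002108
log10 nm and 0.44 on the unshifted one; so formed, it peaks at 556.0 nm:

```{r mixture}
common <- builtin_template("L_common")
mx <- mix_templates(list(shift_template(common, -0.002108), common),
                    c(0.56, 0.44))
find_lambda_max(mx)
```

The observer-level `l_variant = "mixture"` default instead weights
ser180 at 0.56, matching the population frequency of the two alleles and
the mean-L template's own peak position; the two conventions are both
exposed because the source analyses are not mutually consistent on which
component carries the larger weight, and users re-mixing templates should
choose deliberately.

## Numerical choices

* **Peak search.** λ_max is located by grid evaluation at 0.1 nm over the
  template's support, ties broken toward shorter wavelengths, and reported
  on the 0.1 nm lattice. That matches the convention under which the
  renormalization constants were fitted. One consequence: the S-cone
  template's continuous peak lies at 416.985 nm, almost exactly between
  grid points, so the located grid peak is 417.0 nm against a nominal
  416.9; the tests accept either neighbour.
* **Domain policy.** Absorbance templates refuse evaluation outside
  360–850 nm rather than extrapolating; density templates return exactly 0
  outside their fitted support. Densities are clamped at zero from below —
  the raw fits dip below zero by less than 0.005 near their edges — while
  log absorbances are never clamped.
* **Normalization.** Both energy- and quantal-unit fundamentals are
  rescaled to peak at exactly 1 on the requested output grid (the quantal
  normalization is a package convention added for symmetry; its α is
  recorded alongside the energy α). Because the reference is the grid
  maximum, tabulations at different steps can differ by a small
  renormalization, which matters when comparing tables across grids.
* **Integration.** Tristimulus values use the rectangle rule on the
  uniform CMF grid — the same convention as discrete standard tabulations —
  with the step recorded in the result's metadata. No higher-order
  quadrature is claimed.
* **Matrices.** The packaged RGB→LMS and LMS→XYZ matrices are stored and
  applied digit-for-digit as published (including the structural zeros:
  S-cone response to the red primary, and the z̄ row being a pure scaling
  of s̄); reverse directions use numerical inverses, and transformed CMFs
  are never renormalized after matrix application.
* **Default grid.** 390–830 nm at 1 nm, the standard tabulation range. The
  full 360–850 nm range is available, but the sub-390 nm and supra-830 nm
  template regions are extrapolations constructed to make spectral
  shifting possible and should be used with caution — below 400 nm, lens
  density and fluorescence make any colour-matching prediction uncertain.

## What the tests do and do not show

The test-suite fixtures are generated in code: template evaluations are
checked against an independent term-by-term series summation, peak
positions and anchor densities against their published values, and the
pipeline against closed-form single-point cases and structural invariants
(unit peaks, shift composition, self-screening broadening with invariant
argmax, matrix round trips, chromaticity scale invariance). Comparison
utilities are exercised on package-generated and synthetically degraded
tables at small problem sizes (0.1 nm searches over 360–850 nm, 1 nm
pipeline grids), which run in seconds.

What is *not* covered: agreement with externally tabulated standard
fundamentals is not asserted, because those tables are not bundled;
`read_reference()` and `compare_mae()` are provided so users can run that
comparison against a downloaded tabulation (excluding λ < 400 nm, where
the template extensions deliberately depart from the discrete standard).
Passing tests therefore demonstrate internal correctness of the formulae
and transforms, not field agreement with any particular external dataset.

## Known limitations

* Lens density is a single scalar scaling; the age-dependent change in
  lens spectral *shape* is not modelled.
* Macular pigment is a scalar scaling, not an eccentricity profile; predictions
  for field sizes other than 2 and 10 deg require the user to choose
  appropriate `k_mac` and OD values.
* No S-cone genotype pathway exists (S-cone λ_max variation in the
  population is small, sd ≈ 1.5 nm); S shifts must be given in nm.
* Luminous efficiency, rod and melanopsin spectra are out of scope.
* Template behaviour below 390 nm inherits the uncertainty of the
  short-wavelength extensions; fluorescence of the lens is not modelled.
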