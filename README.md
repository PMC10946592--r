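# conefund

Human colour vision begins with the quantum catches of three cone
photoreceptor classes — the long- (L), middle- (M) and short- (S)
wavelength-sensitive cones. Their corneal spectral sensitivities, the *cone
fundamentals* l̄(λ), m̄(λ), s̄(λ), are the colour-matching functions on which
all colorimetry rests. The standard tabulations are discrete (1- or 5-nm
steps) and describe mean observers only, yet real observers differ: in lens
and macular pigment density, in photopigment optical density, and in
photopigment peak wavelength (λ_max) through opsin gene polymorphisms and
hybrids.

`conefund` generates cone fundamentals as **continuous, closed-form
functions of wavelength** from 360 to 850 nm, for the standard 2-deg and
10-deg observers and for individualized observers, and transforms them into
other colour-matching spaces. It is aimed at vision scientists and colour
engineers who need non-standard observer models, continuous spectra for
arbitrary wavelength grids, or spectrally shifted pigment templates.

## The model

Each log10 photopigment absorbance spectrum is a truncated Fourier series

    log10 Ā(λ) = a0 + Σₖ [ aₖ cos(kθ) + bₖ sin(kθ) ] + s,   k = 1..8

where the angle θ = π·log10(λ/360)/log10(850/360) sweeps 0..π across the
360–850 nm range on a **log-wavelength axis**. On that axis pigment spectra
are approximately shape invariant, so a pigment with a different λ_max is
obtained by pure translation: a shift of Δ log10 nm evaluates the template
at λ·10^(−Δ). The macular and lens pigment density spectra use the same
series form on a linear wavelength axis with a multiplicative
renormalization d (macular: 375–550 nm, 0.350 at 460 nm; lens: 360–660 nm,
1.7649 at 400 nm; zero outside).

Corneal fundamentals follow the standard physiological chain, per cone:

    absorptance:      ā_R(λ) = 1 − 10^(−OD · Ā(λ))            (self-screening)
    corneal quantal:  ā_Q(λ) = ā_R(λ) · 10^−(k_lens·lens(λ) + k_mac·mac(λ))
    energy units:     ā(λ)  = α · λ · ā_Q(λ),  α set so max ā = 1

with peak optical densities OD = (0.50, 0.50, 0.40) for L, M, S at 2 deg
and (0.38, 0.38, 0.30) at 10 deg, k_mac = 1 (2 deg) or 0.271 (10 deg), and
k_lens = 1 for the standard observers. Opsin genotypes (`"M[A285T]"` etc.)
map to λ_max shifts via tabulated per-codon effects; the L-cone ser180 /
ala180 polymorphism is available as dedicated templates 2.7 nm apart.
Exact 3×3 matrices transform LMS into Stiles–Burch RGB and CIE XYZ spaces,
and chromaticity projections give the l,m / r,g / x,y spectrum loci.

## Worked example

```r
library(conefund)

cf <- cone_fundamentals(standard_observer("2deg"))  # energy units, 390-830 @ 1 nm
glance(cf)[, c("field", "units", "n", "peak_L", "peak_M", "peak_S")]
#> # A tibble: 1 × 6
#>   field units      n peak_L peak_M peak_S
#>   <chr> <chr>  <int>  <dbl>  <dbl>  <dbl>
#> 1 2deg  energy   441    569    544    443

tri <- tristimulus(tibble::tibble(wavelength = 550, power = 1), cf)
tri                    # cone excitations of a monochromatic 550-nm light
#> # A tibble: 1 × 3
#>       L     M       S
#>   <dbl> <dbl>   <dbl>
#> 1 0.951 0.990 0.00198
chromaticity(tri)
#> # A tibble: 1 × 2
#>       l     m
#>   <dbl> <dbl>
#> 1 0.489 0.509

genotype_shift_nm("M[A285T]")  # alanine -> threonine at opsin codon 285
#> [1] 14
```

The peaks land where expected: the energy-unit 2-deg fundamentals peak near
569, 544 and 443 nm (energy conversion moves the quantal peaks slightly
longward), and a 550-nm light excites L and M cones almost equally while
barely touching S. An `autoplot()` method draws the three fundamentals;
`tidy()` returns them in long form for further analysis.

A command-line interface wraps the same functions
(`system.file("cli", "conefund", package = "conefund")`):

```sh
conefund generate --field 10 --space xyz --out xyz10.csv
conefund shift-info --genotype M[A285T]
```

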