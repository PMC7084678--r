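# lamellar

Analysis of one-dimensional neutron diffraction from oriented lipid
multilayers: Bragg-peak reduction, structure-factor phasing by D₂O
contrast variation, Fourier reconstruction of the neutron scattering
length density (NSLD) profile across the bilayer, and extraction of the
Luzzati structural parameters with propagated uncertainties.

It is written for membrane biophysicists working with stacked-bilayer
samples — e.g. archaeal-type ether/phytanyl lipids, whose weak ordering
yields only 3–5 Bragg orders — and for anyone who wants a tested,
scriptable replacement for spreadsheet-style diffraction bookkeeping.

## The method in brief

A stack of bilayers is a 1D crystal with repeat `D`; Bragg peaks sit at
`q_n = 2πn/D`. For a centrosymmetric unit cell the NSLD profile is a real
cosine series,

    ρ(z) = (2/D) Σₙ νₙ |fₙ| cos(2πnz/D),   νₙ ∈ {−1, +1},

with `|fₙ| = sqrt(Iₙ qₙᵖ)` from the Lorentz-corrected integrated
intensity of the n-th peak (p = 1 for oriented samples). The signs νₙ are
fixed experimentally: the signed fₙ must be linear in the D₂O fraction of
the hydration water, because only the water SLD changes with contrast.
From the reconstructed profile follow the bilayer thickness `D_B`
(headgroup peak-to-peak distance), the water layer `D_w = D − D_B`, the
area per lipid `A = 2V_l/D_B`, the hydrophobic thickness `2D_c = 2V_c/A`,
and the waters per lipid `n_w = A·D_w/(2V_w)`.

A parametric forward model (Gaussian headgroups + hydrocarbon slab +
methyl trough + water) generates synthetic diffractograms and contrast
series with known ground truth, so the entire chain is validated by
recovery tests. See the methods vignette
(`vignettes/lamellar-methods.Rmd`) for the model, conventions, and design
decisions.

## Worked example

Simulate a noiseless four-contrast series for the default PC-like bilayer
(`D = 50.4 Å`, true `D_B = 37.4 Å`) and run the full chain:

```r
library(lamellar)

m <- bilayer_model()                     # the forward model and its truth
series <- synthesize_contrast_series(m, c(0.08, 0.2, 0.5, 1.0),
                                     acquisition_model(noise_scale = 0))
res <- run_condition(series, run_config(), label = "full hydration")
res$phases
#> <phase_assignment> orders 1, 2, 3, 4  reference x_D2O = 0.08
#>   order 1: -  R2 = 1.0000
#>   order 2: -  R2 = 1.0000
#>   order 3: +  R2 = 1.0000 (ambiguous)
#>   order 4: -  R2 = 1.0000
#>   water boundary estimate: 18.7 A
res
#> <condition_result> full hydration - phase: lamellar
#> <bilayer_parameters> [label=full hydration]
#>   D        50.4 +/- 0.0 A
#>   D_B      37.6 +/- 0.0 A
#>   2D_c     31.5 +/- 0.0 A
#>   D_w      12.8 +/- 0.0 A
#>   A        74.5 +/- 0.0 A^2
#>   n_w      15.9 +/- 0.0
```

Reading the output: the four structure-factor signs come out (−, −, +, −)
— the canonical pattern for a PC-type bilayer near the 8% D₂O water match
point — and the estimated lipid/water boundary (18.7 Å) equals the model's
headgroup position. The lattice constant is recovered exactly; `D_B` is
37.6 Å against a ground truth of 37.4 Å, the ~0.5% bias being the price of
reconstructing from only four Fourier orders. The identity
`D = D_B + D_w` holds exactly. (SEs print as 0.0 here because the scans
are noiseless.)

The same chain works peak by peak if you prefer:
`read_diffractogram()` → `subtract_background()` → `fit_peaks()` →
`index_lattice()` → `lorentz_correct()` → `assign_phases()` →
`reconstruct_nsld()` → `headgroup_peak_to_peak()` /
`bilayer_parameters()`. Non-lamellar scans are recognised by
`index_lattice()`/`classify_phase()` (hexagonal ratios
1 : √3 : 2 : √7, or two interleaved lamellar series for phase
coexistence) and reported lattice-only.

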