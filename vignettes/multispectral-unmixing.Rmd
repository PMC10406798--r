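---
title: "Multispectral absorbance unmixing: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral absorbance unmixing: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specunmix)
```

## The physical and statistical model

The package analyses transmission images of thin sections under
monochromatic illumination. For each band the acquisition records the
scene twice — without the sample (reference) and with it — as a stack of
repeated frames; averaging the stacks and dividing sample by reference
gives per-pixel transmission `T(x, y, λ)`. Under the Beer–Lambert model a
section of thickness `L` containing chromophores with extinction spectra
`ε_j(λ)` at concentrations `C_j(x, y)` transmits

`T = exp(−Σ_j ε_j(λ) C_j(x, y) L)`,

so the absorbance `A = −ln T` is linear in the chromophores. Note the
orientation: transmission is *sample over reference* (so `T ≤ 1` and
`A ≥ 0` up to noise); descriptions of such experiments sometimes state the
division the other way around, which would give `1/T`.

Two assumptions matter. First, attenuation is attributed entirely to
absorption: scattering, wavelength-dependent path length and fluorescence
are not modelled. Second, the reference and sample images are assumed
registered (fixed-stage acquisition); no alignment is performed.

The statistical step is a principal component analysis *in wavelength
space*: pixels are observations and bands are variables. Each band image
is centred by its spatial mean `⟨A(λ)⟩` and the N×N band covariance is
diagonalised. Eigenvectors `e_α(λ)` are wavelength profiles; PC images
`PC_α(x, y)` carry the spatial structure; eigenvalues `Γ_α` are the PC
image variances. Because eigenvectors oscillate around zero they are hard
to read as spectra, so endmembers are constructed as
`E_α = ⟨A⟩ + k √Γ_α e_α` with `k = 2`: a point two standard deviations
out along each principal direction of the pixel cloud, i.e. a spectrum on
the outside of the cloud that can act as a pure signature. Abundances are
then estimated per pixel by non-negative least squares; only
non-negativity is imposed, no sum-to-one closure, since absorbance
amplitudes are not fractions of a whole.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 5 | endmembers kept. The cumulative-variance rule (`m = "auto"`, threshold 99%) is available, but published analyses of this kind conventionally fix `m = 5` even where the 99% rule would choose 4; the pipeline warns when the automatic choice departs from 5. |
| `scale_k` | 2 | multiplier on `√Γ_α`. The value 2 places endmembers at two standard deviations from the mean — motivated geometrically, not optimised; exposed because other radii are equally defensible. |
| `eps_floor` | 1e-6 | lower clip on transmission before the logarithm, bounding absorbance at `−ln(1e-6) ≈ 13.8`. Pixels with `T > 1` (noise) clip to `T = 1`, absorbance 0. |
| `thickness_L` | 5 µm | section thickness in the forward model. |
| `bins` | 50 | abundance-pdf bins, uniform over `[0, max]` with the maximum taken across the compared set so group pdfs share one axis. |
| `abundance_threshold` | 0.2 | cutoff for the high-abundance fraction summary. |

## The synthetic phantom

Every stage is validated on a seeded generator that emulates the
acquisition this package targets: 22 bands from 390 to 705 nm in 15 nm
steps, 50 frames per band, additive Gaussian sensor noise, quantisation to
256 grey levels, and a per-band source intensity that varies smoothly
across the spectrum. Scenes are nested-ellipse "eyes" (cornea, lens,
vitreous, retina, choroid; disjoint regions tiling the eye mask) with five
chromophore components: Gaussian absorption bands, one of them
hemoglobin-like with a strong 420 nm and a secondary 550 nm peak, placed
as blob-shaped "vessels" confined to the vitreous and choroid. A
whole-eye baseline component rises toward the blue and peaks at 420 nm, so
the scene's mean absorbance has its maximum at the planted 420 nm band —
the qualitative spectral landmark the analysis should recover. Group
effects (`control`, `D2`, `D8`) scale the vessel concentration by
1.0/0.6/0.4 and perturb the lens/retina texture component, emulating
reduced vascular signal; eye seeds derive from the base seed and eye index
only, so groups generated with one seed share geometry and differ only by
the effect.

The default frame is 128×128 (desk-scale); the study-scale 640×480 is a
configuration away. What the phantom does *not* emulate: optical blur,
scattering, chromatic aberration, stage drift, or spatially structured
illumination — so passing tests demonstrate the correctness of the
arithmetic and the estimator on Beer–Lambert data, not robustness to those
real-data effects.

Two recovery properties anchor the suite. With the *true* spectra supplied
as endmembers and noise off, the full chain (frames → average → divide →
`−ln` → NNLS) returns `C_j L` to better than 1e-6 per pixel. With
PCA-derived endmembers no such identity holds — constructed endmembers are
not the generating spectra, so abundances are mixtures of the true
concentration maps; tests of the PCA route therefore assert algebraic
invariants and variance concentration (five components ≥ 99% at 1% noise),
not map-level recovery.

## Numerical choices

- **Covariance orientation and normalisation.** The covariance is N×N in
  band space (pixels are the sample), with population normalisation 1/M;
  at M ≈ 3·10⁵ the 1/(M−1) difference is far below other error sources.
  Only this orientation is consistent with eigenvectors indexed by
  wavelength and PC images indexed by pixel.
- **Determinism.** Eigenvector signs are fixed by making the
  largest-magnitude entry positive; exactly tied eigenvalues are ordered
  by the first differing eigenvector entry. Group averaging of
  eigenvectors first aligns each eye's vector to the first eye's by the
  sign of their dot product, since per-eye signs are arbitrary.
- **NNLS.** Solved by the Lawson–Hanson active-set method
  (`pracma::lsqnonneg`); correctness is cross-checked against an
  exhaustive support-enumeration oracle, which is the global optimum by
  construction. Per-pixel problems are independent and solved in a fixed
  order.
- **Masks.** Pixels with a non-positive reference are invalid and are
  excluded from means, covariances, pdfs and unmixing (abundances `NA`),
  rather than being filled.
- **On-disk format.** Cubes are written as 32-bit-float TIFF (one page per
  band, ascending wavelength) with a JSON sidecar carrying wavelengths,
  kind, labels and a scale factor (float TIFF storage is limited to
  [0, 1]); round trips are exact to float32 precision, about 1e-7
  relative.
- **Degenerate inputs.** Empty frame stacks, shape mismatches, band-count
  mismatches, all-zero endmember columns, fully masked images and
  unreachable variance thresholds raise errors rather than propagating
  silently.

## Problem sizes

The test-suite and the reproduction script run at desk scale by choice:
unit fixtures of 6×6 to 16×16 pixels with 3–6 bands, phantom checks at
64×64×22, and the variance-concentration and exact-recovery runs at
128×128×22 with 50 frames per band — large enough for the asymptotics they
test (e.g. the 1/√n noise-averaging law within 20%) while keeping a full
run under a minute per property.

## Known limitations

Endmember construction inherits the orthogonality of the eigenvectors, so
constructed endmembers reflect maximally disjoint structures but need not
correspond one-to-one with physical chromophores; interpreting an
abundance map biologically requires external evidence (e.g. comparing the
endmember against a measured extinction spectrum with
`spectral_similarity()`). Abundances have arbitrary scale (that of the
endmember normalisation), so comparisons are meaningful within one
endmember across groups, not across endmembers. Printed variance tables
from other studies cannot be reproduced from their first five eigenvalues
alone when the published percentages were computed over all N eigenvalues;
`variance_percentages()` normalises over what it is given.
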