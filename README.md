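# specunmix

Multispectral absorbance imaging of thin tissue sections, with PCA-derived
endmember spectra and non-negative least-squares (NNLS) abundance maps.

## The problem

Thin (micrometre-scale) paraffin-embedded tissue sections transmit visible
light in a wavelength-dependent way set by the chromophores they contain
(hemoglobin, pigments, structural proteins). Imaging one section at many
narrow wavelength bands gives a multispectral cube `T(x, y, λ)` of per-pixel
transmission, from which the optical density

    A(x, y, λ) = −ln T(x, y, λ) = Σ_j ε_j(λ) C_j(x, y) L        (Beer–Lambert)

is additive over chromophores `j` with extinction spectra `ε_j(λ)`,
concentration maps `C_j(x, y)` and section thickness `L`. The package is for
researchers who want to localise chromophore-like spectral components in
such sections — e.g. vascular structures in embryonic eye tissue — without
staining, starting from nothing more than per-wavelength grayscale frames.

## The method

1. **Acquisition arithmetic** — repeated frames per band are averaged
   pixel-by-pixel; the averaged sample image is divided by the averaged
   no-sample reference to give transmission, then `A = −ln T`.
2. **Wavelength-space PCA** — each band image is centred by its spatial
   mean `⟨A(λ)⟩`; the N×N band covariance `S` is diagonalised,
   `S e_α = Γ_α e_α`, giving unit eigenvectors `e_α(λ)`, eigenvalues `Γ_α`
   (the variance of each principal-component image) and PC images
   `PC_α(x, y) = Σ_λ e_α(λ) Ā(x, y, λ)`.
3. **Endmember construction** — since `√Γ_α` is the spread of the pixel
   cloud along `e_α`, the spectrum

       E_α(λ) = ⟨A(λ)⟩ + 2 √Γ_α e_α(λ)

   sits on the outside of the cloud and serves as an idealised pure
   signature ("endmember"); the top `m` (default 5) are kept.
4. **Spectral unmixing** — every pixel's spectrum `b` is decomposed as
   `b ≈ U x`, `x ≥ 0`, where `U` holds the endmembers in columns, by
   solving one NNLS problem per pixel. The solutions are the abundance
   maps `Ab_k(x, y)`, summarised by probability density functions and
   threshold-exceedance fractions per sample group.

A fully seeded synthetic phantom (nested-ellipse "eye" scenes, five
Gaussian-band chromophores including a hemoglobin-like 420/550 nm
component, Beer–Lambert mixing, CCD noise, 8-bit quantisation, 50 frames
per band over 22 bands from 390 to 705 nm) provides ground truth for every
stage.

## Worked example

```r
library(specunmix)

ph    <- phantom_spec(shape = c(64, 64), seed = 1)   # 22-band synthetic eye
tc    <- render_transmission_cube(ph)
acube <- transmission_to_absorbance(tc$cube)
fit   <- spectral_unmix(acube, m = 5)                # PCA -> endmembers -> NNLS
summary(fit)
```

```
Endmember unmixing summary (64x64 pixels, 22 bands)

   endmember eigenvalue variance_pct mean_abundance max_abundance
 endmember_1   0.979316      74.1183         0.1460        1.1423
 endmember_2   0.224055      16.9573         0.1854        2.1000
 endmember_3   0.075909       5.7451         0.1133        4.0983
 endmember_4   0.037453       2.8346         0.1264        0.9597
 endmember_5   0.004556       0.3448         0.1037        0.6284

per-pixel residual ||Ux - b||: mean 0.2178, max 1.368
```

The eigenvalue column is the variance of each PC image (absorbance²); the
five components capture 100% of the variance of this noise-free phantom.
Abundance maps (`fit$abundance$maps`) are non-negative per construction;
`plot(fit, "abundance", endmember = 1)` shows where the dominant spectral
component concentrates. Comparing the first endmember with the phantom's
hemoglobin-like extinction spectrum:

```r
spectral_similarity(coef(fit)[, 1], tc$model$epsilon[, 1])
# angle 39.1 deg, correlation 0.68
```

`predict(fit, other_cube)` unmixes further cubes with the same endmembers;
`fitted(fit)` and `residuals(fit)` return the implied absorbance cube and
the per-pixel residual norms.

Whole datasets (3 groups × 9 eyes on disk, TIFF + JSON sidecars) are
simulated and analysed with `pipeline_simulate()` / `pipeline_run()` or the
`exec/specunmix` command-line front-end; results (variance tables,
group-averaged eigenvectors, endmembers, abundance pdfs, run report) land
under `<outdir>/results/`.

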