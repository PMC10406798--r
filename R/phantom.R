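# Synthetic eye-like phantoms: layered ellipse scenes mixed through the
# Beer-Lambert model, with a simulated two-shot (reference/sample) CCD
# acquisition. Everything is driven by an integer seed; identical seeds
# give bit-identical outputs.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

gaussian_band <- function(wl, center, width) exp(-((wl - center)^2) / (2 * width^2))

#' Default chromophore spectra for the phantom
#'
#' Five smooth, linearly independent Gaussian absorption bands. Component 1
#' mimics a hemoglobin-like shape with a strong peak at 420 nm and a
#' secondary band near 550 nm, so that spectra recovered from vessel-rich
#' scenes can be compared against a reference blood-pigment spectrum. Units
#' are absorbance per unit concentration per micrometre.
#'
#' @param wavelengths band-centre wavelengths in nm.
#' @return bands x 5 matrix with named columns.
#' @export
default_component_spectra <- function(wavelengths = seq(390, 705, by = 15)) {
  wl <- as.numeric(wavelengths)
  eps <- cbind(
    hemoglobin_vessels = 0.32 * gaussian_band(wl, 420, 18) +
                         0.13 * gaussian_band(wl, 550, 30),
    lens_fibers        = 0.16 * gaussian_band(wl, 480, 55),
    retina_pigment     = 0.20 * gaussian_band(wl, 600, 45),
    stroma             = 0.12 * gaussian_band(wl, 660, 60),
    matrix_background  = 0.10 * gaussian_band(wl, 420, 90))
  rownames(eps) <- wl
  eps
}

#' Build an eye-like scene of concentration maps
#'
#' Lays out nested elliptical regions -- cornea, lens, vitreous, retina,
#' choroid -- that are disjoint and tile the eye mask, and assigns each of
#' five chromophore components a non-negative concentration map:
#' component 1 ("vessels") as small Gaussian blobs confined to the vitreous
#' and choroid, component 2 in lens and retina, component 3 in retina and
#' cornea, component 4 in choroid and cornea, and component 5 as a weak
#' baseline across the whole eye. The seed controls the geometry jitter
#' (eye centre and axes) and blob placement.
#'
#' @param shape integer pair (rows, columns), at least 64 x 64.
#' @param seed integer seed; fully determines the scene.
#' @param vessel_scale multiplier on the vessel concentration (group
#'   effects scale this down).
#' @param texture_perturb relative amplitude of a periodic perturbation of
#'   the lens/retina texture component (0 = none; must be < 1).
#' @return list with `concentration` (rows x cols x 5 array),
#'   `regions` (integer label matrix: 0 background, 1 cornea, 2 lens,
#'   3 vitreous, 4 retina, 5 choroid), `region_names`,
#'   `component_names`.
#' @export
make_eye_scene <- function(shape, seed = 1L, vessel_scale = 1,
                           texture_perturb = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 64L))
    stop("scene shape must be at least 64 x 64")
  if (texture_perturb < 0 || texture_perturb >= 1)
    stop("texture_perturb must be in [0, 1)")
  R <- shape[1L]; C <- shape[2L]
  with_seed(seed, {
    cy <- R / 2 * (1 + stats::runif(1, -0.03, 0.03))
    cx <- C / 2 * (1 + stats::runif(1, -0.03, 0.03))
    a <- 0.42 * R * stats::runif(1, 0.95, 1.05)
    b <- 0.42 * C * stats::runif(1, 0.95, 1.05)
    yy <- matrix(seq_len(R), R, C)
    xx <- matrix(seq_len(C), R, C, byrow = TRUE)
    rho <- sqrt(((yy - cy) / a)^2 + ((xx - cx) / b)^2)

    regions <- matrix(0L, R, C)
    eye <- rho <= 1
    regions[eye & rho > 0.90] <- 5L                    # choroid (outer ring)
    regions[eye & rho > 0.78 & rho <= 0.90] <- 4L      # retina
    regions[eye & rho <= 0.78] <- 3L                   # vitreous
    # anterior cap: cornea overrides the outer rings at the front
    front <- xx < cx - 0.55 * b
    regions[eye & rho > 0.78 & front] <- 1L
    # lens: anterior ellipse inside the vitreous
    lens <- sqrt(((yy - cy) / (0.26 * a))^2 +
                 ((xx - (cx - 0.38 * b)) / (0.26 * b))^2) <= 1
    regions[lens & regions == 3L] <- 2L

    # smooth deterministic texture so the maps are not piecewise constant
    tex1 <- 0.85 + 0.15 * sin(2 * pi * yy / R) * cos(2 * pi * xx / C)
    tex2 <- 0.85 + 0.15 * cos(3 * pi * yy / R)

    # vessels: Gaussian blobs seeded inside vitreous + choroid, then
    # clipped to that support
    vessel_support <- regions == 3L | regions == 5L
    vessels <- matrix(0, R, C)
    cand <- which(vessel_support)
    n_blob <- 25L
    centers <- sample(cand, n_blob)
    rad <- stats::runif(n_blob, 0.012, 0.028) * min(R, C)
    amp <- stats::runif(n_blob, 0.6, 1.2)
    for (i in seq_len(n_blob)) {
      r0 <- (centers[i] - 1L) %% R + 1L
      c0 <- (centers[i] - 1L) %/% R + 1L
      vessels <- vessels +
        amp[i] * exp(-((yy - r0)^2 + (xx - c0)^2) / (2 * rad[i]^2))
    }
    vessels[!vessel_support] <- 0
    vessels <- vessels * vessel_scale

    lens_retina <- (regions == 2L) * 1.0 + (regions == 4L) * 0.6
    lens_retina <- lens_retina * tex1
    if (texture_perturb > 0)
      lens_retina <- lens_retina *
        (1 + texture_perturb * sin(12 * pi * yy / R) * sin(12 * pi * xx / C))
    retina_cornea <- ((regions == 4L) * 1.0 + (regions == 1L) * 0.5) * tex2
    chor_cornea <- ((regions == 5L) * 1.0 + (regions == 1L) * 0.4) * tex1
    background <- (regions > 0L) * 0.8 * tex2

    conc <- array(0, c(R, C, 5L))
    conc[, , 1L] <- vessels
    conc[, , 2L] <- lens_retina
    conc[, , 3L] <- retina_cornea
    conc[, , 4L] <- chor_cornea
    conc[, , 5L] <- background
    list(concentration = conc, regions = regions,
         region_names = c("cornea", "lens", "vitreous", "retina", "choroid"),
         component_names = colnames(default_component_spectra()))
  })
}

#' Specify a synthetic multispectral phantom
#'
#' Bundles everything needed to generate a synthetic acquisition: frame
#' shape, wavelength grid (default 22 bands, 390-705 nm in 15 nm steps),
#' component spectra and concentration maps, section thickness (default
#' 5 um), the CCD noise level, the number of repeated frames per band
#' (default 50), the quantisation depth (default 256 grey levels; use
#' `Inf` to disable quantisation) and the seed.
#'
#' @param shape integer pair (rows, columns); default 128 x 128 keeps
#'   desk-scale runs fast, the study-scale 640 x 480 is available by
#'   configuration.
#' @param wavelengths band-centre wavelengths in nm.
#' @param components optional list with `epsilon` (bands x n matrix) and
#'   `concentration` (rows x cols x n array); defaults to
#'   [default_component_spectra()] on a [make_eye_scene()] scene.
#' @param thickness_L section thickness in um.
#' @param noise_sigma additive Gaussian intensity-noise standard deviation
#'   in grey levels (applied per frame before quantisation).
#' @param n_frames repeated frames per band.
#' @param levels quantisation levels (`Inf` = none).
#' @param seed integer seed; fully determines the phantom and its
#'   simulated acquisition.
#' @param vessel_scale,texture_perturb passed to [make_eye_scene()] when
#'   the default scene is used (group effects).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         wavelengths = seq(390, 705, by = 15),
                         components = NULL, thickness_L = 5,
                         noise_sigma = 0, n_frames = 50L, levels = 256L,
                         seed = 1L, vessel_scale = 1, texture_perturb = 0) {
  check_wavelength_grid(wavelengths)
  if (is.null(components)) {
    scene <- make_eye_scene(shape, seed = seed, vessel_scale = vessel_scale,
                            texture_perturb = texture_perturb)
    components <- list(epsilon = default_component_spectra(wavelengths),
                       concentration = scene$concentration,
                       regions = scene$regions,
                       names = scene$component_names)
  }
  if (any(components$epsilon < 0) || any(components$concentration < 0))
    stop("component spectra and concentrations must be >= 0")
  if (nrow(components$epsilon) != length(wavelengths))
    stop("epsilon rows must match the wavelength grid")
  if (!identical(dim(components$concentration)[1:2], as.integer(shape)))
    stop("concentration maps do not match the frame shape")
  if (thickness_L <= 0) stop("thickness_L must be > 0")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  # tunable-source intensity profile, in grey levels per band
  lv <- if (is.finite(levels)) levels else 256
  wl <- as.numeric(wavelengths)
  base_intensity <- lv * (0.50 + 0.25 * sin(pi * (wl - min(wl)) /
                                              max(diff(range(wl)), 1)))
  structure(list(shape = as.integer(shape), wavelengths = wl,
                 components = components, thickness_L = thickness_L,
                 noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
                 levels = levels, seed = as.integer(seed),
                 base_intensity = base_intensity),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$shape[1L], "x", x$shape[2L], " pixels, ",
      length(x$wavelengths), " bands, ", ncol(x$components$epsilon),
      " components, L = ", x$thickness_L, " um\n", sep = "")
  cat("  acquisition: ", x$n_frames, " frames/band, noise sd ",
      x$noise_sigma, ", ", x$levels, " levels, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Render the noise-free transmission cube of a phantom
#'
#' Applies the Beer-Lambert forward model to the phantom's concentration
#' maps: `T = exp(-sum_j epsilon_j C_j L)`, together with the ground truth
#' an unmixing run should recover.
#'
#' @param spec a [phantom_spec()].
#' @return list with `cube` (transmission [spectral_cube()]), `model` (the
#'   [chromophore_model()]) and `truth`: `concentration`, `epsilon`,
#'   `absorbance` (rows x cols x bands array of `sum_j eps_j C_j L`) and
#'   `abundance` (rows x cols x n array of `C_j * L`, the coefficients an
#'   exact unmixing against the true spectra returns).
#' @export
render_transmission_cube <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  model <- chromophore_model(spec$components$epsilon, spec$wavelengths,
                             thickness_L = spec$thickness_L)
  cube <- beer_lambert_transmission(model, spec$components$concentration)
  d <- dim(spec$components$concentration)
  Cf <- matrix(spec$components$concentration, d[1L] * d[2L], d[3L])
  A <- Cf %*% t(model$epsilon) * model$thickness_L
  list(cube = cube, model = model,
       truth = list(concentration = spec$components$concentration,
                    epsilon = model$epsilon,
                    absorbance = array(A, c(d[1L], d[2L], nrow(model$epsilon))),
                    abundance = spec$components$concentration * spec$thickness_L))
}

quantize_frames <- function(x, levels) {
  if (!is.finite(levels)) return(x)
  pmin(pmax(round(x), 0), levels - 1)
}

#' Simulate the two-shot CCD acquisition of a phantom
#'
#' For every band, `n_frames` reference frames are generated as the flat
#' source intensity at that wavelength plus additive Gaussian sensor
#' noise, and `n_frames` sample frames as the reference intensity times
#' the phantom's transmission plus noise; both are then quantised to the
#' configured grey levels (skipped when `levels = Inf`). Fully seeded:
#' the same spec yields bit-identical stacks.
#'
#' @param spec a [phantom_spec()].
#' @param tcube the phantom's transmission cube (defaults to rendering it
#'   from `spec`).
#' @return list with `reference` and `sample` (lists over bands of
#'   rows x cols x n_frames arrays), `wavelengths`, `levels`.
#' @export
simulate_acquisition <- function(spec, tcube = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(tcube)) tcube <- render_transmission_cube(spec)$cube
  stopifnot(inherits(tcube, "spectral_cube"))
  if (is.finite(spec$levels) && any(spec$base_intensity >= spec$levels))
    stop("intensity scale saturates the detector")
  R <- spec$shape[1L]; C <- spec$shape[2L]
  nf <- spec$n_frames
  N <- length(spec$wavelengths)
  refs <- vector("list", N); samps <- vector("list", N)
  with_seed(spec$seed + 1L, {
    for (b in seq_len(N)) {
      i0 <- spec$base_intensity[b]
      noise_r <- if (spec$noise_sigma > 0)
        stats::rnorm(R * C * nf, sd = spec$noise_sigma) else 0
      refs[[b]] <- quantize_frames(array(i0 + noise_r, c(R, C, nf)),
                                   spec$levels)
      s0 <- i0 * tcube$data[, , b]
      noise_s <- if (spec$noise_sigma > 0)
        stats::rnorm(R * C * nf, sd = spec$noise_sigma) else 0
      samps[[b]] <- quantize_frames(array(rep(s0, nf) + noise_s, c(R, C, nf)),
                                    spec$levels)
    }
  })
  list(reference = refs, sample = samps, wavelengths = spec$wavelengths,
       levels = spec$levels)
}

#' Recover a transmission cube from a simulated (or real) acquisition
#'
#' Per band, the repeated reference and sample frames are averaged
#' pixel-by-pixel and the averaged sample is divided by the averaged
#' reference; per-band validity masks are combined (a pixel must be valid
#' in every band).
#'
#' @param acq acquisition as returned by [simulate_acquisition()]: lists
#'   `reference` and `sample` of per-band frame stacks plus
#'   `wavelengths`.
#' @param eps_floor transmission clipping floor (see
#'   [compute_transmission()]).
#' @param group,individual labels for the resulting cube.
#' @return a transmission [spectral_cube()].
#' @export
acquisition_to_transmission <- function(acq, eps_floor = 1e-6,
                                        group = NA_character_,
                                        individual = NA) {
  N <- length(acq$reference)
  if (N == 0L || N != length(acq$sample))
    stop("acquisition must hold matching reference and sample stacks")
  imgs <- vector("list", N)
  mask <- NULL
  for (b in seq_len(N)) {
    tr <- compute_transmission(average_frames(acq$sample[[b]]),
                               average_frames(acq$reference[[b]]),
                               eps_floor = eps_floor)
    imgs[[b]] <- tr$transmission
    mask <- if (is.null(mask)) tr$mask else mask & tr$mask
  }
  build_cube(imgs, acq$wavelengths, kind = "transmission",
             group = group, individual = individual, mask = mask)
}

#' Generate a group of phantom eyes
#'
#' Emulates a study arm: `n_eyes` phantoms with per-eye geometry jitter.
#' The control group uses the base concentrations; treatment arms scale the
#' vessel component down by a configured factor (emulating reduced vascular
#' signal, most visibly in the vitreous) and perturb the lens/retina
#' texture component. Eye seeds are derived from `seed` and the eye index
#' only, so calling the three groups with the same `seed` yields paired
#' geometries differing only by the group effect.
#'
#' @param group `"control"`, `"D2"` or `"D8"`.
#' @param n_eyes eyes per group (default 9).
#' @param shape,wavelengths,thickness_L,noise_sigma,n_frames,levels
#'   passed to [phantom_spec()].
#' @param seed integer base seed.
#' @param vessel_factors named vessel-concentration multipliers per group.
#' @param texture_perturbs named texture-perturbation amplitudes per
#'   group.
#' @return list of eyes; each eye is a list with `spec`, `cube` (labelled
#'   noise-free transmission cube) and `truth` (see
#'   [render_transmission_cube()]).
#' @export
generate_group <- function(group = c("control", "D2", "D8"), n_eyes = 9L,
                           shape = c(128L, 128L),
                           wavelengths = seq(390, 705, by = 15),
                           thickness_L = 5, noise_sigma = 0, n_frames = 50L,
                           levels = 256L, seed = 1L,
                           vessel_factors = c(control = 1, D2 = 0.6, D8 = 0.4),
                           texture_perturbs = c(control = 0, D2 = 0.15, D8 = 0.3)) {
  group <- match.arg(group)
  if (n_eyes < 1L) stop("n_eyes must be >= 1")
  lapply(seq_len(n_eyes), function(e) {
    eye_seed <- as.integer(seed) * 1000L + e
    sp <- phantom_spec(shape = shape, wavelengths = wavelengths,
                       thickness_L = thickness_L, noise_sigma = noise_sigma,
                       n_frames = n_frames, levels = levels, seed = eye_seed,
                       vessel_scale = unname(vessel_factors[group]),
                       texture_perturb = unname(texture_perturbs[group]))
    rend <- render_transmission_cube(sp)
    cube <- rend$cube
    cube$group <- group
    cube$individual <- e
    list(spec = sp, cube = cube, truth = rend$truth)
  })
}
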