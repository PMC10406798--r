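#' Per-pixel transmission from sample and reference intensity images
#'
#' Transmission is the ratio of light intensity through the sample to the
#' intensity recorded without the sample at the same wavelength,
#' `T = sample / reference`. Pixels where the reference is not positive
#' carry no information and are masked invalid rather than propagating
#' infinities. Before any logarithm downstream, T is clipped to
#' `(eps_floor, 1]`: noise can make a sample pixel brighter than the
#' reference, which would give a negative absorbance, so such pixels are
#' clipped to T = 1 (absorbance 0); the floor bounds the absorbance from
#' above.
#'
#' @param sample_img,reference_img numeric matrices of the same shape, in
#'   the same (arbitrary) intensity units.
#' @param eps_floor lower clipping bound for T (default `1e-6`).
#' @return list with components `transmission` (matrix) and `mask` (logical
#'   matrix, `TRUE` = valid).
#' @export
compute_transmission <- function(sample_img, reference_img, eps_floor = 1e-6) {
  if (!identical(dim(sample_img), dim(reference_img)))
    stop("sample and reference images have different shapes")
  mask <- is.finite(reference_img) & reference_img > 0 & is.finite(sample_img)
  tr <- matrix(1, nrow(sample_img), ncol(sample_img))
  tr[mask] <- sample_img[mask] / reference_img[mask]
  tr[mask] <- pmin(1, pmax(eps_floor, tr[mask]))
  if (!any(mask)) stop("transmission image is fully masked (no valid reference pixels)")
  list(transmission = tr, mask = mask)
}

#' Convert a transmission cube to absorbance
#'
#' Absorbance (optical density) is `A = -ln(T)` per pixel and band. Under
#' the Beer-Lambert model it is additive over chromophores:
#' `A(x, y, lambda) = sum_j epsilon_j(lambda) * C_j(x, y) * L`.
#' The validity mask is carried over unchanged.
#'
#' @param tcube a [spectral_cube()] of kind `"transmission"`.
#' @return a [spectral_cube()] of kind `"absorbance"`.
#' @export
transmission_to_absorbance <- function(tcube) {
  stopifnot(inherits(tcube, "spectral_cube"))
  if (tcube$kind != "transmission")
    stop("input cube has kind '", tcube$kind, "', expected 'transmission'")
  a <- -log(tcube$data)
  a[array(!tcube$mask, dim(a))] <- 0
  spectral_cube(a, tcube$wavelengths, kind = "absorbance",
                group = tcube$group, individual = tcube$individual,
                mask = tcube$mask)
}

#' Chromophore absorption model
#'
#' Holds the per-band absorption coefficients of `n` tissue components and
#' the section thickness of the Beer-Lambert forward model.
#'
#' @param epsilon numeric matrix, bands x components, of absorption
#'   coefficients per unit concentration and per micrometre of path
#'   (elementwise >= 0). Column names are used as component names.
#' @param wavelengths band-centre wavelengths in nm, one per row of
#'   `epsilon`.
#' @param thickness_L section thickness in micrometres (> 0); paraffin
#'   sections in this workflow are 5 um thick.
#' @return object of class `chromophore_model`.
#' @export
chromophore_model <- function(epsilon, wavelengths, thickness_L = 5) {
  epsilon <- as.matrix(epsilon)
  check_wavelength_grid(wavelengths)
  if (nrow(epsilon) != length(wavelengths))
    stop("epsilon must have one row per wavelength")
  if (any(!is.finite(epsilon)) || any(epsilon < 0))
    stop("absorption coefficients must be finite and >= 0")
  if (!is.finite(thickness_L) || thickness_L <= 0)
    stop("thickness_L must be > 0")
  if (is.null(colnames(epsilon)))
    colnames(epsilon) <- paste0("component_", seq_len(ncol(epsilon)))
  structure(list(epsilon = epsilon, wavelengths = as.numeric(wavelengths),
                 thickness_L = thickness_L, n_components = ncol(epsilon)),
            class = "chromophore_model")
}

#' @export
print.chromophore_model <- function(x, ...) {
  cat("<chromophore_model> ", x$n_components, " components x ",
      nrow(x$epsilon), " bands, L = ", x$thickness_L, " um\n", sep = "")
  cat("  components:", paste(colnames(x$epsilon), collapse = ", "), "\n")
  invisible(x)
}

#' Beer-Lambert forward model: concentrations to transmission
#'
#' Computes `T(x, y, lambda) = exp(-sum_j epsilon_j(lambda) C_j(x, y) L)`,
#' so that the corresponding absorbance is exactly the linear mixture
#' `sum_j epsilon_j C_j L`.
#'
#' @param model a [chromophore_model()].
#' @param conc concentration maps: a 3-D array (rows, columns, components)
#'   or list of matrices, elementwise >= 0, one map per model component.
#' @inheritParams spectral_cube
#' @return a [spectral_cube()] of kind `"transmission"` with values in
#'   (0, 1].
#' @export
beer_lambert_transmission <- function(model, conc, group = NA_character_,
                                      individual = NA) {
  stopifnot(inherits(model, "chromophore_model"))
  if (is.list(conc) && !is.array(conc)) {
    conc <- array(unlist(conc, use.names = FALSE),
                  c(dim(conc[[1L]]), length(conc)))
  }
  if (length(dim(conc)) != 3L || dim(conc)[3L] != model$n_components)
    stop("concentration maps do not match the model's component count")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  d <- dim(conc)
  N <- nrow(model$epsilon)
  # absorbance = C_flat (pixels x comps) %*% t(epsilon) (comps x bands) * L
  Cf <- matrix(conc, d[1L] * d[2L], d[3L])
  A <- Cf %*% t(model$epsilon) * model$thickness_L
  spectral_cube(array(exp(-A), c(d[1L], d[2L], N)), model$wavelengths,
                kind = "transmission", group = group, individual = individual)
}

#' Mean absorbance spectrum of a cube
#'
#' The per-band spatial mean over valid pixels; the spectrum removed when
#' centering a cube for PCA, and the quantity averaged across eyes in the
#' group absorbance report.
#'
#' @param acube a [spectral_cube()] of kind `"absorbance"`.
#' @return named numeric vector, one mean per band (names = wavelengths).
#' @export
mean_absorbance <- function(acube) {
  stopifnot(inherits(acube, "spectral_cube"))
  if (acube$kind != "absorbance")
    stop("input cube has kind '", acube$kind, "', expected 'absorbance'")
  cm <- cube_matrix(acube)
  if (nrow(cm$X) == 0L) stop("no valid pixels")
  m <- colMeans(cm$X)
  names(m) <- acube$wavelengths
  m
}
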