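#' Remove the per-band spatial mean from an absorbance cube
#'
#' Each band image is shifted to zero mean over valid pixels; the removed
#' spectrum is returned alongside. Adding the mean spectrum back recovers
#' the input exactly.
#'
#' @param acube a [spectral_cube()] of kind `"absorbance"`.
#' @return list with components `cube` (centered cube, kind `"absorbance"`)
#'   and `mean_spectrum` (numeric vector).
#' @export
center_by_band_mean <- function(acube) {
  mu <- mean_absorbance(acube)
  d <- dim(acube$data)
  centered <- acube$data - rep(mu, each = d[1L] * d[2L])
  centered[array(!acube$mask, d)] <- 0
  out <- spectral_cube(centered, acube$wavelengths, kind = "absorbance",
                       group = acube$group, individual = acube$individual,
                       mask = acube$mask)
  list(cube = out, mean_spectrum = mu)
}

#' Band-space covariance matrix of a centered cube
#'
#' With M valid pixels and N bands, the N x N covariance is
#' `S[l, l'] = (1/M) * sum_pixels Abar(x, l) * Abar(x, l')` — the
#' population (1/M) normalisation; at the typical M of ~3e5 pixels the
#' difference from 1/(M-1) is negligible.
#'
#' @param centered a centered absorbance cube (see
#'   [center_by_band_mean()]).
#' @return symmetric positive semidefinite N x N matrix.
#' @export
band_covariance <- function(centered) {
  stopifnot(inherits(centered, "spectral_cube"))
  cm <- cube_matrix(centered)
  if (nrow(cm$X) == 0L) stop("no valid pixels")
  crossprod(cm$X) / nrow(cm$X)
}

#' Eigendecomposition of a band covariance matrix
#'
#' Solves `S e_a = Gamma_a e_a` for a symmetric PSD matrix. Eigenvalues are
#' returned in descending order (tiny negative values from round-off are
#' clamped to 0) and eigenvectors as unit-norm columns under a
#' deterministic sign convention: each column is flipped so its
#' largest-magnitude entry is positive. Exactly tied eigenvalues are
#' ordered by the first differing eigenvector entry after the sign fix.
#'
#' @param S symmetric numeric matrix.
#' @param tol asymmetry tolerance relative to `max(abs(S))`.
#' @return list with `values` (numeric vector) and `vectors` (matrix,
#'   eigenvectors in columns).
#' @export
eigendecompose <- function(S, tol = 1e-8) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("S must be square")
  asym <- max(abs(S - t(S)))
  if (asym > tol * max(1, max(abs(S))))
    stop("S is not symmetric (max asymmetry ", format(asym), ")")
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- fix_eigenvector_signs(e$vectors)
  # deterministic order among exact ties
  if (anyDuplicated(vals)) {
    for (v in unique(vals[duplicated(vals)])) {
      grp <- which(vals == v)
      ord <- do.call(order, as.data.frame(t(-vecs[, grp, drop = FALSE])))
      vecs[, grp] <- vecs[, grp[ord]]
    }
  }
  list(values = vals, vectors = vecs)
}

fix_eigenvector_signs <- function(vecs) {
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  vecs
}

#' Principal-component images of a centered cube
#'
#' Each PC image is the eigenvector-weighted combination of the centered
#' band images, `PC_a(x, y) = sum_l e[l, a] * Abar(x, y, l)`. PC images are
#' zero-mean and pairwise uncorrelated, and the spatial variance of
#' `PC_a` equals the eigenvalue `Gamma_a`.
#'
#' @param centered a centered absorbance cube.
#' @param eigenvectors bands x components matrix of unit-norm eigenvectors.
#' @return 3-D array (rows, columns, components); masked pixels are `NA`.
#' @export
compute_principal_components <- function(centered, eigenvectors) {
  stopifnot(inherits(centered, "spectral_cube"))
  eigenvectors <- as.matrix(eigenvectors)
  d <- dim(centered$data)
  if (nrow(eigenvectors) != d[3L])
    stop("eigenvector rows (", nrow(eigenvectors),
         ") do not match band count (", d[3L], ")")
  X <- matrix(centered$data, d[1L] * d[2L], d[3L])
  P <- X %*% eigenvectors
  P[!c(centered$mask), ] <- NA_real_
  array(P, c(d[1L], d[2L], ncol(eigenvectors)))
}

#' Reconstruct an absorbance cube from its principal components
#'
#' Inverts the PC expansion: `Abar(x, y, l) = sum_a e[l, a] * PC_a(x, y)`,
#' then adds the mean spectrum back. With all components this is an exact
#' round trip; with the top m only, the omitted variance equals the sum of
#' the trailing eigenvalues.
#'
#' @param pcs 3-D array of PC images (rows, columns, components).
#' @param eigenvectors bands x components matrix (same components as
#'   `pcs`).
#' @param mean_spectrum numeric vector of per-band means to add back.
#' @param wavelengths band wavelengths for the output cube.
#' @param mask optional validity mask.
#' @return a [spectral_cube()] of kind `"absorbance"`.
#' @export
reconstruct_cube <- function(pcs, eigenvectors, mean_spectrum, wavelengths,
                             mask = NULL) {
  eigenvectors <- as.matrix(eigenvectors)
  if (length(mean_spectrum) != nrow(eigenvectors))
    stop("mean_spectrum length does not match eigenvector rows")
  d <- dim(pcs)
  if (length(d) == 2L) { d <- c(d, 1L); pcs <- array(pcs, d) }
  if (d[3L] != ncol(eigenvectors))
    stop("component count mismatch between pcs and eigenvectors")
  P <- matrix(pcs, d[1L] * d[2L], d[3L])
  P[is.na(P)] <- 0
  A <- P %*% t(eigenvectors)
  A <- A + rep(mean_spectrum, each = d[1L] * d[2L])
  spectral_cube(array(A, c(d[1L], d[2L], nrow(eigenvectors))), wavelengths,
                kind = "absorbance", mask = mask)
}

#' Percentage of total variance per eigenvalue
#'
#' @param eigenvalues non-negative eigenvalues, not all zero.
#' @return numeric vector summing to 100.
#' @export
variance_percentages <- function(eigenvalues) {
  if (any(eigenvalues < 0)) stop("eigenvalues must be >= 0")
  tot <- sum(eigenvalues)
  if (tot == 0) stop("all eigenvalues are zero")
  100 * eigenvalues / tot
}

#' Choose how many principal components to keep
#'
#' Either a fixed count, or the smallest m whose cumulative variance
#' percentage reaches a threshold. Analyses of this kind in the literature
#' often fix m = 5 even when a 99% rule would select fewer, so the fixed
#' override is the default entry point in the pipeline.
#'
#' @param percentages per-component variance percentages, descending.
#' @param threshold_pct cumulative-variance threshold in (0, 100].
#' @param fixed_m if given, returned as-is (override).
#' @return integer component count m.
#' @export
select_num_components <- function(percentages, threshold_pct = 99,
                                  fixed_m = NULL) {
  if (!is.null(fixed_m)) return(as.integer(fixed_m))
  if (threshold_pct <= 0 || threshold_pct > 100)
    stop("threshold_pct must be in (0, 100]")
  cum <- cumsum(percentages)
  m <- which(cum >= threshold_pct - 1e-12)[1L]
  if (is.na(m)) stop("cumulative variance never reaches ", threshold_pct, "%")
  as.integer(m)
}

#' PCA of an absorbance cube in wavelength space
#'
#' Centers each band image, forms the band-space covariance, diagonalises
#' it and projects the cube onto the eigenvectors. Returns the full
#' decomposition: mean spectrum, eigenvalues (variances of the PC images),
#' orthonormal eigenvectors indexed by wavelength, PC images and variance
#' percentages.
#'
#' @param acube a [spectral_cube()] of kind `"absorbance"` with at least
#'   two bands.
#' @return object of class `spectral_pca` with fields `mean_spectrum`,
#'   `eigenvalues`, `eigenvectors`, `pcs`, `variance_pct`, `wavelengths`,
#'   `mask`, `group`, `individual`.
#' @export
spectral_pca <- function(acube) {
  stopifnot(inherits(acube, "spectral_cube"))
  if (n_bands(acube) < 2L) stop("PCA needs at least 2 bands")
  ctr <- center_by_band_mean(acube)
  S <- band_covariance(ctr$cube)
  e <- eigendecompose(S)
  pcs <- compute_principal_components(ctr$cube, e$vectors)
  structure(
    list(mean_spectrum = ctr$mean_spectrum, eigenvalues = e$values,
         eigenvectors = e$vectors, pcs = pcs,
         variance_pct = variance_percentages(e$values),
         wavelengths = acube$wavelengths, mask = acube$mask,
         group = acube$group, individual = acube$individual),
    class = "spectral_pca")
}

#' @export
print.spectral_pca <- function(x, ...) {
  N <- length(x$eigenvalues)
  cat("<spectral_pca> ", N, " bands (", min(x$wavelengths), "-",
      max(x$wavelengths), " nm)\n", sep = "")
  k <- min(5L, N)
  cat("  top eigenvalues:", paste(signif(x$eigenvalues[1:k], 3), collapse = ", "), "\n")
  cat("  variance %:     ", paste(sprintf("%.2f", x$variance_pct[1:k]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.spectral_pca <- function(object, n = 10L, ...) {
  n <- min(n, length(object$eigenvalues))
  data.frame(component = seq_len(n),
             eigenvalue = object$eigenvalues[1:n],
             variance_pct = object$variance_pct[1:n],
             cumulative_pct = cumsum(object$variance_pct)[1:n])
}

#' @export
plot.spectral_pca <- function(x, components = 1:min(5L, ncol(x$eigenvectors)),
                              ...) {
  graphics::matplot(x$wavelengths, x$eigenvectors[, components, drop = FALSE],
                    type = "l", lty = 1, xlab = "wavelength (nm)",
                    ylab = "eigenvector weight", ...)
  graphics::legend("topright", legend = paste0("e", components),
                   col = seq_along(components), lty = 1, bty = "n")
  invisible(x)
}

#' Average one eigenvector across the eyes of a group
#'
#' Eigenvector signs are arbitrary per decomposition, so before averaging
#' each eye's vector is aligned to the first eye's (flipped when their dot
#' product is negative). Returns the per-band mean and standard deviation
#' (the error bars of a group eigenvector plot).
#'
#' @param decomps list of [spectral_pca()] objects (or lists with an
#'   `eigenvectors` matrix and `wavelengths`), all on the same wavelength
#'   grid.
#' @param alpha which component to average (1 = largest eigenvalue).
#' @return list with `mean`, `sd` (numeric vectors per band) and
#'   `wavelengths`.
#' @export
group_average_eigenvectors <- function(decomps, alpha = 1L) {
  if (length(decomps) == 0L) stop("empty decomposition list")
  wl <- decomps[[1L]]$wavelengths
  V <- sapply(decomps, function(d) {
    if (!isTRUE(all.equal(d$wavelengths, wl)))
      stop("decompositions are on different wavelength grids")
    d$eigenvectors[, alpha]
  })
  V <- as.matrix(V)
  ref <- V[, 1L]
  for (j in seq_len(ncol(V)))
    if (sum(V[, j] * ref) < 0) V[, j] <- -V[, j]
  sdv <- if (ncol(V) > 1L) apply(V, 1L, stats::sd) else rep(0, nrow(V))
  list(mean = rowMeans(V), sd = sdv, wavelengths = wl)
}
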