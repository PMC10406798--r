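#' Construct endmember spectra from a PCA decomposition
#'
#' In the scatter cloud of pixel spectra, the eigenvectors of the band
#' covariance mark the principal directions and `sqrt(Gamma_a)` the spread
#' of the cloud along each. A spectrum placed two standard deviations out
#' from the mean along direction a,
#' `E_a(lambda) = <A(lambda)> + scale_k * sqrt(Gamma_a) * e_a(lambda)`,
#' lies on the outside of the cloud and serves as an idealised pure
#' signature (endmember). Components are taken in descending-eigenvalue
#' order, so endmember 1 reflects the dominant spectral structure.
#'
#' Endmembers built this way can carry negative entries; they are not
#' clipped by default since the non-negativity constraint of the unmixing
#' applies to abundances, not spectra. Set `clip_negative = TRUE` for
#' physically interpretable (non-negative) spectra.
#'
#' @param decomp a [spectral_pca()] object, or any list with
#'   `mean_spectrum`, `eigenvalues`, `eigenvectors` (and optionally
#'   `wavelengths`).
#' @param m number of endmembers (default 5, at most the number of
#'   components available).
#' @param scale_k positive multiplier on `sqrt(Gamma_a)` (default 2).
#' @param clip_negative clip negative endmember entries to zero.
#' @return object of class `endmember_set`: fields `spectra` (bands x m
#'   matrix), `wavelengths`, `scale_k`, `source`.
#' @export
construct_endmembers <- function(decomp, m = 5L, scale_k = 2,
                                 clip_negative = FALSE) {
  if (!is.numeric(scale_k) || length(scale_k) != 1L || scale_k <= 0)
    stop("scale_k must be a positive number")
  E <- as.matrix(decomp$eigenvectors)
  if (m < 1L || m > ncol(E))
    stop("m = ", m, " exceeds the ", ncol(E), " available components")
  mu <- as.numeric(decomp$mean_spectrum)
  U <- sapply(seq_len(m), function(k)
    mu + scale_k * sqrt(decomp$eigenvalues[k]) * E[, k])
  U <- matrix(U, nrow = length(mu))
  if (clip_negative) U <- pmax(U, 0)
  colnames(U) <- paste0("endmember_", seq_len(m))
  endmember_set(U,
                wavelengths = if (!is.null(decomp$wavelengths))
                  decomp$wavelengths else seq_len(length(mu)),
                scale_k = scale_k, source = "pca-derived")
}

#' Bundle endmember spectra
#'
#' @param spectra bands x m numeric matrix, one endmember per column; all
#'   entries finite, no all-zero column, and at least as many bands as
#'   endmembers (an underdetermined unmixing is refused).
#' @param wavelengths band wavelengths in nm.
#' @param scale_k the multiplier used in the construction (`NA` for
#'   user-supplied spectra).
#' @param source provenance tag, `"pca-derived"` or `"user-supplied"`.
#' @return object of class `endmember_set`.
#' @export
endmember_set <- function(spectra, wavelengths = seq_len(nrow(spectra)),
                          scale_k = NA_real_,
                          source = c("user-supplied", "pca-derived")) {
  source <- match.arg(source)
  spectra <- as.matrix(spectra)
  if (ncol(spectra) < 1L) stop("need at least one endmember")
  if (nrow(spectra) < ncol(spectra))
    stop("fewer bands (", nrow(spectra), ") than endmembers (", ncol(spectra), ")")
  if (any(!is.finite(spectra))) stop("endmember spectra must be finite")
  if (any(colSums(abs(spectra)) == 0)) stop("all-zero endmember column")
  check_wavelength_grid(wavelengths)
  if (length(wavelengths) != nrow(spectra))
    stop("wavelength grid does not match endmember band count")
  if (is.null(colnames(spectra)))
    colnames(spectra) <- paste0("endmember_", seq_len(ncol(spectra)))
  structure(list(spectra = spectra, wavelengths = as.numeric(wavelengths),
                 scale_k = scale_k, source = source),
            class = "endmember_set")
}

#' @export
print.endmember_set <- function(x, ...) {
  cat("<endmember_set> ", ncol(x$spectra), " endmembers x ", nrow(x$spectra),
      " bands (", x$source, ")", sep = "")
  if (!is.na(x$scale_k)) cat(", scale_k =", x$scale_k)
  cat("\n")
  invisible(x)
}

#' Non-negative least squares
#'
#' Solves `min ||U x - b||_2` subject to `x >= 0` with the Lawson-Hanson
#' active-set algorithm (via [pracma::lsqnonneg()]). At the solution the
#' Karush-Kuhn-Tucker conditions hold: the gradient `U'(Ux - b)` vanishes
#' on the active (positive) components and is non-negative on the rest.
#'
#' @param U numeric N x m matrix, no all-zero column.
#' @param b numeric length-N vector.
#' @return numeric length-m vector `x >= 0`.
#' @seealso [nnls_bruteforce_oracle()] for the exhaustive reference
#'   solution used in validation.
#' @export
nnls_solve <- function(U, b) {
  U <- as.matrix(U)
  if (length(b) != nrow(U)) stop("length(b) must equal nrow(U)")
  if (any(colSums(abs(U)) == 0)) stop("U has an all-zero column")
  pracma::lsqnonneg(U, as.numeric(b))$x
}

#' Exhaustive reference solution of small NNLS problems
#'
#' Enumerates all 2^m support sets, solves the unconstrained least-squares
#' problem restricted to each support via the pseudo-inverse, keeps the
#' candidates that are feasible (non-negative on their support), and
#' returns the feasible candidate with the smallest residual. Since the
#' NNLS optimum is the unconstrained optimum on its own active set, this
#' enumeration is guaranteed to find the global optimum. Exponential in m;
#' refuse m > 10.
#'
#' @inheritParams nnls_solve
#' @return numeric length-m vector `x >= 0`.
#' @export
nnls_bruteforce_oracle <- function(U, b) {
  U <- as.matrix(U)
  m <- ncol(U)
  if (m > 10L) stop("oracle limited to m <= 10 endmembers")
  if (length(b) != nrow(U)) stop("length(b) must equal nrow(U)")
  b <- as.numeric(b)
  best_x <- numeric(m)                     # empty support: x = 0
  best_res <- sum(b^2)
  for (code in seq_len(2^m - 1L)) {
    supp <- which(bitwAnd(code, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    Us <- U[, supp, drop = FALSE]
    xs <- tryCatch(c(pracma::pinv(Us) %*% b), error = function(e) NULL)
    if (is.null(xs) || any(xs < 0)) next
    r <- sum((Us %*% xs - b)^2)
    if (r < best_res - 1e-15) {
      best_res <- r
      best_x <- numeric(m)
      best_x[supp] <- xs
    }
  }
  best_x
}

#' Unmix an absorbance cube into endmember abundances
#'
#' Solves one NNLS system per valid pixel: `U` holds the endmember spectra
#' in columns, `b` the pixel's absorbance spectrum, and the solution is
#' the pixel's abundance vector (all entries >= 0, no sum-to-one
#' constraint). Pixel problems are independent, so the result does not
#' depend on evaluation order. Masked pixels yield `NA` abundances.
#'
#' @param acube a [spectral_cube()] of kind `"absorbance"`.
#' @param endmembers an [endmember_set()] on the same band grid.
#' @return object of class `abundance_maps`: `maps` (rows x columns x m
#'   array), `residual` (rows x columns matrix of per-pixel
#'   `||U x - b||_2`), `endmember_names`, `mask`.
#' @export
unmix_cube <- function(acube, endmembers) {
  stopifnot(inherits(acube, "spectral_cube"),
            inherits(endmembers, "endmember_set"))
  if (acube$kind != "absorbance")
    stop("input cube has kind '", acube$kind, "', expected 'absorbance'")
  U <- endmembers$spectra
  if (n_bands(acube) != nrow(U))
    stop("cube has ", n_bands(acube), " bands but endmembers have ", nrow(U))
  d <- dim(acube$data)
  m <- ncol(U)
  cm <- cube_matrix(acube)
  X <- matrix(NA_real_, d[1L] * d[2L], m)
  res <- matrix(NA_real_, d[1L], d[2L])
  resv <- numeric(nrow(cm$X))
  sol <- matrix(0, nrow(cm$X), m)
  for (i in seq_len(nrow(cm$X))) {
    b <- cm$X[i, ]
    x <- nnls_solve(U, b)
    sol[i, ] <- x
    resv[i] <- sqrt(sum((U %*% x - b)^2))
  }
  X[cm$idx, ] <- sol
  res[cm$idx] <- resv
  structure(list(maps = array(X, c(d[1L], d[2L], m)), residual = res,
                 endmember_names = colnames(U), mask = acube$mask,
                 group = acube$group, individual = acube$individual),
            class = "abundance_maps")
}

#' @export
print.abundance_maps <- function(x, ...) {
  d <- dim(x$maps)
  mu <- apply(x$maps, 3L, mean, na.rm = TRUE)
  cat("<abundance_maps> ", d[1L], "x", d[2L], " pixels, ", d[3L],
      " endmembers\n", sep = "")
  cat("  mean abundance:", paste(signif(mu, 3), collapse = ", "), "\n")
  cat("  mean residual: ", signif(mean(x$residual, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Similarity between two spectra
#'
#' Quantifies how alike two spectra are by the spectral angle
#' `arccos(s1.s2 / (||s1|| ||s2||))` in degrees (0 for proportional
#' spectra, scale-invariant) and by the Pearson correlation of the two
#' series.
#'
#' @param s1,s2 numeric vectors of equal length, nonzero norm.
#' @return list with `angle_deg` and `correlation`.
#' @export
spectral_similarity <- function(s1, s2) {
  if (length(s1) != length(s2)) stop("spectra have different lengths")
  n1 <- sqrt(sum(s1^2)); n2 <- sqrt(sum(s2^2))
  if (n1 == 0 || n2 == 0) stop("zero-norm spectrum")
  cosang <- min(1, max(-1, sum(s1 * s2) / (n1 * n2)))
  list(angle_deg = acos(cosang) * 180 / pi,
       correlation = stats::cor(s1, s2))
}
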