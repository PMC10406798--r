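#' Fit the endmember-unmixing model to an absorbance cube
#'
#' The central estimator of the package. Given an absorbance cube it (1)
#' runs wavelength-space PCA ([spectral_pca()]), (2) constructs `m`
#' endmember spectra from the mean spectrum, eigenvalues and eigenvectors
#' ([construct_endmembers()]), and (3) estimates per-pixel non-negative
#' abundances by NNLS ([unmix_cube()]). Alternatively a fixed
#' [endmember_set()] (e.g. known chromophore spectra) can be supplied, in
#' which case step 2 is skipped (the PCA is still computed for the variance
#' bookkeeping).
#'
#' @param acube a [spectral_cube()] of kind `"absorbance"`.
#' @param m number of endmembers to construct (default 5).
#' @param scale_k multiplier on `sqrt(Gamma_a)` in the endmember
#'   construction (default 2).
#' @param endmembers optional [endmember_set()] to use instead of the
#'   PCA-derived construction.
#' @param keep_pcs keep the PC images in the returned object (they are the
#'   largest part of it; default `TRUE`).
#' @return object of class `spectral_unmix` with fields `pca`,
#'   `endmembers`, `abundance` (an `abundance_maps` object), `wavelengths`,
#'   `dim`, `call`. Methods: `print`, `summary`, `coef` (endmember
#'   spectra), `fitted` (reconstructed absorbance cube), `residuals`
#'   (per-pixel residual norm), `predict` (unmix a new cube with the fitted
#'   endmembers), `plot`.
#' @examples
#' ph <- phantom_spec(shape = c(64, 64), seed = 1)
#' tc <- render_transmission_cube(ph)
#' fit <- spectral_unmix(transmission_to_absorbance(tc$cube), m = 3)
#' summary(fit)
#' @export
spectral_unmix <- function(acube, m = 5L, scale_k = 2, endmembers = NULL,
                           keep_pcs = TRUE) {
  stopifnot(inherits(acube, "spectral_cube"))
  pca <- spectral_pca(acube)
  if (is.null(endmembers)) {
    endmembers <- construct_endmembers(pca, m = m, scale_k = scale_k)
  } else {
    stopifnot(inherits(endmembers, "endmember_set"))
  }
  ab <- unmix_cube(acube, endmembers)
  if (!keep_pcs) pca$pcs <- NULL
  structure(list(pca = pca, endmembers = endmembers, abundance = ab,
                 wavelengths = acube$wavelengths, dim = dim(acube$data),
                 group = acube$group, individual = acube$individual,
                 call = match.call()),
            class = "spectral_unmix")
}

#' @export
print.spectral_unmix <- function(x, ...) {
  cat("Endmember unmixing fit (", x$dim[1L], "x", x$dim[2L], " pixels, ",
      x$dim[3L], " bands)\n", sep = "")
  cat("  endmembers: ", ncol(x$endmembers$spectra), " (",
      x$endmembers$source, ")\n", sep = "")
  k <- min(5L, length(x$pca$variance_pct))
  cat("  top-", k, " variance: ",
      sprintf("%.2f%%", sum(x$pca$variance_pct[1:k])), "\n", sep = "")
  invisible(x)
}

#' @export
summary.spectral_unmix <- function(object, ...) {
  m <- ncol(object$endmembers$spectra)
  ab <- object$abundance
  tab <- data.frame(
    endmember = colnames(object$endmembers$spectra),
    eigenvalue = if (object$endmembers$source == "pca-derived")
      object$pca$eigenvalues[1:m] else NA_real_,
    variance_pct = if (object$endmembers$source == "pca-derived")
      object$pca$variance_pct[1:m] else NA_real_,
    mean_abundance = apply(ab$maps, 3L, mean, na.rm = TRUE),
    max_abundance = apply(ab$maps, 3L, max, na.rm = TRUE))
  out <- list(table = tab,
              mean_residual = mean(ab$residual, na.rm = TRUE),
              max_residual = max(ab$residual, na.rm = TRUE),
              dim = object$dim, scale_k = object$endmembers$scale_k)
  class(out) <- "summary.spectral_unmix"
  out
}

#' @export
print.summary.spectral_unmix <- function(x, ...) {
  cat("Endmember unmixing summary (", x$dim[1L], "x", x$dim[2L], " pixels, ",
      x$dim[3L], " bands)\n\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  cat("\nper-pixel residual ||Ux - b||: mean ", signif(x$mean_residual, 4),
      ", max ", signif(x$max_residual, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.spectral_unmix <- function(object, ...) object$endmembers$spectra

#' @describeIn spectral_unmix reconstructed absorbance cube
#'   `sum_k E_k(lambda) Ab_k(x, y)` implied by the fit.
#' @param object,... method arguments.
#' @export
fitted.spectral_unmix <- function(object, ...) {
  d <- dim(object$abundance$maps)
  Ab <- matrix(object$abundance$maps, d[1L] * d[2L], d[3L])
  Ab[is.na(Ab)] <- 0
  A <- Ab %*% t(object$endmembers$spectra)
  spectral_cube(array(A, c(d[1L], d[2L], nrow(object$endmembers$spectra))),
                object$wavelengths, kind = "absorbance",
                group = object$group, individual = object$individual,
                mask = object$abundance$mask)
}

#' @export
residuals.spectral_unmix <- function(object, ...) object$abundance$residual

#' @export
predict.spectral_unmix <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectral_cube"))
  unmix_cube(newdata, object$endmembers)
}

#' @export
plot.spectral_unmix <- function(x, which = c("endmembers", "abundance"),
                                endmember = 1L, ...) {
  which <- match.arg(which)
  if (which == "endmembers") {
    graphics::matplot(x$wavelengths, x$endmembers$spectra, type = "l",
                      lty = 1, xlab = "wavelength (nm)",
                      ylab = "endmember absorbance", ...)
    graphics::legend("topright", legend = colnames(x$endmembers$spectra),
                     col = seq_len(ncol(x$endmembers$spectra)), lty = 1,
                     bty = "n")
  } else {
    map <- x$abundance$maps[, , endmember]
    graphics::image(t(map[nrow(map):1, ]), axes = FALSE, useRaster = TRUE,
                    col = grDevices::gray.colors(256, 0, 1),
                    main = paste("abundance,",
                                 x$abundance$endmember_names[endmember]), ...)
  }
  invisible(x)
}
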