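#' Construct a multispectral cube
#'
#' A spectral cube is a 3-D array over (row, column, band) holding one image
#' per wavelength band, together with its wavelength grid, a kind tag saying
#' what physical quantity the values are, sample labels, and a validity mask.
#' Bands are always stored in ascending wavelength order with the band axis
#' last.
#'
#' @param data numeric 3-D array, dimensions (rows, columns, bands); all
#'   values must be finite wherever the mask is valid, non-negative for
#'   intensity/transmission kinds, and strictly positive for transmission.
#' @param wavelengths numeric vector of band-centre wavelengths in nm;
#'   strictly increasing, one per band.
#' @param kind one of `"intensity"`, `"transmission"`, `"absorbance"`.
#' @param group,individual optional sample labels (e.g. diet group and eye
#'   id); stored as-is.
#' @param mask logical matrix (rows x columns); `TRUE` marks valid pixels.
#'   Defaults to all valid. Invalid pixels are excluded from every
#'   downstream statistic.
#' @return an object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelengths,
                          kind = c("intensity", "transmission", "absorbance"),
                          group = NA_character_, individual = NA,
                          mask = NULL) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array (rows, columns, bands)")
  wavelengths <- as.numeric(wavelengths)
  check_wavelength_grid(wavelengths)
  if (dim(data)[3L] != length(wavelengths))
    stop("band count (", dim(data)[3L], ") does not match wavelength grid length (",
         length(wavelengths), ")")
  if (is.null(mask)) {
    mask <- matrix(TRUE, dim(data)[1L], dim(data)[2L])
  } else {
    mask <- as.matrix(mask)
    if (!is.logical(mask) || !identical(dim(mask), dim(data)[1:2]))
      stop("'mask' must be a logical matrix matching the image shape")
  }
  valid <- rep(c(mask), times = dim(data)[3L])
  vals <- data[valid]
  if (any(!is.finite(vals)))
    stop("non-finite values in valid pixels of a '", kind, "' cube")
  if (kind == "transmission" && any(vals <= 0))
    stop("transmission values must be > 0 on valid pixels (mask dead pixels instead)")
  if (kind == "intensity" && any(vals < 0))
    stop("intensity values must be >= 0")
  structure(
    list(data = data, wavelengths = wavelengths, kind = kind,
         group = group, individual = individual, mask = mask),
    class = "spectral_cube")
}

check_wavelength_grid <- function(wavelengths) {
  if (length(wavelengths) < 1L || any(!is.finite(wavelengths)))
    stop("wavelength grid must be a non-empty finite numeric vector")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing with no duplicates")
  invisible(wavelengths)
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat("<spectral_cube> ", d[1L], "x", d[2L], " pixels, ", d[3L], " bands (",
      min(x$wavelengths), "-", max(x$wavelengths), " nm), kind = ", x$kind,
      "\n", sep = "")
  if (!is.na(x$group) || !is.na(x$individual))
    cat("  labels: group =", x$group, " individual =", x$individual, "\n")
  nbad <- sum(!x$mask)
  if (nbad > 0L) cat("  masked pixels:", nbad, "\n")
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

#' Number of bands in a cube
#' @param cube a [spectral_cube()].
#' @return integer band count.
#' @export
n_bands <- function(cube) dim(cube$data)[3L]

#' Average repeated frames pixel-by-pixel
#'
#' Repeated frames taken at one wavelength are averaged per pixel to
#' suppress temporal detector noise; the standard error of each averaged
#' pixel shrinks as 1/sqrt(n) for n independent frames. Integer (quantised)
#' frames are promoted to floating point.
#'
#' @param frames a list of numeric matrices of identical shape, or a 3-D
#'   array with frames along the third axis.
#' @return a numeric matrix: the per-pixel arithmetic mean.
#' @export
average_frames <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    if (dim(frames)[3L] == 0L) stop("empty frame stack")
    return(rowMeans(frames, dims = 2L))
  }
  if (!is.list(frames) || length(frames) == 0L) stop("empty frame stack")
  shp <- dim(frames[[1L]])
  if (is.null(shp)) stop("frames must be matrices")
  for (f in frames)
    if (!identical(dim(f), shp)) stop("frames have mismatched shapes")
  acc <- matrix(0, shp[1L], shp[2L])
  for (f in frames) acc <- acc + f
  acc / length(frames)
}

#' Flatten a (row, column) pixel index to a single index
#'
#' Pixels of an R x C detector array are ordered column-major:
#' `k = (c - 1) * R + r` with 1-based `r`, `c` and `k` in `1..R*C`. This is
#' the ordering under which a cube's band images line up with the rows of
#' the pixels-by-bands data matrix used for PCA.
#'
#' @param r,c 1-based row and column indices (vectorised).
#' @param R number of rows of the array.
#' @return integer vector of flat indices `k`.
#' @seealso [unflatten_pixel_index()]
#' @export
flatten_pixel_index <- function(r, c, R) {
  if (any(r < 1L | r > R) || any(c < 1L))
    stop("pixel index out of range")
  as.integer((c - 1L) * R + r)
}

#' Invert the flat pixel index back to (row, column)
#'
#' @param k flat index in `1..R*C` (vectorised).
#' @param R number of rows of the array.
#' @return list with integer components `r` and `c`.
#' @export
unflatten_pixel_index <- function(k, R) {
  if (any(k < 1L)) stop("pixel index out of range")
  list(r = as.integer((k - 1L) %% R + 1L),
       c = as.integer((k - 1L) %/% R + 1L))
}

#' Assemble band images into a spectral cube
#'
#' Bands are re-ordered by ascending wavelength regardless of the order the
#' images are supplied in, so a shuffled acquisition yields the same cube as
#' a sorted one.
#'
#' @param images list of numeric matrices, one per wavelength, all the same
#'   shape.
#' @param wavelengths numeric vector, one wavelength in nm per image (need
#'   not be sorted; no duplicates).
#' @inheritParams spectral_cube
#' @return a [spectral_cube()].
#' @export
build_cube <- function(images, wavelengths,
                       kind = c("intensity", "transmission", "absorbance"),
                       group = NA_character_, individual = NA, mask = NULL) {
  kind <- match.arg(kind)
  if (!is.list(images) || length(images) == 0L) stop("no band images supplied")
  if (length(images) != length(wavelengths))
    stop("got ", length(images), " images for ", length(wavelengths), " wavelengths")
  if (anyDuplicated(wavelengths)) stop("duplicate wavelengths")
  shp <- dim(images[[1L]])
  for (im in images)
    if (!identical(dim(im), shp)) stop("band images have mismatched shapes")
  ord <- order(wavelengths)
  data <- array(0, c(shp, length(images)))
  for (b in seq_along(ord)) data[, , b] <- images[[ord[b]]]
  spectral_cube(data, wavelengths[ord], kind = kind, group = group,
                individual = individual, mask = mask)
}

# Matrix view of a cube: valid pixels (column-major flat order) x bands.
# Returns the matrix plus the flat indices of the valid pixels.
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  X <- matrix(cube$data, d[1L] * d[2L], d[3L])
  keep <- which(c(cube$mask))
  list(X = X[keep, , drop = FALSE], idx = keep, dim = d)
}
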