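#' Write a spectral cube to disk
#'
#' The cube is written as a multi-page 32-bit float TIFF (one page per band,
#' ascending wavelength) or as a directory of per-band TIFFs, always
#' accompanied by a JSON sidecar holding the wavelength grid, kind tag,
#' labels, a value scale and any invalid pixels. TIFF float storage is
#' limited to [0, 1], so values are divided by a `scale` (recorded in the
#' sidecar and re-applied on read); round-trips are exact up to float32
#' precision.
#'
#' @param cube a [spectral_cube()].
#' @param path output path; for `format = "tiff"` the `.tif` file (a
#'   sidecar `.json` with the same stem is written next to it), for
#'   `format = "dir"` a directory.
#' @param format `"tiff"` (multi-page, default) or `"dir"` (one file per
#'   band, `band_001.tif`, ...).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("tiff", "dir")) {
  format <- match.arg(format)
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  vals <- cube$data
  vals[array(!cube$mask, d)] <- 0
  mx <- max(vals)
  scale <- if (is.finite(mx) && mx > 1) mx else 1
  pages <- lapply(seq_len(d[3L]), function(b) vals[, , b] / scale)

  if (format == "tiff") {
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) path <- paste0(path, ".tif")
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    sidecar <- sidecar_path(path)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (b in seq_len(d[3L]))
      tiff::writeTIFF(pages[[b]], file.path(path, sprintf("band_%03d.tif", b)),
                      bits.per.sample = 32L)
    sidecar <- file.path(path, "cube.json")
  }

  meta <- list(wavelengths_nm = cube$wavelengths, kind = cube$kind,
               group = cube$group, individual = cube$individual,
               scale = scale)
  if (any(!cube$mask)) {
    bad <- which(!cube$mask, arr.ind = TRUE)
    meta$invalid_pixels <- unname(apply(bad, 1L, as.list))
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(tif) sub("\\.tiff?$", ".json", tif, ignore.case = TRUE)

#' Read a spectral cube from disk
#'
#' Accepts either a multi-page TIFF with a `.json` sidecar of the same stem,
#' or a directory of per-band images (`.tif`/`.tiff`/`.png`) with a
#' `cube.json` sidecar. The sidecar lists one wavelength per band in file
#' order; if they are unsorted the bands are re-sorted ascending on read.
#'
#' @param path path to a `.tif` file or a band directory.
#' @return a [spectral_cube()].
#' @export
read_cube <- function(path) {
  if (dir.exists(path)) {
    sidecar <- file.path(path, "cube.json")
    if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
    files <- sort(list.files(path, pattern = "\\.(tiff?|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no band images in ", path)
    pages <- lapply(files, read_band_image)
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    sidecar <- sidecar_path(path)
    if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
    pages <- tiff::readTIFF(path, all = TRUE)
    pages <- lapply(pages, drop_channels)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  wl <- as.numeric(meta$wavelengths_nm)
  if (length(pages) != length(wl))
    stop("sidecar lists ", length(wl), " wavelengths but data has ",
         length(pages), " bands")
  kinds <- c("intensity", "transmission", "absorbance")
  if (is.null(meta$kind) || !meta$kind %in% kinds)
    stop("unknown kind tag in sidecar: ", meta$kind)
  scale <- if (is.null(meta$scale)) 1 else as.numeric(meta$scale)
  pages <- lapply(pages, function(p) p * scale)

  mask <- NULL
  if (!is.null(meta$invalid_pixels) && length(meta$invalid_pixels) > 0L) {
    mask <- matrix(TRUE, nrow(pages[[1L]]), ncol(pages[[1L]]))
    ij <- meta$invalid_pixels
    if (is.data.frame(ij)) ij <- as.matrix(ij)
    if (is.list(ij)) ij <- do.call(rbind, lapply(ij, unlist))
    mask[cbind(as.integer(ij[, 1L]), as.integer(ij[, 2L]))] <- FALSE
    # masked transmission pixels were stored as 0; lift them off the
    # invalid-value floor so the constructor accepts them
    if (meta$kind == "transmission")
      pages <- lapply(pages, function(p) { p[!mask] <- 1; p })
  }
  build_cube(pages, wl, kind = meta$kind,
             group = if (is.null(meta$group)) NA_character_ else meta$group,
             individual = if (is.null(meta$individual)) NA else meta$individual,
             mask = mask)
}

read_band_image <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
    requireNamespace("png")
    png::readPNG(f)
  } else {
    tiff::readTIFF(f)
  }
  drop_channels(img)
}

# collapse an RGB(A) page to grey by averaging colour channels
drop_channels <- function(img) {
  if (length(dim(img)) == 3L) img <- rowMeans(img[, , 1:min(3L, dim(img)[3L]), drop = FALSE], dims = 2L)
  img
}
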