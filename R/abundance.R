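#' Probability density function of an abundance map
#'
#' Normalised histogram of the abundance values over valid pixels: the
#' per-bin density integrates to 1 over the bin grid.
#'
#' @param map numeric matrix of abundances (>= 0; `NA` = masked).
#' @param bin_edges strictly increasing bin boundaries covering the data
#'   (values outside the range are counted into the edge bins).
#' @param endmember_id,group,individual labels carried on the result.
#' @return object of class `abundance_pdf`: `bin_edges`, `density`,
#'   `endmember_id`, `group`, `individual`, `n_pixels`.
#' @export
abundance_pdf <- function(map, bin_edges, endmember_id = NA,
                          group = NA_character_, individual = NA) {
  v <- map[!is.na(map)]
  if (length(v) == 0L) stop("empty abundance map")
  if (any(v < 0)) stop("abundances must be >= 0")
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing")
  v <- pmin(pmax(v, bin_edges[1L]), bin_edges[length(bin_edges)])
  counts <- graphics::hist(v, breaks = bin_edges, plot = FALSE)$counts
  widths <- diff(bin_edges)
  structure(list(bin_edges = bin_edges,
                 density = counts / (sum(counts) * widths),
                 endmember_id = endmember_id, group = group,
                 individual = individual, n_pixels = length(v)),
            class = "abundance_pdf")
}

#' Shared bin grid for a set of abundance maps
#'
#' Uniform bins over `[0, max]` where the maximum is taken across every
#' map in the comparison, so densities of different groups are directly
#' comparable on one axis.
#'
#' @param maps list of abundance matrices (or a single matrix).
#' @param bins number of bins (default 50).
#' @return numeric vector of `bins + 1` edges.
#' @export
abundance_bin_edges <- function(maps, bins = 50L) {
  if (is.matrix(maps)) maps <- list(maps)
  hi <- max(vapply(maps, function(m) max(m, na.rm = TRUE), numeric(1L)))
  if (hi <= 0) hi <- 1
  seq(0, hi, length.out = bins + 1L)
}

#' Average abundance pdfs across eyes
#'
#' Per-bin arithmetic mean of densities over pdfs computed on identical
#' bin grids; the mean still integrates to 1.
#'
#' @param pdfs list of [abundance_pdf()] objects with identical
#'   `bin_edges`.
#' @return an `abundance_pdf` (labels taken from the first input's
#'   endmember id, group set to `"mean"` unless all agree).
#' @export
group_mean_pdf <- function(pdfs) {
  if (length(pdfs) == 0L) stop("empty pdf list")
  edges <- pdfs[[1L]]$bin_edges
  D <- sapply(pdfs, function(p) {
    if (!isTRUE(all.equal(p$bin_edges, edges)))
      stop("pdfs have mismatched bin edges")
    p$density
  })
  D <- as.matrix(D)
  groups <- unique(vapply(pdfs, function(p) as.character(p$group), character(1L)))
  structure(list(bin_edges = edges, density = rowMeans(D),
                 endmember_id = pdfs[[1L]]$endmember_id,
                 group = if (length(groups) == 1L) groups else "mean",
                 individual = NA,
                 n_pixels = sum(vapply(pdfs, function(p) p$n_pixels, numeric(1L)))),
            class = "abundance_pdf")
}

#' @export
print.abundance_pdf <- function(x, ...) {
  cat("<abundance_pdf> endmember ", x$endmember_id, ", ",
      length(x$density), " bins on [", min(x$bin_edges), ", ",
      signif(max(x$bin_edges), 4), "], ", x$n_pixels, " pixels\n", sep = "")
  invisible(x)
}

#' @export
plot.abundance_pdf <- function(x, ...) {
  mids <- (x$bin_edges[-1L] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(mids, x$density, type = "s", xlab = "abundance",
                 ylab = "probability density", ...)
  invisible(x)
}

#' Fraction of pixels above an abundance threshold
#'
#' Descriptive statistic for localising strongly expressed endmembers
#' (e.g. the fraction of a map with abundance above 0.2).
#'
#' @param map abundance matrix (`NA` = masked).
#' @param threshold non-negative cutoff.
#' @return fraction in `[0, 1]` of valid pixels with abundance strictly
#'   above `threshold`.
#' @export
high_abundance_fraction <- function(map, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  v <- map[!is.na(map)]
  if (length(v) == 0L) stop("empty abundance map")
  mean(v > threshold)
}

#' Group-wise mean absorbance spectra
#'
#' Averages each eye's mean absorbance spectrum within its group and
#' reports, per group, the wavelength of maximal mean absorbance.
#'
#' @param cubes list of absorbance [spectral_cube()]s sharing one
#'   wavelength grid; each cube's `group` label assigns it to a group.
#' @param groups optional character vector overriding the cubes' group
#'   labels.
#' @return list with `table` (data.frame: group, wavelength_nm,
#'   mean_absorbance) and `peak_nm` (named numeric vector: argmax
#'   wavelength per group).
#' @export
mean_absorbance_report <- function(cubes, groups = NULL) {
  if (length(cubes) == 0L) stop("no cubes")
  wl <- cubes[[1L]]$wavelengths
  for (cb in cubes)
    if (!isTRUE(all.equal(cb$wavelengths, wl)))
      stop("cubes are on different wavelength grids")
  if (is.null(groups))
    groups <- vapply(cubes, function(cb) as.character(cb$group), character(1L))
  spectra <- vapply(cubes, mean_absorbance, numeric(length(wl)))
  spectra <- matrix(spectra, nrow = length(wl))
  ug <- unique(groups)
  rows <- list(); peak <- numeric(0)
  for (g in ug) {
    mg <- rowMeans(spectra[, groups == g, drop = FALSE])
    rows[[g]] <- data.frame(group = g, wavelength_nm = wl,
                            mean_absorbance = mg)
    peak[g] <- wl[which.max(mg)]
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       peak_nm = peak)
}
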