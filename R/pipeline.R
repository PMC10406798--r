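# Orchestration of the full workflow: simulate a phantom dataset to disk,
# then run acquisition arithmetic -> absorbance -> PCA -> endmembers ->
# NNLS unmixing -> abundance statistics over it, with a JSON run report.

config_error <- function(...) {
  stop(structure(class = c("specunmix_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}
data_error <- function(...) {
  stop(structure(class = c("specunmix_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}

#' Pipeline run configuration
#'
#' Collects every tunable of a pipeline run in one serialisable list:
#' dataset location and simulation parameters, the endmember count `m`
#' (an integer, or `"auto"` for the cumulative-variance rule), the
#' variance threshold, the endmember scale factor, abundance binning and
#' thresholds, and the seed.
#'
#' @param outdir dataset/output directory.
#' @param groups group labels to simulate/analyse.
#' @param n_eyes eyes per group.
#' @param shape frame shape (rows, columns).
#' @param wavelengths band wavelengths in nm.
#' @param noise_sigma,n_frames,levels acquisition simulation parameters
#'   (see [phantom_spec()]); with `noise_sigma = 0` the simulator writes
#'   the noise-free transmission directly.
#' @param m endmember count, or `"auto"`.
#' @param threshold_pct cumulative-variance threshold used when
#'   `m = "auto"`.
#' @param scale_k endmember construction scale.
#' @param bins abundance-pdf bin count.
#' @param abundance_threshold cutoff for the high-abundance fraction.
#' @param eps_floor transmission clipping floor.
#' @param seed integer seed.
#' @param format on-disk cube format, `"tiff"` or `"dir"`.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            groups = c("control", "D2", "D8"),
                            n_eyes = 9L, shape = c(128L, 128L),
                            wavelengths = seq(390, 705, by = 15),
                            noise_sigma = 0, n_frames = 50L, levels = 256L,
                            m = 5L, threshold_pct = 99, scale_k = 2,
                            bins = 50L, abundance_threshold = 0.2,
                            eps_floor = 1e-6, seed = 1L,
                            format = c("tiff", "dir")) {
  format <- match.arg(format)
  if (missing(outdir) || !is.character(outdir) || length(outdir) != 1L)
    config_error("'outdir' must be a single path")
  if (!(identical(m, "auto") || (is.numeric(m) && m >= 1)))
    config_error("'m' must be a positive integer or \"auto\"")
  if (scale_k <= 0) config_error("'scale_k' must be > 0")
  if (n_eyes < 1L) config_error("'n_eyes' must be >= 1")
  structure(list(outdir = outdir, groups = groups, n_eyes = as.integer(n_eyes),
                 shape = as.integer(shape), wavelengths = as.numeric(wavelengths),
                 noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
                 levels = levels, m = if (identical(m, "auto")) "auto" else as.integer(m),
                 threshold_pct = threshold_pct, scale_k = scale_k,
                 bins = as.integer(bins),
                 abundance_threshold = abundance_threshold,
                 eps_floor = eps_floor, seed = as.integer(seed),
                 format = format),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_pipeline_config` returns a [pipeline_config()];
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error("no such config file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$outdir <- as.character(raw$outdir)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

eye_path <- function(config, group, eye) {
  file.path(config$outdir, "raw", group,
            if (config$format == "tiff") sprintf("eye_%02d.tif", eye)
            else sprintf("eye_%02d", eye))
}

#' Simulate a phantom dataset to disk
#'
#' Generates `n_eyes` phantom eyes per group and writes one transmission
#' cube per eye under `<outdir>/raw/<group>/`, plus a `manifest.json`
#' echoing the configuration. With `noise_sigma > 0` the full two-shot
#' acquisition (repeated noisy frames, quantisation, averaging, reference
#' division) is simulated; otherwise the noise-free transmission is
#' written directly.
#'
#' @param config a [pipeline_config()].
#' @param force overwrite an existing non-empty output directory.
#' @return character vector of written cube paths, invisibly.
#' @export
pipeline_simulate <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  raw <- file.path(config$outdir, "raw")
  if (dir.exists(raw) && length(list.files(raw, recursive = TRUE)) > 0L && !force)
    data_error("output directory ", raw, " is not empty (use force = TRUE)")
  paths <- character(0)
  for (g in config$groups) {
    dir.create(file.path(raw, g), recursive = TRUE, showWarnings = FALSE)
    eyes <- generate_group(g, n_eyes = config$n_eyes, shape = config$shape,
                           wavelengths = config$wavelengths,
                           noise_sigma = config$noise_sigma,
                           n_frames = config$n_frames, levels = config$levels,
                           seed = config$seed)
    for (e in seq_along(eyes)) {
      cube <- eyes[[e]]$cube
      if (config$noise_sigma > 0) {
        acq <- simulate_acquisition(eyes[[e]]$spec, cube)
        cube <- acquisition_to_transmission(acq, eps_floor = config$eps_floor,
                                            group = g, individual = e)
      }
      p <- eye_path(config, g, e)
      write_cube(cube, p, format = config$format)
      paths <- c(paths, p)
    }
  }
  jsonlite::write_json(c(unclass(config), list(files = paths)),
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

write_matrix_csv <- function(m, path, first_col = NULL, first_name = NULL) {
  df <- as.data.frame(m)
  if (!is.null(first_col)) {
    df <- cbind(stats::setNames(data.frame(first_col), first_name), df)
  }
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis over a dataset on disk
#'
#' Reads every transmission cube under `<outdir>/raw/<group>/`, converts
#' to absorbance, decomposes each eye by wavelength-space PCA, selects the
#' endmember count (fixed, or by cumulative variance when `m = "auto"`,
#' with a warning when the automatic choice differs from the conventional
#' fixed value of 5), constructs per-eye endmembers, unmixes every pixel
#' by NNLS, and writes variance tables, group-averaged eigenvectors and
#' endmembers, group mean-absorbance spectra, abundance pdfs and
#' summaries, and a JSON run report (effective config, versions, seed,
#' output checksums) under `<outdir>/results/`.
#'
#' @param config a [pipeline_config()] describing the dataset.
#' @return the run report, invisibly (a named list).
#' @export
pipeline_run <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  resdir <- file.path(config$outdir, "results")
  dir.create(resdir, recursive = TRUE, showWarnings = FALSE)

  # ---- load and convert ------------------------------------------------
  eyes <- list()
  for (g in config$groups) {
    gdir <- file.path(config$outdir, "raw", g)
    if (!dir.exists(gdir)) data_error("missing group directory: ", gdir)
    entries <- list.files(gdir, pattern = "^eye", full.names = TRUE)
    entries <- entries[!grepl("\\.json$", entries)]
    if (length(entries) == 0L) data_error("no cubes found in ", gdir)
    for (p in sort(entries)) {
      cube <- read_cube(p)
      if (!isTRUE(all.equal(cube$wavelengths, config$wavelengths)))
        data_error("band grid of ", p, " does not match the configuration")
      eyes[[length(eyes) + 1L]] <- list(group = g, path = p,
                                        acube = transmission_to_absorbance(cube))
    }
  }

  # ---- PCA per eye -----------------------------------------------------
  decomps <- lapply(eyes, function(e) spectral_pca(e$acube))
  groups_of <- vapply(eyes, `[[`, character(1L), "group")

  pct_mean <- rowMeans(sapply(decomps, `[[`, "variance_pct"))
  if (identical(config$m, "auto")) {
    m <- select_num_components(pct_mean, threshold_pct = config$threshold_pct)
    if (m != 5L)
      warning("auto-selected m = ", m, " from the ", config$threshold_pct,
              "% variance rule; analyses of this kind conventionally fix m = 5",
              call. = FALSE)
  } else m <- min(config$m, length(config$wavelengths))

  eigen_rows <- list()
  for (g in config$groups) {
    D <- decomps[groups_of == g]
    ev <- rowMeans(sapply(D, `[[`, "eigenvalues"))
    pc <- rowMeans(sapply(D, `[[`, "variance_pct"))
    k <- min(m, length(ev))
    eigen_rows[[g]] <- data.frame(group = g, component = seq_len(k),
                                  mean_eigenvalue = ev[1:k],
                                  mean_variance_pct = pc[1:k])
  }
  eigen_table <- do.call(rbind, c(eigen_rows, list(make.row.names = FALSE)))
  utils::write.csv(eigen_table, file.path(resdir, "eigen_table.csv"),
                   row.names = FALSE)

  for (g in config$groups) {
    D <- decomps[groups_of == g]
    em <- sapply(seq_len(m), function(a) group_average_eigenvectors(D, a)$mean)
    write_matrix_csv(em, file.path(resdir, paste0("eigenvectors_", g, ".csv")),
                     first_col = config$wavelengths, first_name = "wavelength_nm")
  }

  # ---- group mean absorbance ------------------------------------------
  rep_abs <- mean_absorbance_report(lapply(eyes, `[[`, "acube"),
                                    groups = groups_of)
  utils::write.csv(rep_abs$table, file.path(resdir, "mean_absorbance.csv"),
                   row.names = FALSE)

  # ---- endmembers + unmixing per eye ----------------------------------
  fits <- lapply(seq_along(eyes), function(i) {
    em <- construct_endmembers(decomps[[i]], m = m, scale_k = config$scale_k)
    list(endmembers = em, ab = unmix_cube(eyes[[i]]$acube, em))
  })
  for (g in config$groups) {
    E <- sapply(fits[groups_of == g], function(f) f$endmembers$spectra,
                simplify = "array")
    write_matrix_csv(rowMeans(E, dims = 2L),
                     file.path(resdir, paste0("endmembers_", g, ".csv")),
                     first_col = config$wavelengths, first_name = "wavelength_nm")
  }

  # ---- abundance statistics -------------------------------------------
  all_maps <- lapply(fits, function(f) f$ab$maps)
  summ <- list(); pdf_tabs <- list()
  for (k in seq_len(m)) {
    edges <- abundance_bin_edges(lapply(all_maps, function(a) a[, , k]),
                                 bins = config$bins)
    mids <- (edges[-1L] + edges[-length(edges)]) / 2
    ptab <- data.frame(bin_mid = mids)
    for (g in config$groups) {
      idx <- which(groups_of == g)
      pdfs <- lapply(idx, function(i)
        abundance_pdf(all_maps[[i]][, , k], edges, endmember_id = k,
                      group = g, individual = i))
      ptab[[g]] <- group_mean_pdf(pdfs)$density
      for (i in idx)
        summ[[length(summ) + 1L]] <- data.frame(
          group = g, eye = eyes[[i]]$path, endmember = k,
          mean_abundance = mean(all_maps[[i]][, , k], na.rm = TRUE),
          high_fraction = high_abundance_fraction(all_maps[[i]][, , k],
                                                  config$abundance_threshold))
    }
    pdf_tabs[[k]] <- ptab
    utils::write.csv(ptab, file.path(resdir, sprintf("pdf_endmember_%d.csv", k)),
                     row.names = FALSE)
  }
  summary_table <- do.call(rbind, c(summ, list(make.row.names = FALSE)))
  utils::write.csv(summary_table, file.path(resdir, "abundance_summary.csv"),
                   row.names = FALSE)

  # ---- run report ------------------------------------------------------
  outputs <- list.files(resdir, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(resdir, "run_report.json"))
  report <- list(config = unclass(config), m = m,
                 peak_wavelength_nm = as.list(rep_abs$peak_nm),
                 n_eyes_analysed = length(eyes),
                 versions = list(specunmix = as.character(utils::packageVersion("specunmix")),
                                 R = paste(R.version$major, R.version$minor, sep = ".")),
                 checksums = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(report, file.path(resdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
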