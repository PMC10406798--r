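test_that("endmember construction is mean + scale * sqrt(Gamma) * e", {
  toy <- list(mean_spectrum = c(1, 1),
              eigenvalues = c(0.25, 0),
              eigenvectors = cbind(c(1, 0), c(0, 1)),
              wavelengths = c(400, 500))
  em <- construct_endmembers(toy, m = 2, scale_k = 2)
  expect_equal(unname(em$spectra[, 1]), c(2, 1))
  # zero eigenvalue collapses to the mean spectrum
  expect_equal(unname(em$spectra[, 2]), c(1, 1))
  expect_identical(em$source, "pca-derived")
  expect_identical(em$scale_k, 2)

  expect_error(construct_endmembers(toy, m = 2, scale_k = 0), "positive")
  expect_error(construct_endmembers(toy, m = 3), "exceeds")

  toy$mean_spectrum <- c(0.1, 1)
  toy$eigenvectors <- cbind(c(-1, 0), c(0, 1))
  neg <- construct_endmembers(toy, m = 1, scale_k = 4)  # 0.1 - 2 sqrt(.25) 4 < 0
  expect_lt(min(neg$spectra), 0)
  clipped <- construct_endmembers(toy, m = 1, scale_k = 4, clip_negative = TRUE)
  expect_gte(min(clipped$spectra), 0)
})

test_that("endmember sets validate their shape", {
  expect_error(endmember_set(matrix(1, 2, 3)), "fewer bands")
  expect_error(endmember_set(cbind(c(1, 1), c(0, 0))), "all-zero")
  es <- endmember_set(cbind(c(1, 2), c(2, 1)), wavelengths = c(400, 500))
  expect_identical(es$source, "user-supplied")
})

test_that("nnls_solve solves trivial systems and satisfies the KKT conditions", {
  expect_equal(nnls_solve(diag(2), c(0.3, 0.7)), c(0.3, 0.7))
  expect_equal(nnls_solve(diag(2), c(-1, 2)), c(0, 2))
  expect_error(nnls_solve(cbind(c(1, 1), 0), c(1, 1)), "all-zero")
  expect_error(nnls_solve(diag(2), c(1, 2, 3)), "length")

  set.seed(30)
  for (i in 1:20) {
    U <- matrix(rnorm(6 * 3), 6, 3)
    b <- rnorm(6)
    x <- nnls_solve(U, b)
    expect_true(all(x >= 0))
    g <- drop(crossprod(U, U %*% x - b))
    tol <- 1e-8 * max(abs(crossprod(U, b)))
    expect_lt(max(abs(g[x > 0]), 0), tol + 1e-12)     # stationarity on support
    expect_true(all(g[x == 0] >= -tol - 1e-12))       # dual feasibility
  }
})

test_that("brute-force oracle closed forms hold", {
  expect_equal(nnls_bruteforce_oracle(diag(2), c(0.3, 0.7)), c(0.3, 0.7))
  u <- c(1, 2, 2)
  for (b in list(c(1, 1, 1), c(-1, -2, -2))) {
    expect_equal(nnls_bruteforce_oracle(matrix(u, 3, 1), b),
                 max(0, sum(u * b) / sum(u * u)))
  }
  expect_error(nnls_bruteforce_oracle(matrix(1, 2, 11), 1:2), "m <= 10")
})

test_that("solver agrees with the support-enumeration oracle", {
  set.seed(31)
  for (i in 1:100) {
    dims <- if (i %% 2 == 0) c(4L, 2L) else c(6L, 3L)
    U <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    b <- rnorm(dims[1])
    x_solver <- nnls_solve(U, b)
    x_oracle <- nnls_bruteforce_oracle(U, b)
    expect_equal(x_solver, x_oracle, tolerance = 1e-6)
  }
})

test_that("NNLS residual is at least the unconstrained residual", {
  set.seed(32)
  for (i in 1:20) {
    U <- matrix(rnorm(8 * 3), 8, 3)
    b <- rnorm(8)
    x <- nnls_solve(U, b)
    x_ls <- qr.solve(U, b)
    expect_gte(sum((U %*% x - b)^2), sum((U %*% x_ls - b)^2) - 1e-12)
  }
})

test_that("cube unmixing recovers exact mixtures pixel by pixel", {
  wl <- seq(400, 480, 20)
  U <- cbind(c(1, 0.5, 0.2, 0.1, 0.4), c(0.1, 0.6, 1, 0.3, 0.2))
  es <- endmember_set(U, wavelengths = wl)

  pure <- spectral_cube(array(rep(U[, 1], each = 9), c(3, 3, 5)), wl,
                        kind = "absorbance")
  ab <- unmix_cube(pure, es)
  expect_equal(ab$maps[, , 1], matrix(1, 3, 3), tolerance = 1e-10)
  expect_equal(ab$maps[, , 2], matrix(0, 3, 3), tolerance = 1e-10)
  expect_lt(max(ab$residual), 1e-10)

  mix <- spectral_cube(array(rep(0.4 * U[, 1] + 0.6 * U[, 2], each = 9),
                             c(3, 3, 5)), wl, kind = "absorbance")
  abm <- unmix_cube(mix, es)
  expect_equal(abm$maps[, , 1], matrix(0.4, 3, 3), tolerance = 1e-10)
  expect_equal(abm$maps[, , 2], matrix(0.6, 3, 3), tolerance = 1e-10)
  expect_lt(max(abm$residual), 1e-10)

  wrong <- spectral_cube(array(1, c(3, 3, 4)), wl[1:4], kind = "absorbance")
  expect_error(unmix_cube(wrong, es), "bands")
})

test_that("unmixing treats pixels independently and honours the mask", {
  wl <- seq(400, 480, 20)
  U <- cbind(c(1, 0.5, 0.2, 0.1, 0.4), c(0.1, 0.6, 1, 0.3, 0.2))
  es <- endmember_set(U, wavelengths = wl)
  set.seed(33)
  dat <- array(abs(rnorm(4 * 4 * 5)), c(4, 4, 5))
  msk <- matrix(TRUE, 4, 4); msk[3, 1] <- FALSE
  cube <- spectral_cube(dat, wl, kind = "absorbance", mask = msk)
  ab <- unmix_cube(cube, es)
  expect_true(all(is.na(ab$maps[3, 1, ])))
  expect_true(all(ab$maps[!is.na(ab$maps)] >= 0))
  # per-pixel solutions equal the standalone solver's
  for (px in list(c(1, 1), c(2, 4), c(4, 4)))
    expect_equal(ab$maps[px[1], px[2], ],
                 nnls_solve(U, dat[px[1], px[2], ]), tolerance = 1e-12)
})

test_that("noise-free phantom unmixes exactly against its true spectra", {
  ph <- phantom_spec(shape = c(64, 64), seed = 40)
  rend <- render_transmission_cube(ph)
  acube <- transmission_to_absorbance(rend$cube)
  es <- endmember_set(rend$model$epsilon, wavelengths = ph$wavelengths)
  ab <- unmix_cube(acube, es)
  expect_lt(max(abs(ab$maps - rend$truth$abundance)), 1e-8)
})

test_that("spectral similarity measures angle and correlation", {
  s <- c(1, 2, 3, 2)
  same <- spectral_similarity(s, s)
  expect_equal(same$angle_deg, 0, tolerance = 1e-8)
  expect_equal(same$correlation, 1)
  expect_equal(spectral_similarity(s, 3 * s)$angle_deg, 0, tolerance = 1e-6)
  expect_equal(spectral_similarity(c(1, 0), c(0, 1))$angle_deg, 90)
  expect_error(spectral_similarity(c(0, 0), s[1:2]), "zero-norm")
  expect_error(spectral_similarity(s, s[1:2]), "different lengths")
})

test_that("the fitted unmixing model exposes the standard methods", {
  ph <- phantom_spec(shape = c(64, 64), seed = 41)
  acube <- transmission_to_absorbance(render_transmission_cube(ph)$cube)
  fit <- spectral_unmix(acube, m = 3)
  expect_s3_class(fit, "spectral_unmix")
  expect_equal(dim(coef(fit)), c(22L, 3L))
  expect_equal(dim(residuals(fit)), c(64L, 64L))
  f <- fitted(fit)
  expect_s3_class(f, "spectral_cube")
  # fitted cube is U %*% abundances per pixel
  px <- drop(fit$abundance$maps[10, 12, ])
  expect_equal(f$data[10, 12, ], drop(coef(fit) %*% px), tolerance = 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.spectral_unmix")
  expect_equal(nrow(s$table), 3L)
  # predict on new data uses the fitted endmembers
  pred <- predict(fit, acube)
  expect_equal(pred$maps, fit$abundance$maps, tolerance = 1e-12)
  expect_output(print(fit), "Endmember unmixing fit")
})
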