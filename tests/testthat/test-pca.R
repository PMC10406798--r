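test_that("band-mean centering removes the mean and is invertible", {
  cube <- spectral_cube(array(rep(c(1.5, 2.5), each = 9), c(3, 3, 2)),
                        c(400, 500), kind = "absorbance")
  ctr <- center_by_band_mean(cube)
  expect_equal(ctr$cube$data, array(0, c(3, 3, 2)))
  expect_equal(unname(ctr$mean_spectrum), c(1.5, 2.5))

  cube <- rand_cube(7, 6, 4, seed = 11)
  ctr <- center_by_band_mean(cube)
  expect_lt(max(abs(apply(ctr$cube$data, 3, mean))), 1e-10)
  restored <- ctr$cube$data +
    rep(ctr$mean_spectrum, each = 42)
  expect_equal(restored, cube$data, tolerance = 1e-14)
})

test_that("band covariance matches a brute-force triple loop", {
  zero <- spectral_cube(array(0, c(4, 4, 3)), c(1:3) * 100, kind = "absorbance")
  expect_equal(band_covariance(zero), matrix(0, 3, 3))

  one <- spectral_cube(array(c(-1, 1), c(2, 1, 1)), 500, kind = "absorbance")
  expect_equal(band_covariance(one), matrix(1, 1, 1))

  cube <- rand_cube(6, 6, 3, seed = 12)
  ctr <- center_by_band_mean(cube)$cube
  S <- band_covariance(ctr)
  M <- 36
  oracle <- matrix(0, 3, 3)
  for (l1 in 1:3) for (l2 in 1:3) {
    s <- 0
    for (i in 1:6) for (j in 1:6)
      s <- s + ctr$data[i, j, l1] * ctr$data[i, j, l2]
    oracle[l1, l2] <- s / M
  }
  expect_equal(S, oracle, tolerance = 1e-12)
  expect_equal(S, t(S))
})

test_that("eigendecomposition solves S e = Gamma e deterministically", {
  e <- eigendecompose(diag(c(2, 1)))
  expect_equal(e$values, c(2, 1))
  expect_equal(abs(e$vectors), diag(2))
  # sign convention: largest-magnitude entry positive
  expect_true(all(apply(e$vectors, 2, max) > 0))

  set.seed(13)
  B <- matrix(rnorm(25), 5, 5)
  S <- crossprod(B) / 5
  e <- eigendecompose(S)
  expect_equal(sum(e$values), sum(diag(S)), tolerance = 1e-10)
  expect_equal(crossprod(e$vectors), diag(5), tolerance = 1e-10)
  rebuilt <- e$vectors %*% diag(e$values) %*% t(e$vectors)
  expect_equal(rebuilt, S, tolerance = 1e-10)
  for (a in 1:5)
    expect_lt(max(abs(S %*% e$vectors[, a] - e$values[a] * e$vectors[, a])),
              1e-8 * sum(diag(S)))
  expect_error(eigendecompose(matrix(c(1, 2, 0, 1), 2, 2)), "not symmetric")
})

test_that("PC images are zero-mean, uncorrelated, with variance Gamma", {
  cube <- rand_cube(12, 10, 5, seed = 14)
  ctr <- center_by_band_mean(cube)$cube
  S <- band_covariance(ctr)
  e <- eigendecompose(S)

  # identity eigenvectors reproduce the centered bands
  expect_equal(compute_principal_components(ctr, diag(5)), ctr$data)

  pcs <- compute_principal_components(ctr, e$vectors)
  M <- 120
  P <- matrix(pcs, M, 5)
  expect_lt(max(abs(colMeans(P))), 1e-8)
  cov_pc <- crossprod(P) / M       # population, matching band_covariance
  off <- cov_pc - diag(diag(cov_pc))
  expect_lt(max(abs(off)), 1e-8 * e$values[1L])
  expect_equal(diag(cov_pc), e$values, tolerance = 1e-8)
})

test_that("reconstruction inverts the PC expansion", {
  cube <- rand_cube(8, 8, 4, seed = 15)
  ctr <- center_by_band_mean(cube)
  e <- eigendecompose(band_covariance(ctr$cube))
  pcs <- compute_principal_components(ctr$cube, e$vectors)
  back <- reconstruct_cube(pcs, e$vectors, ctr$mean_spectrum,
                           cube$wavelengths)
  expect_lt(max(abs(back$data - cube$data)), 1e-8)

  # zero components: the mean spectrum broadcast
  m0 <- reconstruct_cube(array(0, c(8, 8, 0)),
                         e$vectors[, 0, drop = FALSE], ctr$mean_spectrum,
                         cube$wavelengths)
  expect_equal(m0$data,
               array(rep(ctr$mean_spectrum, each = 64), c(8, 8, 4)),
               tolerance = 1e-12)

  # rank-1 cube is reconstructed exactly from one component
  set.seed(16)
  spec <- abs(rnorm(4)); img <- matrix(rnorm(36), 6, 6)
  r1 <- spectral_cube(outer(img, spec), seq(400, 460, 20), kind = "absorbance")
  ctr1 <- center_by_band_mean(r1)
  e1 <- eigendecompose(band_covariance(ctr1$cube))
  pcs1 <- compute_principal_components(ctr1$cube, e1$vectors)
  back1 <- reconstruct_cube(pcs1[, , 1, drop = FALSE],
                            e1$vectors[, 1, drop = FALSE],
                            ctr1$mean_spectrum, r1$wavelengths)
  expect_lt(max(abs(back1$data - r1$data)), 1e-8)
})

test_that("rank-m residual variance equals the trailing eigenvalue sum", {
  cube <- rand_cube(15, 12, 6, seed = 17)
  ctr <- center_by_band_mean(cube)
  e <- eigendecompose(band_covariance(ctr$cube))
  pcs <- compute_principal_components(ctr$cube, e$vectors)
  M <- prod(dim(cube$data)[1:2])
  prev <- Inf
  for (m in 0:6) {
    back <- reconstruct_cube(pcs[, , seq_len(m), drop = FALSE],
                             e$vectors[, seq_len(m), drop = FALSE],
                             ctr$mean_spectrum, cube$wavelengths)
    resid_var <- sum((back$data - cube$data)^2) / M
    expect_lte(resid_var, prev + 1e-12)   # monotone in m
    prev <- resid_var
    tail_sum <- sum(e$values[seq_len(6) > m])
    if (tail_sum > 0)
      expect_lt(abs(resid_var - tail_sum) / tail_sum, 1e-6)
  }
})

test_that("variance percentages normalise the eigenvalue spectrum", {
  expect_equal(variance_percentages(c(3, 1)), c(75, 25))
  expect_equal(variance_percentages(5), 100)
  expect_error(variance_percentages(c(0, 0)), "all eigenvalues are zero")

  # normalising a published-style 5-value spectrum over its own sum does
  # not recover table percentages whose denominator held trailing
  # eigenvalues as well
  ev <- c(2.41, 0.25, 0.03, 0.02, 0.01)
  pct <- variance_percentages(ev)
  expect_equal(pct, c(88.6029411764706, 9.19117647058824, 1.10294117647059,
                      0.735294117647059, 0.367647058823529),
               tolerance = 1e-10)
  expect_equal(sum(pct), 100, tolerance = 1e-8)
  expect_gt(abs(pct[1] - 88.08), 0.1)
})

test_that("component-count selection honours threshold and override", {
  pct <- c(88.08, 9.27, 1.25, 0.56, 0.33)
  expect_identical(select_num_components(pct, threshold_pct = 99), 4L)
  expect_identical(select_num_components(100, threshold_pct = 99), 1L)
  expect_identical(select_num_components(pct, threshold_pct = 99,
                                         fixed_m = 5), 5L)
  expect_error(select_num_components(c(50, 20), threshold_pct = 99),
               "never reaches")
})

test_that("group eigenvector averaging aligns signs before the mean", {
  cube <- rand_cube(9, 9, 4, seed = 18)
  d <- spectral_pca(cube)
  same <- group_average_eigenvectors(list(d, d), alpha = 1)
  expect_equal(same$mean, unname(d$eigenvectors[, 1]))
  expect_equal(same$sd, rep(0, 4))

  flipped <- d; flipped$eigenvectors <- -d$eigenvectors
  ga <- group_average_eigenvectors(list(d, flipped), alpha = 2)
  expect_equal(ga$mean, unname(d$eigenvectors[, 2]), tolerance = 1e-12)
  expect_equal(ga$sd, rep(0, 4), tolerance = 1e-12)

  # perturbed eyes: explicit-loop mean/sd oracle
  set.seed(19)
  perturbed <- lapply(1:4, function(i) {
    di <- d
    di$eigenvectors <- d$eigenvectors + matrix(rnorm(16, sd = 0.01), 4, 4)
    di
  })
  ga <- group_average_eigenvectors(perturbed, alpha = 1)
  V <- sapply(perturbed, function(x) x$eigenvectors[, 1])
  for (j in 1:4) if (sum(V[, j] * V[, 1]) < 0) V[, j] <- -V[, j]
  mean_o <- numeric(4); sd_o <- numeric(4)
  for (b in 1:4) {
    mean_o[b] <- mean(V[b, ])
    sd_o[b] <- sqrt(sum((V[b, ] - mean_o[b])^2) / 3)
  }
  expect_equal(ga$mean, mean_o, tolerance = 1e-12)
  expect_equal(ga$sd, sd_o, tolerance = 1e-12)

  d2 <- spectral_pca(rand_cube(9, 9, 3, seed = 20))
  expect_error(group_average_eigenvectors(list(d, d2)), "different wavelength")
})

test_that("total variance is conserved through the decomposition", {
  cube <- rand_cube(10, 14, 5, seed = 21)
  p <- spectral_pca(cube)
  band_vars <- apply(cube$data, 3, function(b) mean((b - mean(b))^2))
  expect_equal(sum(p$eigenvalues), sum(band_vars), tolerance = 1e-10)
  expect_equal(sum(p$variance_pct), 100, tolerance = 1e-8)
})

test_that("noise eigenvalues beyond the signal rank sit at the noise floor", {
  # cube built from q = 2 independent spectra plus white noise of known sd
  set.seed(22)
  R <- 40L; C <- 40L; N <- 6L; sigma <- 0.05
  s1 <- abs(rnorm(N)); s2 <- abs(rnorm(N))
  c1 <- matrix(runif(R * C), R, C); c2 <- matrix(runif(R * C), R, C)
  dat <- outer(c1, s1) + outer(c2, s2) + array(rnorm(R * C * N, sd = sigma),
                                               c(R, C, N))
  p <- spectral_pca(spectral_cube(dat, seq(400, 500, 20), kind = "absorbance"))
  expect_true(all(p$eigenvalues[3:N] <= sigma^2 * 1.3))
})
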