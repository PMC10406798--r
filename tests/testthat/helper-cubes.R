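# shared fixture builders (all generated in code, fully seeded)

rand_cube <- function(R, C, N, seed = 1L, kind = "absorbance") {
  set.seed(seed)
  spectral_cube(array(abs(rnorm(R * C * N)), c(R, C, N)),
                wavelengths = seq(400, by = 10, length.out = N), kind = kind)
}

# small two-chromophore Beer-Lambert scene with linearly independent spectra
toy_model <- function(N = 6L, L = 5) {
  wl <- seq(400, by = 20, length.out = N)
  eps <- cbind(a = 0.1 + 0.05 * sin(wl / 40), b = 0.02 + 0.002 * (wl - 400) / 20)
  chromophore_model(eps, wl, thickness_L = L)
}

expect_cube_equal <- function(x, y, tol = 1e-12) {
  expect_equal(x$data, y$data, tolerance = tol)
  expect_equal(x$wavelengths, y$wavelengths)
  expect_identical(x$kind, y$kind)
}
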