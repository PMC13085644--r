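test_that("wavelength grid arithmetic", {
  g <- wavelength_grid()
  expect_equal(g$n, 81L)
  expect_equal(range(g$wavelengths), c(220, 300))
  expect_equal(wavelength_grid(200, 400, 2)$n, 101L)
  expect_error(wavelength_grid(300, 220), "exceed")
  expect_error(wavelength_grid(220, 300, 0.7), "integral")
})

test_that("pure spectra are Gaussian band sums", {
  g <- wavelength_grid()
  one <- pure_spectrum(band_model("x", 250, 10, 1.0), g)
  expect_equal(g$wavelengths[which.max(one)], 250)
  expect_equal(max(one), 1.0)
  # analytic value off-peak
  expect_equal(one[g$wavelengths == 260], exp(-100 / 200))
  empty <- pure_spectrum(band_model("0", numeric(0), numeric(0), numeric(0)), g)
  expect_equal(empty, rep(0, 81))
  expect_true(all(pure_spectrum(band_model("y", c(230, 270), c(4, 6),
                                           c(1, 2)), g) >= 0))
  expect_error(band_model("x", 250, -1, 1), "widths")
  expect_error(band_model("x", 250, 1, -1), "amplitudes")
})

test_that("default component library has the documented shape features", {
  g <- wavelength_grid()
  lib <- default_component_library(g)
  S <- t(sapply(lib, pure_spectrum, grid = g))
  expect_equal(dim(S), c(3L, 81L))
  lam <- g$wavelengths
  local_maxima <- function(s) lam[which(diff(sign(diff(s))) == -2) + 1]
  cin_max <- local_maxima(S["CIN", ])
  expect_equal(sum(cin_max >= 240 & cin_max <= 260), 2L)
  expect_true(lam[which.max(S["DOM", ])] >= 283 &&
              lam[which.max(S["DOM", ])] <= 287)
  expect_true(any(local_maxima(S["DOM", ]) >= 225 &
                  local_maxima(S["DOM", ]) <= 235))
  bnz_max <- local_maxima(S["BNZ", ])
  expect_length(bnz_max, 1L)
  expect_true(abs(bnz_max - 250) <= 2)
  cs <- c(cosine_similarity(S[1, ], S[2, ]),
          cosine_similarity(S[1, ], S[3, ]),
          cosine_similarity(S[2, ], S[3, ]))
  expect_true(all(cs > 0.3 & cs < 0.98))
})

test_that("mixture simulation is bilinear, seeded and validated", {
  g <- wavelength_grid()
  lib <- default_component_library(g)
  conc <- calibration_design_25()
  z <- simulate_mixtures(matrix(0, 2, 3,
                                dimnames = list(NULL, names(lib))),
                         lib, noise_model(0), g)
  expect_equal(z$absorbance, matrix(0, 2, 81), ignore_attr = TRUE)
  # superposition at sd = 0
  c1 <- conc[1:4, ]; c2 <- conc[5:8, ]
  a1 <- simulate_mixtures(c1, lib, noise_model(0), g)$absorbance
  a2 <- simulate_mixtures(c2, lib, noise_model(0), g)$absorbance
  a12 <- simulate_mixtures(c1 + c2, lib, noise_model(0), g)$absorbance
  expect_equal(a1 + a2, a12, tolerance = 1e-12)
  # noiseless rank equals number of varying components
  d <- simulate_mixtures(conc, lib, noise_model(0), g)
  sv <- svd(d$absorbance)$d
  expect_equal(sum(sv / sv[1] > 1e-10), 3L)
  expect_equal(d$absorbance, d$concentration %*% d$pure_spectra,
               ignore_attr = TRUE)
  # seeded determinism, bit identical
  n1 <- simulate_mixtures(conc, lib, noise_model(0.003, seed = 7), g)
  n2 <- simulate_mixtures(conc, lib, noise_model(0.003, seed = 7), g)
  expect_identical(n1$absorbance, n2$absorbance)
  expect_error(simulate_mixtures(matrix(-1, 1, 3), lib, noise_model(0), g),
               "negative")
  expect_error(noise_model(sd = -1), "sd")
})

test_that("replicate blanks estimate the noise level", {
  g <- wavelength_grid()
  lib <- default_component_library(g)
  blanks <- simulate_mixtures(
    matrix(0, 1000, 3, dimnames = list(NULL, names(lib))),
    lib, noise_model(0.005, seed = 21), g)
  sds <- apply(blanks$absorbance, 2, sd)
  # sampling error of a sd at n = 1000 is ~2.2 %; pooled estimate tight,
  # per-wavelength estimates within a 4.5-sigma band
  expect_lt(abs(sqrt(mean(sds^2)) - 0.005) / 0.005, 0.01)
  expect_true(all(abs(sds - 0.005) / 0.005 < 0.10))
})

test_that("instrument perturbations behave as documented", {
  g <- wavelength_grid()
  lib <- default_component_library(g)
  A <- simulate_mixtures(calibration_design_25()[1:5, ], lib,
                         noise_model(0), g)$absorbance
  # zero magnitude / native interval are identities
  expect_equal(perturb_instrument(A, "bandwidth", 0, g), A)
  expect_equal(perturb_instrument(A, "interval", 1, g), A)
  expect_equal(perturb_instrument(A, "scan_speed", 0, g), A)
  # bandwidth smoothing conserves integrated absorbance within 0.1 %
  sm <- perturb_instrument(A, "bandwidth", 0.9, g)
  expect_true(all(abs(rowSums(sm) - rowSums(A)) / rowSums(A) < 1e-3))
  # re-interpolated peak shifts at most one grid step
  ri <- perturb_instrument(A, "interval", 1.1, g)
  for (i in seq_len(nrow(A)))
    expect_true(abs(g$wavelengths[which.max(ri[i, ])] -
                    g$wavelengths[which.max(A[i, ])]) <= g$step)
  # scan-speed noise is seeded
  s1 <- perturb_instrument(A, "scan_speed", 0.002, g, seed = 3)
  s2 <- perturb_instrument(A, "scan_speed", 0.002, g, seed = 3)
  expect_identical(s1, s2)
  expect_error(perturb_instrument(A, "wobble", 1, g))
})
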