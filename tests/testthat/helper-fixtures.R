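# Shared builders for the test suite. Everything is generated in code;
# no binary fixtures.

toy_factors <- function() {
  list(factor_range("A", 0, 4, 5L),
       factor_range("B", 10, 30, 5L))
}

default_factors <- cin_dom_bnz_factors

# Tiny two-Gaussian bilinear system for MCR / ambiguity tests.
toy_two_component <- function(n = 8, seed = 2, noise_sd = 0) {
  lam <- seq(0, 60, by = 1)
  s1 <- exp(-(lam - 20)^2 / 50)
  s2 <- exp(-(lam - 40)^2 / 50)
  S <- rbind(s1 / sqrt(sum(s1^2)), s2 / sqrt(sum(s2^2)))
  set.seed(seed)
  C <- matrix(stats::runif(2 * n, 0.2, 2), n, 2)
  D <- C %*% S
  if (noise_sd > 0) D <- D + matrix(stats::rnorm(length(D), 0, noise_sd),
                                    nrow(D), ncol(D))
  list(C = C, S = S, D = D, lam = lam)
}

# Standard synthetic datasets for the three-analyte system.
sim_calval <- function(noise_sd = 0, seed_c = 11, seed_v = 12,
                       baseline = 0) {
  g <- wavelength_grid()
  lib <- default_component_library(g)
  calib <- simulate_mixtures(calibration_design_25(), lib,
                             noise_model(noise_sd, baseline, seed = seed_c), g)
  sel <- d_optimal_select(enumerate_candidates(cin_dom_bnz_factors()),
                          13, model_spec(), n_starts = 10, seed = 3)
  valid <- simulate_mixtures(sel$concentration, lib,
                             noise_model(noise_sd, baseline, seed = seed_v), g)
  list(grid = g, lib = lib, calib = calib, valid = valid,
       calib_conc = calibration_design_25(), valid_conc = sel$concentration)
}

# Brute-force NNLS oracle: enumerate active sets, keep the KKT-feasible
# solution with minimal residual.
nnls_oracle <- function(A, b) {
  n <- ncol(A)
  best <- NULL; best_rss <- Inf
  for (mask in 0:(2^n - 1)) {
    P <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    x <- numeric(n)
    if (length(P)) {
      cf <- qr.coef(qr(A[, P, drop = FALSE]), b)
      if (any(is.na(cf))) next
      x[P] <- cf
    }
    if (any(x < -1e-10)) next
    w <- crossprod(A, b - A %*% x)
    if (any(w[-P] > 1e-8 * max(abs(w), 1))) next
    rss <- sum((b - A %*% x)^2)
    if (rss < best_rss - 1e-12) { best_rss <- rss; best <- x }
  }
  best
}

# Brute-force D-optimality oracle.
dopt_oracle <- function(Xall, n_select) {
  best <- -Inf
  for (ix in utils::combn(nrow(Xall), n_select, simplify = FALSE)) {
    d <- det(crossprod(Xall[ix, , drop = FALSE]))
    if (d > best) best <- d
  }
  best
}
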