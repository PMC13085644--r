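test_that("Brereton 5-level design reproduces the published 25-mixture set", {
  des <- generate_brereton_design(cin_dom_bnz_factors())
  expect_equal(nrow(des$coded), 25L)
  expect_equal(unname(des$concentration[1, ]), c(12, 9, 3))
  expect_equal(unclass(des$concentration), unclass(calibration_design_25()),
               ignore_attr = TRUE)
})

test_that("generated designs are balanced, cyclic and orthogonal", {
  for (factors in list(cin_dom_bnz_factors(), toy_factors(),
                       list(factor_range("X", 0, 2, 3L),
                            factor_range("Y", 0, 2, 3L)))) {
    L <- factors[[1]]$n_levels
    des <- generate_brereton_design(factors)
    cd <- unclass(des$coded)
    h <- (L - 1) / 2
    # balance: each level exactly L times per column
    for (j in seq_len(ncol(cd)))
      expect_true(all(table(factor(cd[, j], levels = -h:h)) == L))
    # run 1 is the all-center run
    expect_true(all(cd[1, ] == 0))
    # cyclic relation between adjacent columns (runs 2..L^2)
    n <- L * L
    for (j in seq_len(ncol(cd) - 1))
      expect_equal(cd[2:n, j + 1], cd[c(3:n, 2), j])
    # exact orthogonality, integer arithmetic
    G <- crossprod(cd)
    expect_true(all(G[upper.tri(G)] == 0))
    # decoded design sits on the factor grids and round-trips
    expect_equal(unclass(concentration_to_code(des$concentration, factors)),
                 cd, ignore_attr = TRUE)
  }
})

test_that("design generation rejects invalid configurations", {
  expect_error(generate_brereton_design(
    list(factor_range("A", 0, 1, 4L))), "odd")
  expect_error(generate_brereton_design(
    list(factor_range("A", 0, 1, 5L), factor_range("B", 0, 1, 3L))),
    "same number of levels")
  expect_error(generate_brereton_design(
    rep(list(factor_range("A", 0, 1, 3L)), 3)), "unsupported")
  expect_error(factor_range("A", 5, 2), "c_min < c_max")
  expect_error(factor_range("A", 0, 1, 1L), "n_levels")
})

test_that("coding and decoding match the midpoint + step contract", {
  f <- factor_range("CIN", 4, 20, 5L)
  expect_equal(code_to_concentration(matrix(0), list(f))[1], 12)
  expect_equal(code_to_concentration(matrix(-2), list(f))[1], 4)
  expect_equal(code_to_concentration(
    matrix(2), list(factor_range("DOM", 3, 15, 5L)))[1], 15)
  expect_error(code_to_concentration(matrix(3), list(f)), "out of range")
  expect_error(code_to_concentration(matrix(0.5), list(f)), "out of range")
  expect_error(concentration_to_code(matrix(13), list(f)), "off the level grid")
  # half-integer coded levels are legal for even level counts
  f2 <- factor_range("A", 0, 1, 2L)
  expect_equal(code_to_concentration(matrix(c(-0.5, 0.5)), list(f2))[, 1],
               c(0, 1))
})

test_that("model matrix has the documented columns and order", {
  expect_equal(ncol(build_model_matrix(matrix(1, 1, 3), model_spec())), 10L)
  expect_equal(ncol(build_model_matrix(
    matrix(1, 1, 3), model_spec(interactions = FALSE, quadratic = FALSE))), 4L)
  row <- build_model_matrix(matrix(c(2, 3, 5), 1, 3), model_spec())
  expect_equal(unname(row[1, ]),
               c(1, 2, 3, 5, 2 * 3, 2 * 5, 3 * 5, 4, 9, 25))
  expect_error(model_spec(FALSE, FALSE, FALSE, FALSE), "non-empty")
})

test_that("candidate grids are complete, unique and lexicographic", {
  cand <- enumerate_candidates(cin_dom_bnz_factors())
  expect_equal(cand$n_candidates, 125L)
  expect_equal(nrow(unique(cand$coded)), 125L)
  # lexicographic: last factor fastest
  expect_equal(cand$coded[1:5, 3], c(-2, -1, 0, 1, 2))
  expect_equal(nrow(enumerate_candidates(
    list(factor_range("A", 0, 1, 2L), factor_range("B", 0, 1, 2L)))$coded), 4L)
  one <- enumerate_candidates(list(factor_range("A", 4, 20, 5L)))
  expect_equal(one$concentration[, 1], c(4, 8, 12, 16, 20))
})

test_that("exchange selection attains the brute-force optimum on small grids", {
  # all grids with <= 12 candidates and n_select <= 6
  cases <- list(
    list(factors = list(factor_range("A", 0, 1, 2L),
                        factor_range("B", 0, 1, 2L)),
         spec = model_spec(interactions = FALSE, quadratic = FALSE),
         n = 3),
    list(factors = list(factor_range("A", 0, 2, 3L),
                        factor_range("B", 0, 2, 3L)),
         spec = model_spec(quadratic = FALSE), n = 5),
    list(factors = list(factor_range("A", 0, 2, 3L),
                        factor_range("B", 0, 2, 3L)),
         spec = model_spec(), n = 6),
    list(factors = list(factor_range("A", 0, 1, 2L),
                        factor_range("B", 0, 1, 2L),
                        factor_range("C", 0, 1, 3L)),
         spec = model_spec(interactions = FALSE, quadratic = FALSE),
         n = 6))
  for (cs in cases) {
    cand <- enumerate_candidates(cs$factors)
    Xall <- build_model_matrix(cand$coded, cs$spec)
    sel <- d_optimal_select(cand, cs$n, cs$spec, n_starts = 10, seed = 5)
    expect_equal(10^sel$log10_det, dopt_oracle(Xall, cs$n), tolerance = 1e-9)
  }
})

test_that("exchange trajectory is monotone and reproducible", {
  cand <- enumerate_candidates(cin_dom_bnz_factors())
  sel1 <- d_optimal_select(cand, 13, model_spec(), n_starts = 5, seed = 42)
  sel2 <- d_optimal_select(cand, 13, model_spec(), n_starts = 5, seed = 42)
  expect_identical(sel1$indices, sel2$indices)
  expect_true(all(diff(sel1$trace) >= -1e-12))
  expect_true(sel1$log10_det >= sel1$trace[1])
  # degenerate case: selecting everything returns the full grid
  spec_lin <- model_spec(interactions = FALSE, quadratic = FALSE)
  small <- enumerate_candidates(list(factor_range("A", 0, 1, 2L),
                                     factor_range("B", 0, 1, 2L)))
  all4 <- d_optimal_select(small, 4, spec_lin, n_starts = 2, seed = 1)
  expect_equal(all4$indices, 1:4)
  Xf <- build_model_matrix(small$coded, spec_lin)
  expect_equal(all4$log10_det, log10(det(crossprod(Xf))))
  expect_error(d_optimal_select(small, 2, model_spec(quadratic = FALSE)),
               "infeasible")
})

test_that("design diagnostics report correlations, counts and coverage", {
  d <- design_diagnostics(calibration_design_25())
  expect_true(all(abs(d$correlation[upper.tri(d$correlation)]) < 1e-12))
  expect_true(all(vapply(d$level_counts, function(tb) all(tb == 5), TRUE)))
  expect_equal(unname(d$coverage), c(1, 1, 1))
  # identical columns correlate to 1
  two <- cbind(a = 1:5, b = 1:5)
  expect_equal(design_diagnostics(two)$correlation["a", "b"], 1)
  # constant column flagged NA, no error
  cc <- design_diagnostics(cbind(a = 1:5, b = rep(2, 5)))
  expect_true(is.na(cc$correlation["a", "b"]))
  # printed validation set spans BNZ fully; CIN/DOM nearly
  dv <- design_diagnostics(validation_design_13())
  expect_equal(unname(dv$coverage["BNZ"]), 1)
  expect_true(all(dv$coverage > 0.9))
  expect_error(design_diagnostics(matrix(1, 1, 2)), "2 runs")
})

test_that("solution preparation chains dilution arithmetic exactly", {
  expect_equal(solution_prep(list(
    list(stock_ugml = 1250, aliquot_mL = 5, final_mL = 250))), 25)
  expect_equal(solution_prep(list(
    list(stock_ugml = 100, aliquot_mL = 10, final_mL = 10))), 100)
  expect_equal(solution_prep(list(
    list(mass_mg = 20, final_mL = 100),
    list(aliquot_mL = 0.5, final_mL = 10))), 10)
  expect_equal(solution_prep(list(
    list(mass_mg = 15, final_mL = 100),
    list(aliquot_mL = 0.5, final_mL = 10))), 7.5)
  expect_error(solution_prep(list(
    list(stock_ugml = 10, aliquot_mL = -1, final_mL = 5))), "non-positive")
  expect_error(solution_prep(list(
    list(stock_ugml = 10, aliquot_mL = 6, final_mL = 5))), "exceeds")
})
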