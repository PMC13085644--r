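test_that("error metrics match hand values and the summation oracle", {
  p <- prediction_set(c(3, 4), c(4, 3))   # errors (+1, -1)
  expect_equal(rmse(p), 1)
  expect_equal(rmse(prediction_set(1:5, 1:5)), 0)
  expect_error(rmse(prediction_set(numeric(0), numeric(0))), "empty")

  bs <- bias_sec(prediction_set(c(1, 3), c(1, 1)))   # errors (0, 2)
  expect_equal(bs$bias, 1)
  expect_equal(bs$sec, sqrt(2))
  cst <- bias_sec(prediction_set(c(1, 2, 3), c(0.5, 1.5, 2.5)))
  expect_equal(cst$bias, 0.5); expect_equal(cst$sec, 0)
  flip <- bias_sec(prediction_set(c(1, 3), c(1, 5)))  # errors (0, -2)
  expect_equal(flip$bias, -1); expect_equal(flip$sec, sqrt(2))
  expect_error(bias_sec(prediction_set(1, 1)), "n >= 2")

  expect_equal(rrmsep(prediction_set(c(3, 4), c(3, 5))), 20)
  expect_equal(rrmsep(prediction_set(1:5, 1:5)), 0)
  p1 <- prediction_set(c(2, 5, 9), c(2.2, 4.6, 9.3))
  expect_equal(rrmsep(p1),
               rrmsep(prediction_set(c(2, 5, 9) * 1000,
                                     c(2.2, 4.6, 9.3) * 1000)))
  expect_error(rrmsep(prediction_set(c(0, 0), c(1, 1))), "zero")

  expect_equal(bcrmsep(prediction_set(c(1, 3), c(1, 1))), 1)  # errors 0,2
  expect_equal(bcrmsep(prediction_set(c(1, 2), c(0.9, 1.9))), 0)

  # random instances against direct summation oracles
  set.seed(17)
  for (i in 1:10) {
    a <- runif(9, 1, 20); b <- a + rnorm(9, 0.1, 0.4)
    pp <- prediction_set(a, b)
    e <- a - b
    expect_equal(rmse(pp), sqrt(sum(e^2) / 9), tolerance = 1e-12)
    expect_equal(rrmsep(pp), 100 * sqrt(sum(e^2) / sum(a^2)),
                 tolerance = 1e-12)
    # Pythagorean identity with the n denominator
    expect_equal(mean(e)^2 + bcrmsep(pp)^2, rmse(pp)^2, tolerance = 1e-12)
  }
})

test_that("recovery statistics and the bias t-test follow the footnote formulas", {
  r <- recovery_stats(prediction_set(c(10, 10), c(9.9, 10.1)))
  expect_equal(r$mean, 100)
  expect_equal(r$sd, sqrt(2))
  d <- recovery_stats(prediction_set(c(5, 8), 2 * c(5, 8)))
  expect_equal(d$mean, 200)
  expect_error(recovery_stats(prediction_set(c(0, 1), c(1, 1))), "zero")

  # one perturbed value keeps sd > 0; bias is far from significant
  tt <- bias_t_test(c(rep(100, 12), 100.001))
  expect_lt(tt$t_exp, min(tt$critical))
  expect_false(any(tt$significant))
  expect_equal(unname(round(bias_t_test(rnorm(13, 100))$critical, 3)),
               c(2.179, 3.055))
  # formula check against an explicit computation
  rec <- c(98.5, 101.2, 99.8, 100.4, 97.9)
  tt2 <- bias_t_test(rec)
  expect_equal(tt2$t_exp, abs(100 - mean(rec)) * sqrt(5) / sd(rec))
  expect_true(bias_t_test(rep(101, 5))$infinite_t)
})

test_that("NAS detection limits keep the 3.3 / 10 ratio", {
  b <- c(0.2, -0.1, 0.4)
  ll <- lod_loq(b, 0.003)
  expect_equal(ll$lod, 3.3 * 0.003 * sqrt(sum(b^2)))
  expect_equal(ll$loq / ll$lod, 10 / 3.3)
  expect_equal(lod_loq(b, 0)$lod, 0)
  expect_equal(lod_loq(2 * b, 0.006)$lod, 4 * ll$lod)
  expect_error(lod_loq(c(0, 0), 1), "zero-norm")
})

test_that("linearity statistics equal the closed-form oracle", {
  p <- prediction_set(1:6, 2 * (1:6) + 1)
  ls <- linearity_stats(p)
  expect_equal(ls$slope, 2); expect_equal(ls$intercept, 1)
  expect_equal(ls$r_squared, 1)
  set.seed(23)
  a <- runif(12, 1, 20); b <- 0.97 * a + 0.2 + rnorm(12, 0, 0.3)
  ls2 <- linearity_stats(prediction_set(a, b))
  fit <- lm(b ~ a)
  expect_equal(ls2$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(ls2$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
  expect_equal(ls2$r_squared, summary(fit)$r.squared, tolerance = 1e-12)
  expect_error(linearity_stats(prediction_set(c(1, 1, 1), c(1, 2, 3))),
               "constant")
})

test_that("one-way ANOVA matches stats::anova and the t^2 identity", {
  g1 <- c(99.1, 100.4, 100.9, 99.7)
  g2 <- c(100.8, 101.4, 99.9, 100.6)
  g3 <- c(98.9, 99.5, 100.2, 99.8)
  res <- one_way_anova(list(g1, g2, g3))
  df <- data.frame(y = c(g1, g2, g3),
                   g = factor(rep(1:3, each = 4)))
  ref <- anova(lm(y ~ g, df))
  expect_equal(res$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)
  # two groups: F = t^2
  tt <- t.test(g1, g2, var.equal = TRUE)
  res2 <- one_way_anova(list(g1, g2))
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  # permutation invariance and identical groups
  expect_equal(one_way_anova(list(g3, g1, g2))$F, res$F)
  same <- one_way_anova(list(c(1, 2), c(1, 2)))
  expect_equal(same$F, 0); expect_equal(same$p_value, 1)
  expect_error(one_way_anova(list(g1)), "2 groups")
  expect_error(one_way_anova(list(g1, 1)), "n >= 2")
})

test_that("fom_record bundles the validation sheet for one analyte", {
  s <- sim_calval(noise_sd = 0.003)
  m <- fit_cls(s$calib$absorbance, s$calib_conc)
  pc <- predict_cls(m, s$calib$absorbance)
  pv <- predict_cls(m, s$valid$absorbance)
  rec <- fom_record(
    prediction_set(s$calib_conc[, "CIN"], pc[, "CIN"], "CIN", "calibration"),
    prediction_set(s$valid_conc[, "CIN"], pv[, "CIN"], "CIN", "validation"),
    b = rnorm(81, 0, 0.05), noise_sd = 0.003)
  expect_s3_class(rec, "fom_record")
  expect_equal(rec$loq / rec$lod, 10 / 3.3)
  expect_true(rec$r_squared > 0.99)
  expect_equal(rec$bias^2 + rec$bcrmsep^2, rec$rmsep^2, tolerance = 1e-10)
  expect_equal(unname(round(rec$t_critical, 3)), c(2.179, 3.055))
})
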