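#' Pair of true and predicted concentrations
#'
#' @param actual,predicted Equal-length numeric vectors (ug/mL).
#' @param analyte Analyte name.
#' @param label Set label, `"calibration"` or `"validation"`.
#' @return Object of class `prediction_set`.
#' @export
prediction_set <- function(actual, predicted, analyte = "",
                           label = c("validation", "calibration")) {
  if (length(actual) != length(predicted))
    stop("length mismatch", call. = FALSE)
  structure(list(actual = as.numeric(actual),
                 predicted = as.numeric(predicted),
                 analyte = analyte, label = match.arg(label),
                 n = length(actual)), class = "prediction_set")
}

.as_pset <- function(p) {
  if (inherits(p, "prediction_set")) return(p)
  stop("expected a prediction_set", call. = FALSE)
}

#' Root mean square error
#'
#' `RMSE = sqrt(sum((E_i - Ehat_i)^2) / n)`; labelled RMSEC, RMSECV or
#' RMSEP depending on which set the pairs come from.
#' @param p A [prediction_set()].
#' @export
rmse <- function(p) {
  p <- .as_pset(p)
  if (p$n < 1) stop("empty prediction set", call. = FALSE)
  sqrt(mean((p$actual - p$predicted)^2))
}

#' Bias and standard error of calibration
#'
#' `bias = mean(E - Ehat)`; `SEC = sqrt(sum((E - Ehat - bias)^2) / (n-1))`.
#' @param p A [prediction_set()] with n >= 2.
#' @return Named list `bias`, `sec`.
#' @export
bias_sec <- function(p) {
  p <- .as_pset(p)
  if (p$n < 2) stop("need n >= 2", call. = FALSE)
  e <- p$actual - p$predicted
  b <- mean(e)
  list(bias = b, sec = sqrt(sum((e - b)^2) / (p$n - 1)))
}

#' Relative root mean square error of prediction (percent)
#'
#' `RRMSEP = 100 * sqrt(sum((E - Ehat)^2) / sum(E^2))`; invariant under a
#' common unit rescaling of both vectors.
#' @param p A [prediction_set()].
#' @export
rrmsep <- function(p) {
  p <- .as_pset(p)
  if (sum(p$actual^2) <= 0) stop("all-zero truth", call. = FALSE)
  100 * sqrt(sum((p$actual - p$predicted)^2) / sum(p$actual^2))
}

#' Bias-corrected root mean square error of prediction
#'
#' `BCRMSEP = sqrt(sum((E - Ehat - bias)^2) / n)` over the validation set
#' (n denominator, so that `bias^2 + BCRMSEP^2 = RMSEP^2` holds exactly).
#' @param p A [prediction_set()] with n >= 2.
#' @export
bcrmsep <- function(p) {
  p <- .as_pset(p)
  if (p$n < 2) stop("need n >= 2", call. = FALSE)
  e <- p$actual - p$predicted
  sqrt(mean((e - mean(e))^2))
}

#' Recovery statistics
#'
#' Percent recoveries `R_i = 100 * Ehat_i / E_i`; returns their mean,
#' standard deviation (n-1) and RSD.
#' @param p A [prediction_set()] with strictly positive truth.
#' @return Named list `recoveries`, `mean`, `sd`, `rsd`.
#' @export
recovery_stats <- function(p) {
  p <- .as_pset(p)
  if (any(p$actual <= 0)) stop("zero or negative truth", call. = FALSE)
  r <- 100 * p$predicted / p$actual
  list(recoveries = r, mean = mean(r), sd = stats::sd(r),
       rsd = 100 * stats::sd(r) / mean(r))
}

#' Bias significance test on recoveries
#'
#' `t_exp = |100 - mean(R)| * sqrt(n) / sd(R)` compared against two-tailed
#' Student-t critical values at n-1 degrees of freedom.
#' @param recoveries Vector of percent recoveries (n >= 2).
#' @param alpha Significance levels (default 0.05 and 0.01).
#' @return List `t_exp`, `df`, `critical` (named by alpha), `significant`
#'   (logical per alpha), `infinite_t` flag when sd(R) = 0.
#' @export
bias_t_test <- function(recoveries, alpha = c(0.05, 0.01)) {
  n <- length(recoveries)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  s <- stats::sd(recoveries)
  crit <- stats::qt(1 - alpha / 2, df = n - 1)
  names(crit) <- paste0("alpha_", alpha)
  if (s == 0) {
    return(list(t_exp = Inf, df = n - 1, critical = crit,
                significant = abs(mean(recoveries) - 100) > 0 & rep(TRUE, length(alpha)),
                infinite_t = TRUE))
  }
  t_exp <- abs(100 - mean(recoveries)) * sqrt(n) / s
  list(t_exp = t_exp, df = n - 1, critical = crit,
       significant = t_exp > crit, infinite_t = FALSE)
}

#' Net-analyte-signal detection and quantification limits
#'
#' `LOD = 3.3 * sd * ||b||`, `LOQ = 10 * sd * ||b||`, where `b` is the
#' analyte's regression vector (mL/ug per AU) and `sd` the spectral noise
#' level (AU); thus LOQ/LOD = 10/3.3 exactly.
#' @param b Per-analyte regression vector.
#' @param noise_sd Spectral noise standard deviation (AU, >= 0).
#' @return Named list `lod`, `loq` (ug/mL).
#' @export
lod_loq <- function(b, noise_sd) {
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("zero-norm regression vector", call. = FALSE)
  if (noise_sd < 0) stop("negative noise sd", call. = FALSE)
  list(lod = 3.3 * noise_sd * nb, loq = 10 * noise_sd * nb)
}

#' Predicted-versus-actual regression line
#'
#' OLS of predicted on actual concentrations: slope, intercept and r^2.
#' @param p A [prediction_set()] with n >= 3 and non-constant truth.
#' @return Named list `slope`, `intercept`, `r_squared`.
#' @export
linearity_stats <- function(p) {
  p <- .as_pset(p)
  if (p$n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(p$actual) == 0) stop("constant truth", call. = FALSE)
  x <- p$actual; y <- p$predicted
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  icpt <- mean(y) - slope * mean(x)
  ssr <- sum((y - icpt - slope * x)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  list(slope = slope, intercept = icpt, r_squared = r2)
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition over >= 2 groups.
#' @param groups List of numeric vectors (each n >= 2).
#' @return Named list `F`, `p_value`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs n >= 2", call. = FALSE)
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  grand <- mean(x)
  means <- vapply(groups, mean, 0)
  ns <- vapply(groups, length, 1L)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((x - means[g])^2)
  dfb <- length(groups) - 1
  dfw <- length(x) - length(groups)
  if (ssw == 0 && ssb == 0) return(list(F = 0, p_value = 1,
                                        df_between = dfb, df_within = dfw))
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, p_value = stats::pf(Fv, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw)
}

#' Assemble a per-analyte figures-of-merit record
#'
#' Bundles the validation-sheet metrics for one analyte under one model:
#' calibration line, RMSEC/RMSEP/RRMSEP/BCRMSEP, bias, SEC, recovery
#' statistics with the bias t-test, and (when `b` and `noise_sd` are
#' given) NAS detection limits.
#'
#' @param calib,valid [prediction_set()]s for the calibration and
#'   validation sets of one analyte.
#' @param b Optional regression vector for [lod_loq()].
#' @param noise_sd Optional spectral noise sd (AU).
#' @return Object of class `fom_record` (a named list of scalars plus the
#'   recovery vector).
#' @export
fom_record <- function(calib, valid, b = NULL, noise_sd = NULL) {
  lin <- linearity_stats(calib)
  bs_c <- bias_sec(calib)
  rec_v <- recovery_stats(valid)
  rec_c <- recovery_stats(calib)
  tt <- bias_t_test(rec_v$recoveries)
  out <- list(
    analyte = valid$analyte,
    slope = lin$slope, intercept = lin$intercept, r_squared = lin$r_squared,
    mean_recovery_calibration = rec_c$mean, sd_recovery_calibration = rec_c$sd,
    mean_recovery_validation = rec_v$mean, sd_recovery_validation = rec_v$sd,
    rmsec = rmse(calib), rmsep = rmse(valid),
    rrmsep = rrmsep(valid), bcrmsep = bcrmsep(valid),
    bias = mean(valid$actual - valid$predicted), sec = bs_c$sec,
    t_exp = tt$t_exp, t_critical = tt$critical,
    recoveries_validation = rec_v$recoveries)
  if (!is.null(b) && !is.null(noise_sd)) {
    ll <- lod_loq(b, noise_sd)
    out$lod <- ll$lod; out$loq <- ll$loq
  }
  structure(out, class = "fom_record")
}
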