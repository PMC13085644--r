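#' Cross-validation plan
#'
#' @param scheme `"venetian"` (interleaved: sample i goes to fold
#'   `i mod k`) or `"loo"` (leave-one-out).
#' @param k Number of splits for venetian blinds (default 5).
#' @return Object of class `cv_plan`.
#' @export
cv_plan <- function(scheme = c("venetian", "loo"), k = 5L) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, k = as.integer(k)), class = "cv_plan")
}

#' Fold index sets of a plan
#' @param plan A [cv_plan()].
#' @param n Number of samples.
#' @return List of integer vectors partitioning `1:n`.
#' @export
cv_folds <- function(plan, n) {
  if (plan$scheme == "loo") return(as.list(seq_len(n)))
  k <- min(plan$k, n)
  unname(split(seq_len(n), (seq_len(n) - 1L) %% k))
}

#' Fit a PLS model by NIPALS
#'
#' Multi-response PLS2 on mean-centered data (no autoscaling: absorbance
#' units are homogeneous). The NIPALS start vector is the response column
#' of largest variance, making the fit deterministic. Per-analyte
#' regression vectors `b` satisfy `yhat = (A - colmeans) %*% b + intercept`.
#'
#' @param A Samples x wavelengths absorbance matrix.
#' @param C Samples x analytes concentration matrix.
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @return Object of class `pls_model`: `n_lv`, `weights` (W), `loadings`
#'   (P), `scores` (T), `y_loadings` (Q), `b` (wavelengths x analytes),
#'   `x_center`, `y_center`, `intercept` (per analyte), training `rmsec`.
#' @export
fit_pls <- function(A, C, n_lv) {
  A <- as.matrix(A); C <- as.matrix(C)
  if (is.null(colnames(C))) colnames(C) <- paste0("y", seq_len(ncol(C)))
  n <- nrow(A)
  if (nrow(C) != n) stop("sample count mismatch", call. = FALSE)
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > min(n - 1L, ncol(A)))
    stop("n_lv out of range", call. = FALSE)
  x_center <- colMeans(A); y_center <- colMeans(C)
  X <- sweep(A, 2, x_center); Y <- sweep(C, 2, y_center)
  if (sum(X^2) < 1e-300)
    stop("degenerate input: zero-variance spectral data", call. = FALSE)
  p <- ncol(X); m <- ncol(Y)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); Q <- matrix(0, m, n_lv)
  Xk <- X; Yk <- Y
  for (a in seq_len(n_lv)) {
    u <- Yk[, which.max(apply(Yk, 2, stats::var))]
    if (sum(u^2) < 1e-300) u <- Xk[, which.max(colSums(Xk^2))]
    for (it in 1:500) {
      w <- crossprod(Xk, u); w <- w / sqrt(sum(w^2))
      tt <- Xk %*% w
      q <- crossprod(Yk, tt) / sum(tt^2)
      u_new <- if (m == 1L) Yk[, 1] else Yk %*% q / sum(q^2)
      if (sum((u_new - u)^2) <= 1e-24 * max(sum(u^2), 1e-300)) { u <- u_new; break }
      u <- u_new
    }
    pp <- crossprod(Xk, tt) / sum(tt^2)
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; Q[, a] <- q
    Xk <- Xk - tcrossprod(tt, pp)
    Yk <- Yk - tcrossprod(tt, q)
  }
  # b = W (P'W)^-1 Q'
  B <- W %*% solve(crossprod(P, W), t(Q))
  colnames(B) <- colnames(C)
  fitted <- sweep(X %*% B, 2, y_center, "+")
  structure(list(
    n_lv = n_lv, weights = W, loadings = P, scores = Tm, y_loadings = Q,
    b = B, x_center = x_center, y_center = y_center,
    intercept = y_center - as.numeric(crossprod(B, x_center)),
    components = colnames(C),
    rmsec = sqrt(colMeans((fitted - C)^2))), class = "pls_model")
}

#' Predict concentrations from a PLS model
#' @param model A `pls_model`.
#' @param A Samples x wavelengths absorbance matrix on the training grid.
#' @return Samples x analytes concentration matrix.
#' @export
predict_pls <- function(model, A) {
  A <- as.matrix(A)
  if (ncol(A) != length(model$x_center))
    stop("wavelength grid mismatch", call. = FALSE)
  sweep(sweep(A, 2, model$x_center) %*% model$b, 2, model$y_center, "+")
}

#' RMSECV curve over latent-variable counts
#'
#' Pooled (over analytes and folds) root mean square error of
#' cross-validation for each LV count in `lv_range`. If a training fold is
#' too small for the requested LVs the fold is capped at its maximum and a
#' warning is recorded in the `capped` attribute.
#'
#' @param A,C Calibration spectra and concentrations.
#' @param lv_range Integer vector of LV counts (default 1:10).
#' @param cv A [cv_plan()] (default 5-split venetian blinds).
#' @return Named numeric vector RMSECV(k); attribute `capped` lists folds
#'   where the LV count was reduced.
#' @export
rmsecv_curve <- function(A, C, lv_range = 1:10,
                         cv = cv_plan("venetian", 5L)) {
  A <- as.matrix(A); C <- as.matrix(C)
  folds <- cv_folds(cv, nrow(A))
  sq <- matrix(0, length(lv_range), 1)
  cnt <- 0
  capped <- character(0)
  preds <- array(NA_real_, c(nrow(A), ncol(C), length(lv_range)))
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    tr <- setdiff(seq_len(nrow(A)), fold)
    max_lv_fold <- min(length(tr) - 1L, ncol(A))
    for (ki in seq_along(lv_range)) {
      k <- min(lv_range[ki], max_lv_fold)
      if (k < lv_range[ki])
        capped <- c(capped, sprintf("fold %d: LV %d capped at %d",
                                    fi, lv_range[ki], k))
      m <- fit_pls(A[tr, , drop = FALSE], C[tr, , drop = FALSE], k)
      preds[fold, , ki] <- predict_pls(m, A[fold, , drop = FALSE])
    }
  }
  out <- vapply(seq_along(lv_range), function(ki)
    sqrt(mean((preds[, , ki] - C)^2)), 0)
  names(out) <- lv_range
  # fold-to-fold scatter of the per-fold RMSE: standard error of the
  # pooled estimate, used by the global-min tie rule (1-SE convention)
  fold_rmse <- vapply(seq_along(lv_range), function(ki)
    vapply(folds, function(fold)
      sqrt(mean((preds[fold, , ki] - C[fold, , drop = FALSE])^2)), 0),
    numeric(length(folds)))
  attr(out, "se") <- apply(fold_rmse, 2, stats::sd) / sqrt(length(folds))
  if (length(capped)) {
    warning("some folds were too small for the requested LVs; capped")
    attr(out, "capped") <- unique(capped)
  }
  out
}

#' Select the number of latent variables from an RMSECV curve
#'
#' @param curve Output of [rmsecv_curve()].
#' @param rule `"global-min"`: argmin of the curve, ties (within a 1e-6
#'   relative band) resolved toward fewer LVs. `"parsimonious-F"`: the
#'   smallest k whose PRESS ratio to the global minimum is below the
#'   F quantile at `alpha` (Haaland-Thomas style).
#' @param alpha Significance level for the F rule (default 0.25).
#' @param n Number of calibration samples (needed for the F rule).
#' @return Selected LV count (integer).
#' @export
select_lv <- function(curve, rule = c("global-min", "parsimonious-F"),
                      alpha = 0.25, n = NULL) {
  rule <- match.arg(rule)
  if (!length(curve)) stop("empty curve", call. = FALSE)
  ks <- as.integer(names(curve))
  if (any(is.na(ks))) ks <- seq_along(curve)
  if (rule == "global-min") {
    # ties resolve toward fewer LVs; "tie" means within one standard
    # error of the minimum when the curve carries fold scatter (1-SE
    # convention), else within numerical tolerance
    se <- attr(curve, "se")
    tol <- if (!is.null(se)) se[which.min(curve)]
           else max(1e-12, min(curve) * 1e-6)
    return(ks[which(curve <= min(curve) + tol)[1]])
  }
  if (is.null(n)) stop("parsimonious-F rule needs n", call. = FALSE)
  press <- curve^2 * n
  fstat <- press / min(press)
  fcrit <- stats::qf(1 - alpha, n, n)
  ks[which(fstat < fcrit)[1]]
}
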