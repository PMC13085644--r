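#' Fit a classical least squares (K-matrix) calibration model
#'
#' Direct Beer-Lambert calibration: at every wavelength the absorbance is
#' regressed on the known concentrations, `A ~ [1 | C] [k0; K]`, giving the
#' pure-analyte sensitivity matrix K (components x wavelengths) and, when
#' `intercept = TRUE`, an intercept spectrum `k0` absorbing constant
#' baseline contributions.
#'
#' @param A Samples x wavelengths absorbance matrix (AU).
#' @param C Samples x components concentration matrix (ug/mL).
#' @param intercept Include an intercept spectrum (default TRUE).
#' @param window Optional moving-average smoothing width in grid points
#'   (odd); spectra are smoothed before fitting and before prediction.
#' @return Object of class `cls_model` with `K`, `intercept_spectrum`
#'   (NULL when off), `window`, residual statistics, and training shapes.
#' @export
fit_cls <- function(A, C, intercept = TRUE, window = NULL) {
  A <- as.matrix(A); C <- as.matrix(C)
  if (nrow(A) != nrow(C)) stop("sample count mismatch", call. = FALSE)
  need <- ncol(C) + as.integer(intercept)
  if (nrow(A) <= need)
    stop("need more samples than components (+ intercept)", call. = FALSE)
  q <- qr(if (intercept) cbind(1, C) else C)
  if (q$rank < need) {
    piv <- q$pivot[seq_len(q$rank)]
    bad <- setdiff(seq_len(need), piv)
    nm <- if (intercept) c("(intercept)", colnames(C)) else colnames(C)
    stop("collinear concentration design; offending columns: ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.null(window)) A <- smooth_spectra(A, window)
  B <- qr.coef(q, A)                       # (components [+1]) x wavelengths
  fitted <- (if (intercept) cbind(1, C) else C) %*% B
  structure(list(
    K = if (intercept) B[-1, , drop = FALSE] else B,
    intercept_spectrum = if (intercept) B[1, ] else NULL,
    window = window,
    components = colnames(C),
    n_wavelengths = ncol(A),
    residual_sd = stats::sd(A - fitted)), class = "cls_model")
}

#' Predict concentrations from a CLS model
#'
#' Each unknown spectrum (minus the intercept spectrum, if fitted) is
#' projected onto the K rows by least squares.
#'
#' @param model A `cls_model`.
#' @param A Samples x wavelengths absorbance matrix on the training grid.
#' @return Samples x components concentration matrix.
#' @export
predict_cls <- function(model, A) {
  A <- as.matrix(A)
  if (ncol(A) != model$n_wavelengths)
    stop("wavelength grid mismatch", call. = FALSE)
  if (!is.null(model$window)) A <- smooth_spectra(A, model$window)
  if (!is.null(model$intercept_spectrum))
    A <- sweep(A, 2, model$intercept_spectrum, "-")
  Ct <- qr.coef(qr(t(model$K)), t(A))      # solve K' c = a per sample
  C <- t(Ct)
  colnames(C) <- model$components
  C
}

#' Moving-average smoothing of spectra
#'
#' @param A Samples x wavelengths matrix.
#' @param window Width in grid points, odd; 1 is the identity. Edges are
#'   padded by replication.
#' @export
smooth_spectra <- function(A, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 1L)
    stop("window must be a positive odd number of points", call. = FALSE)
  A <- as.matrix(A)
  if (window == 1L) return(A)
  if (window > ncol(A)) stop("window exceeds spectrum length", call. = FALSE)
  half <- (window - 1L) %/% 2L
  t(apply(A, 1, function(y) {
    ypad <- c(rep(y[1], half), y, rep(y[length(y)], half))
    out <- stats::filter(ypad, rep(1 / window, window), sides = 2)
    as.numeric(out[(half + 1):(half + length(y))])
  }))
}

#' Cross-validated moving-window width selection for CLS
#'
#' For each candidate width the spectra are moving-average smoothed, a CLS
#' model is fitted, and the pooled RMSECV over the plan's folds is
#' computed; the width minimizing pooled RMSECV wins (ties -> smaller
#' width).
#'
#' @param A,C Calibration spectra and concentrations.
#' @param widths Candidate widths in nm (converted to points via
#'   `grid_step`); each must map to an odd point count. Default 5-29 nm.
#' @param cv A [cv_plan()].
#' @param grid_step Grid step in nm (default 1).
#' @param intercept Passed to [fit_cls()].
#' @return List with `width` (best width, nm), `rmsecv` (named vector over
#'   widths), and `model` (CLS model refitted on all data at that width).
#' @export
moving_window_select <- function(A, C, widths = seq(5, 29, by = 2),
                                 cv = cv_plan("venetian", 5L),
                                 grid_step = 1, intercept = TRUE) {
  A <- as.matrix(A); C <- as.matrix(C)
  pts <- widths / grid_step
  if (any(abs(pts - round(pts)) > 1e-8) || any(round(pts) %% 2 == 0))
    stop("widths must be odd multiples of the grid step", call. = FALSE)
  pts <- as.integer(round(pts))
  if (any(pts > ncol(A))) stop("window exceeds spectrum length", call. = FALSE)
  folds <- cv_folds(cv, nrow(A))
  rmsecv <- vapply(pts, function(w) {
    sq <- 0; cnt <- 0
    for (fold in folds) {
      tr <- setdiff(seq_len(nrow(A)), fold)
      m <- fit_cls(A[tr, , drop = FALSE], C[tr, , drop = FALSE],
                   intercept = intercept, window = w)
      pred <- predict_cls(m, A[fold, , drop = FALSE])
      sq <- sq + sum((pred - C[fold, , drop = FALSE])^2)
      cnt <- cnt + length(fold) * ncol(C)
    }
    sqrt(sq / cnt)
  }, 0)
  names(rmsecv) <- widths
  # ties -> smaller width; absolute floor so the noiseless all-zero case ties
  tol <- max(1e-8, min(rmsecv) * 1e-6)
  best <- which(rmsecv <= min(rmsecv) + tol)[1]
  list(width = widths[best], rmsecv = rmsecv,
       model = fit_cls(A, C, intercept = intercept, window = pts[best]))
}
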