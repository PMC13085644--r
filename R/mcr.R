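#' Non-negative least squares (Lawson-Hanson)
#'
#' Solves `min ||A x - b||` subject to `x >= 0` by the active-set
#' algorithm. Small dense problems only (the MCR sub-problems here have as
#' many unknowns as chemical components).
#'
#' @param A Design matrix (m x n).
#' @param b Right-hand side (length m).
#' @return Coefficient vector (length n, >= 0).
#' @export
nnls_solve <- function(A, b) {
  A <- as.matrix(A); b <- as.numeric(b)
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  tol <- 1e-12 * max(abs(w), 1)
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      P <- which(passive)
      s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      s[P][is.na(s[P])] <- 0
      if (all(s[P] > tol)) { x <- s; break }
      neg <- P[s[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { x <- numeric(n); break }
    }
    w <- crossprod(A, b - A %*% x)
  }
  pmax(x, 0)
}

#' Evolving factor analysis
#'
#' Forward trace: singular values of growing leading submatrices
#' `D[1:i, ]`; backward trace: growing trailing submatrices. Eigenvalues
#' (squared singular values) are normalized to the largest eigenvalue of
#' the full matrix before log10 thresholding. The estimated rank is the
#' number of full-size eigenvalues above the threshold. An initial
#' concentration estimate is assembled from the window envelopes
#' (component j: `min(forward_j, backward_(rank - j + 1))`).
#'
#' @param D Samples x wavelengths data matrix (>= 2 samples).
#' @param log10_threshold Threshold on log10 normalized eigenvalues
#'   (default -4).
#' @param max_rank Cap on traced components (default 10).
#' @return List: `rank`, `forward` and `backward` log10-normalized
#'   eigenvalue traces (samples x max_rank), `C_init` (samples x rank; NULL
#'   when rank is 0), `degenerate` flag (TRUE when the envelope columns are
#'   near-collinear, i.e. no evolving structure).
#' @export
efa <- function(D, log10_threshold = -4, max_rank = 10L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("need >= 2 samples", call. = FALSE)
  k <- min(max_rank, n, ncol(D))
  sv_full <- svd(D, nu = 0, nv = 0)$d
  ev_ref <- sv_full[1]^2
  fwd <- matrix(NA_real_, n, k)
  bwd <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    sf <- svd(D[1:i, , drop = FALSE], nu = 0, nv = 0)$d
    sb <- svd(D[(n - i + 1):n, , drop = FALSE], nu = 0, nv = 0)$d
    fwd[i, seq_len(min(k, length(sf)))] <- sf[seq_len(min(k, length(sf)))]^2
    bwd[n - i + 1, seq_len(min(k, length(sb)))] <- sb[seq_len(min(k, length(sb)))]^2
  }
  lf <- log10(pmax(fwd / ev_ref, 1e-300))
  lb <- log10(pmax(bwd / ev_ref, 1e-300))
  full_ev <- log10(pmax(sv_full^2 / ev_ref, 1e-300))
  rank <- sum(full_ev > log10_threshold)
  if (rank == 0L) {
    warning("threshold above all eigenvalues: rank 0, degenerate windows")
    return(list(rank = 0L, forward = lf, backward = lb,
                C_init = NULL, degenerate = TRUE))
  }
  rank <- min(rank, k)
  C0 <- sapply(seq_len(rank), function(j) {
    f <- ifelse(is.na(lf[, j]), -Inf, lf[, j])
    b <- ifelse(is.na(lb[, rank - j + 1]), -Inf, lb[, rank - j + 1])
    env <- pmin(f, b)
    pmax(10^(env / 2), 0) * (env > log10_threshold)  # back to sv scale
  })
  C0 <- matrix(C0, n, rank)
  # degenerate when envelope columns are (near-)collinear: no evolving
  # structure, as in calibration-mixture data where every component is
  # present in every sample
  degenerate <- rank > 1 && {
    cs <- sqrt(colSums(C0^2))
    ok <- cs > 0
    if (sum(ok) < rank) TRUE else {
      G <- crossprod(sweep(C0, 2, cs, "/"))
      min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < 1e-6
    }
  }
  list(rank = rank, forward = lf, backward = lb, C_init = C0,
       degenerate = degenerate)
}

#' Constraint set for MCR-ALS
#'
#' @param nonneg_c,nonneg_s Non-negativity of concentration profiles /
#'   spectral profiles (default TRUE, TRUE).
#' @param closure Closure total for concentration rows (row sums forced to
#'   this value after each C update); NULL disables (default: mixture
#'   concentrations here are not mass-closed).
#' @param unimodal_s Force each resolved spectrum to a single maximum via
#'   monotone-regression flattening (default FALSE).
#' @param selectivity Optional list, one entry per component, each either
#'   NULL or a list with `windows` (2-column matrix of wavelength index
#'   ranges where ONLY that component absorbs is known; other components
#'   are zeroed there) or `reference` (spectrum the component is pinned
#'   to).
#' @export
constraint_set <- function(nonneg_c = TRUE, nonneg_s = TRUE, closure = NULL,
                           unimodal_s = FALSE, selectivity = NULL) {
  if (!is.null(closure) && closure <= 0)
    stop("closure total must be > 0", call. = FALSE)
  structure(list(nonneg_c = nonneg_c, nonneg_s = nonneg_s, closure = closure,
                 unimodal_s = unimodal_s, selectivity = selectivity),
            class = "constraint_set")
}

# Project a vector onto the unimodal cone about its maximum: monotone
# (isotonic) regression increasing up to the mode, decreasing after.
.unimodal_project <- function(y) {
  m <- which.max(y)
  up <- if (m > 1) .pava(y[1:m]) else y[1]
  down <- if (m < length(y)) rev(.pava(rev(y[m:length(y)]))) else y[length(y)]
  c(up, down[-1])
}

# Pool-adjacent-violators for nondecreasing fit (unit weights).
.pava <- function(y) {
  n <- length(y)
  lev <- 0L
  vals <- numeric(n); wts <- numeric(n); counts <- integer(n)
  for (i in seq_len(n)) {
    lev <- lev + 1L
    vals[lev] <- y[i]; wts[lev] <- 1; counts[lev] <- 1L
    while (lev > 1L && vals[lev - 1L] > vals[lev]) {
      w <- wts[lev - 1L] + wts[lev]
      vals[lev - 1L] <- (vals[lev - 1L] * wts[lev - 1L] + vals[lev] * wts[lev]) / w
      wts[lev - 1L] <- w
      counts[lev - 1L] <- counts[lev - 1L] + counts[lev]
      lev <- lev - 1L
    }
  }
  rep(vals[seq_len(lev)], counts[seq_len(lev)])
}

#' Fit a bilinear model by constrained alternating least squares (MCR-ALS)
#'
#' Decomposes `D = C S + E` (C: samples x components, S: components x
#' wavelengths) by alternating constrained least squares. Spectra are
#' renormalized to unit Euclidean norm each iteration (scale ambiguity
#' removed; the scale moves into C). Convergence: relative change of the
#' residual standard deviation between consecutive iterations below
#' `rel_tol` percent.
#'
#' @param D Samples x wavelengths data matrix.
#' @param ncomp Number of components.
#' @param init `"efa"` (EFA concentration windows; falls back to seeded
#'   random when the windows are degenerate), `"random"` (seeded random
#'   spectra), or a components x wavelengths matrix of reference spectra.
#' @param constraints A [constraint_set()].
#' @param rel_tol Convergence threshold, percent relative change of
#'   residual sd (default 0.20).
#' @param max_iter Maximum ALS iterations (default 50).
#' @param seed Seed for random initialization (default 1).
#' @return Object of class `mcr_model`: `C`, `S`, `E`, `iterations`,
#'   `rel_change` trajectory, `residual_sd` trajectory, `explained_variance`
#'   (percent), `lack_of_fit` (percent), `converged`, `constraints`,
#'   `init`, `seed`.
#' @export
fit_mcr_als <- function(D, ncomp, init = "efa",
                        constraints = constraint_set(),
                        rel_tol = 0.20, max_iter = 50L, seed = 1L) {
  D <- as.matrix(D)
  n <- nrow(D); m <- ncol(D)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("ncomp must be >= 1", call. = FALSE)

  init_label <- if (is.matrix(init)) "reference" else match.arg(init, c("efa", "random"))
  S <- NULL; C <- NULL
  if (is.matrix(init)) {
    if (nrow(init) != ncomp || ncol(init) != m)
      stop("init spectra shape mismatch", call. = FALSE)
    S <- init
  } else if (init_label == "efa") {
    e <- efa(D)
    if (!e$degenerate && e$rank >= ncomp && !is.null(e$C_init)) {
      C <- e$C_init[, seq_len(ncomp), drop = FALSE]
      if (any(colSums(C) == 0)) C <- NULL
    }
    if (is.null(C)) init_label <- "random(efa fallback)"
  }
  if (is.null(S) && is.null(C)) {  # seeded random spectra
    set.seed(seed)
    S <- matrix(abs(stats::rnorm(ncomp * m)), ncomp, m)
  }

  norm_rows <- function(M) {
    ns <- sqrt(rowSums(M^2)); ns[ns == 0] <- 1
    M / ns
  }
  solve_ls <- function(X, B) {
    # min ||X beta - B|| columnwise, unconstrained
    qr.coef(qr(X), B)
  }
  update_C <- function(S) {
    St <- t(S)
    if (constraints$nonneg_c) {
      C <- t(vapply(seq_len(n), function(i) nnls_solve(St, D[i, ]),
                    numeric(ncomp)))
    } else {
      C <- t(solve_ls(St, t(D)))
    }
    C <- matrix(C, n, ncomp)
    if (!is.null(constraints$closure)) {
      rs <- rowSums(C); rs[rs == 0] <- 1
      C <- C * (constraints$closure / rs)
    }
    C
  }
  update_S <- function(C) {
    if (constraints$nonneg_s) {
      S <- vapply(seq_len(m), function(j) nnls_solve(C, D[, j]),
                  numeric(ncomp))
    } else {
      S <- solve_ls(C, D)
    }
    S <- matrix(S, ncomp, m)
    if (constraints$unimodal_s)
      S <- t(apply(S, 1, .unimodal_project))
    if (!is.null(constraints$selectivity)) {
      for (cmp in seq_len(ncomp)) {
        sel <- constraints$selectivity[[cmp]]
        if (is.null(sel)) next
        if (!is.null(sel$reference)) S[cmp, ] <- sel$reference
        if (!is.null(sel$windows)) {
          for (r in seq_len(nrow(sel$windows))) {
            idx <- sel$windows[r, 1]:sel$windows[r, 2]
            S[-cmp, idx] <- 0     # only this component absorbs here
          }
        }
      }
    }
    S
  }

  if (is.null(S)) S <- update_S(pmax(C, 1e-12))
  S <- norm_rows(S)
  sd_old <- Inf
  rel_trace <- numeric(0); sd_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    C <- update_C(S)
    S <- norm_rows(update_S(C))
    C <- update_C(S)          # keep C consistent with normalized S
    E <- D - C %*% S
    sd_new <- stats::sd(as.numeric(E))
    sd_trace <- c(sd_trace, sd_new)
    rel <- if (is.finite(sd_old) && sd_old > 0)
      100 * abs(sd_old - sd_new) / sd_old else Inf
    if (sd_old < 1e-14) rel <- 0
    rel_trace <- c(rel_trace, rel)
    if (rel < rel_tol || sd_new < 1e-12) { converged <- TRUE; break }
    sd_old <- sd_new
  }
  E <- D - C %*% S
  ss_d <- sum(D^2)
  structure(list(
    C = C, S = S, E = E, iterations = it,
    rel_change = rel_trace, residual_sd = sd_trace,
    explained_variance = 100 * (1 - sum(E^2) / ss_d),
    lack_of_fit = 100 * sqrt(sum(E^2) / ss_d),
    converged = converged, constraints = constraints,
    init = init_label, seed = seed), class = "mcr_model")
}

#' Quantify test samples from an augmented-matrix MCR fit
#'
#' The model must have been fitted on the row-wise augmented matrix
#' `rbind(calibration, test)`. Resolved components are matched to analytes
#' by maximal total cosine similarity against reference spectra (over all
#' assignments; an ambiguous optimum raises an error); then for each
#' analyte, the resolved concentration column over the calibration rows is
#' regressed on the known concentrations and the fit is inverted for the
#' test rows. Any rotation-invariant rescaling of the resolved profiles is
#' absorbed by this regression.
#'
#' @param model An `mcr_model` fitted on `rbind(calib, test)` rows.
#' @param calib_conc Calibration concentrations (rows x analytes).
#' @param calib_rows,test_rows Row indices of the augmented matrix.
#' @param reference_spectra Analytes x wavelengths matrix used for
#'   component assignment (row names = analyte names).
#' @return Test-row concentration matrix (rows x analytes).
#' @export
mcr_quantify <- function(model, calib_conc, calib_rows, test_rows,
                         reference_spectra) {
  calib_conc <- as.matrix(calib_conc)
  R <- as.matrix(reference_spectra)
  k <- nrow(model$S)
  if (nrow(R) != ncol(calib_conc))
    stop("reference spectra / analyte count mismatch", call. = FALSE)
  if (ncol(calib_conc) > k)
    stop("more analytes than resolved components", call. = FALSE)
  cosm <- matrix(0, nrow(R), k)
  for (a in seq_len(nrow(R)))
    for (cmp in seq_len(k))
      cosm[a, cmp] <- cosine_similarity(R[a, ], model$S[cmp, ])
  # exhaustive assignment (k is small): maximize total cosine
  perms <- .permutations(k)
  scores <- vapply(seq_len(nrow(perms)), function(i)
    sum(cosm[cbind(seq_len(nrow(R)), perms[i, seq_len(nrow(R))])]), 0)
  best <- which.max(scores)
  if (sum(abs(scores - scores[best]) < 1e-10) > 1L) {
    tied <- perms[abs(scores - scores[best]) < 1e-10, seq_len(nrow(R)), drop = FALSE]
    if (nrow(unique(tied)) > 1L)
      stop("ambiguous component assignment", call. = FALSE)
  }
  assign <- perms[best, seq_len(nrow(R))]
  out <- matrix(NA_real_, length(test_rows), ncol(calib_conc),
                dimnames = list(NULL, colnames(calib_conc)))
  for (a in seq_len(ncol(calib_conc))) {
    x <- model$C[calib_rows, assign[a]]
    fit <- stats::lm.fit(cbind(1, x), calib_conc[, a])
    out[, a] <- cbind(1, model$C[test_rows, assign[a]]) %*% fit$coefficients
  }
  out
}

# all permutations of 1:k (k <= 7)
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}
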