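#' Cosine similarity of two spectra
#'
#' `cos(theta) = (a . b) / (||a|| ||b||)`; scale-invariant, in `[-1, 1]`.
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector", call. = FALSE)
  max(-1, min(1, sum(a * b) / (na * nb)))
}

#' Elliptical joint confidence region for slope and intercept
#'
#' OLS of predicted on actual gives estimates `(b0, b1)`; the joint
#' `(1 - alpha)` region is
#' `{beta : (beta - betahat)' X'X (beta - betahat) <= 2 s^2 F(2, n-2)}`
#' with `X = [1, actual]`. The method is unbiased at level alpha when the
#' region contains the ideal point (intercept 0, slope 1).
#'
#' @param p A [prediction_set()] with n >= 4 and non-constant truth.
#' @param alpha Significance level (default 0.05).
#' @param n_boundary Number of ellipse boundary points returned.
#' @return Object of class `ejcr_result`: `slope`, `intercept`,
#'   `shape` (X'X), `s2`, `radius2` (= 2 s^2 F), `confidence`,
#'   `contains_ideal`, `area`, `boundary` (n x 2, columns intercept/slope).
#' @export
ejcr <- function(p, alpha = 0.05, n_boundary = 181L) {
  p <- .as_pset(p)
  if (p$n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(p$actual) == 0) stop("constant truth", call. = FALSE)
  X <- cbind(1, p$actual)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, p$predicted))
  res <- p$predicted - X %*% beta
  s2 <- sum(res^2) / (p$n - 2)
  Fcrit <- stats::qf(1 - alpha, 2, p$n - 2)
  r2 <- 2 * s2 * Fcrit
  ideal <- c(0, 1)
  d <- ideal - as.numeric(beta)
  q_ideal <- as.numeric(t(d) %*% XtX %*% d)
  area <- if (r2 > 0) pi * r2 / sqrt(det(XtX)) else 0
  boundary <- NULL
  if (r2 > 0) {
    ei <- eigen(XtX, symmetric = TRUE)
    th <- seq(0, 2 * pi, length.out = n_boundary)
    circ <- rbind(cos(th), sin(th))
    axes <- ei$vectors %*% diag(sqrt(r2 / ei$values))
    boundary <- t(axes %*% circ + as.numeric(beta))
    colnames(boundary) <- c("intercept", "slope")
  }
  structure(list(slope = beta[2], intercept = beta[1], shape = XtX,
                 s2 = s2, radius2 = r2, confidence = 1 - alpha,
                 contains_ideal = q_ideal <= r2, area = area,
                 boundary = boundary), class = "ejcr_result")
}

# Signal-contribution function of component c for a transformed solution.
# Ct = C %*% solve(T), St = T %*% S; f_c = ||Ct[,c]|| * ||St[c,]|| / ||C S||_F.
.band_fvals <- function(C, S, Tm) {
  Ti <- tryCatch(solve(Tm), error = function(e) NULL)
  if (is.null(Ti)) return(NULL)
  Ct <- C %*% Ti
  St <- Tm %*% S
  denom <- sqrt(sum((C %*% S)^2))
  list(f = sqrt(colSums(Ct^2)) * sqrt(rowSums(St^2)) / denom,
       Ct = Ct, St = St)
}

# Constraint violation of a transformed solution, relative scale.
.band_violation <- function(sol, constraints) {
  v <- 0
  sC <- max(abs(sol$Ct)); sS <- max(abs(sol$St))
  if (isTRUE(constraints$nonneg_c) && sC > 0)
    v <- v + sum(pmin(sol$Ct / sC, 0)^2)
  if (isTRUE(constraints$nonneg_s) && sS > 0)
    v <- v + sum(pmin(sol$St / sS, 0)^2)
  if (isTRUE(constraints$unimodal_s)) {
    for (i in seq_len(nrow(sol$St))) {
      s <- sol$St[i, ]
      u <- .unimodal_project(s)
      if (sS > 0) v <- v + sum(((s - u) / sS)^2)
    }
  }
  if (!is.null(constraints$selectivity)) {
    for (cmp in seq_along(constraints$selectivity)) {
      sel <- constraints$selectivity[[cmp]]
      if (is.null(sel)) next
      if (!is.null(sel$windows)) {
        for (r in seq_len(nrow(sel$windows))) {
          idx <- sel$windows[r, 1]:sel$windows[r, 2]
          if (sS > 0)
            v <- v + sum((sol$St[-cmp, idx] / sS)^2)
        }
      }
      if (!is.null(sel$reference)) {
        cs <- cosine_similarity(sol$St[cmp, ], sel$reference)
        v <- v + max(0, 0.999 - cs)^2 * 1e4
      }
    }
  }
  v
}

#' Rotational-ambiguity feasible bands (MCR-BANDS style)
#'
#' For each component c, maximizes and minimizes the relative signal
#' contribution `f_c(T) = ||C t_c|| ||t_c^- S|| / ||C S||_F` over
#' invertible transforms T (off-diagonal entries free, diagonal fixed at
#' 1) whose rotated profiles satisfy the active constraints; the feasible
#' interval `[f_min, f_max]` quantifies rotational ambiguity:
#' `AFS% = 100 (f_max - f_min)`. Spectral band statistics (max/avg RFS,
#' critical wavelength) are the per-wavelength width of the component's
#' reconstructed contribution (AU, mean over samples) across the feasible
#' solutions encountered. Selectivity index: `1 - (f_max - f_min)/f_max`.
#'
#' Optimization: penalized Nelder-Mead with seeded multi-start; for k <= 2
#' a dense grid search over the two off-diagonal entries is used (also the
#' independent oracle in the tests).
#'
#' @param model An `mcr_model` (converged).
#' @param constraints A [constraint_set()]; defaults to the model's own.
#' @param wavelengths Optional wavelength vector for the critical
#'   wavelength (defaults to column index).
#' @param n_starts Multi-start count (default 20).
#' @param seed RNG seed.
#' @param grid_n Grid resolution per parameter for the k <= 2 fallback
#'   (default 101).
#' @param grid_range Half-range of off-diagonal grid (default 1.5).
#' @param method `"auto"` (grid for k <= 2, optimizer otherwise),
#'   `"grid"` (k <= 2 only) or `"optim"` (force the penalized optimizer,
#'   any k).
#' @return Object of class `ambiguity_result`: per-component `f_min`,
#'   `f_max`, `afs_percent`, `max_rfs`, `avg_rfs`, `critical_wavelength`,
#'   `selectivity_index`; plus `mean_afs`, `sd_afs`, `unresolved` flag.
#' @export
ambiguity_bands <- function(model, constraints = model$constraints,
                            wavelengths = NULL, n_starts = 20L, seed = 1L,
                            grid_n = 101L, grid_range = 1.5,
                            method = c("auto", "grid", "optim")) {
  method <- match.arg(method)
  C <- model$C; S <- model$S
  k <- ncol(C)
  m <- ncol(S)
  if (is.null(wavelengths)) wavelengths <- seq_len(m)
  if (k == 1L) {
    # scaling-only ambiguity is removed by normalization: no rotation
    sol <- .band_fvals(C, S, diag(1))
    return(structure(list(
      f_min = sol$f, f_max = sol$f, afs_percent = 0,
      max_rfs = 0, avg_rfs = 0,
      critical_wavelength = wavelengths[1],
      selectivity_index = 1, mean_afs = 0, sd_afs = NA_real_,
      unresolved = FALSE), class = "ambiguity_result"))
  }

  off <- which(diag(k) == 0)
  mk_T <- function(par) { Tm <- diag(k); Tm[off] <- par; Tm }
  feas_tol <- 1e-8
  sols <- list()
  add_sol <- function(sol) sols[[length(sols) + 1L]] <<- sol

  f_id <- .band_fvals(C, S, diag(k))
  v_id <- .band_violation(f_id, constraints)
  if (v_id < feas_tol) add_sol(f_id)

  fmin <- rep(NA_real_, k); fmax <- rep(NA_real_, k)
  unresolved <- FALSE

  use_grid <- (method == "grid") || (method == "auto" && k == 2L)
  if (use_grid && k > 2L)
    stop("grid method only available for k <= 2", call. = FALSE)
  if (use_grid) {
    arg_min <- vector("list", k); arg_max <- vector("list", k)
    scan <- function(as, bs, keep_sols) {
      for (a in as) for (b in bs) {
        Tm <- mk_T(c(b, a))     # off fills column-major: (2,1) then (1,2)
        if (abs(1 - a * b) < 1e-6) next
        sol <- .band_fvals(C, S, Tm)
        if (is.null(sol)) next
        if (.band_violation(sol, constraints) < feas_tol) {
          if (keep_sols) add_sol(sol)
          for (cmp in seq_len(k)) {
            if (is.na(fmin[cmp]) || sol$f[cmp] < fmin[cmp]) {
              fmin[cmp] <<- sol$f[cmp]; arg_min[[cmp]] <<- c(a, b)
            }
            if (is.na(fmax[cmp]) || sol$f[cmp] > fmax[cmp]) {
              fmax[cmp] <<- sol$f[cmp]; arg_max[[cmp]] <<- c(a, b)
            }
          }
        }
      }
    }
    g <- seq(-grid_range, grid_range, length.out = grid_n)
    scan(g, g, keep_sols = TRUE)
    # two local refinement passes around each extremum
    h <- g[2] - g[1]
    for (pass in 1:2) {
      for (pt in c(arg_min, arg_max)) {
        if (is.null(pt)) next
        scan(seq(pt[1] - h, pt[1] + h, length.out = 21L),
             seq(pt[2] - h, pt[2] + h, length.out = 21L),
             keep_sols = FALSE)
      }
      h <- h / 10
    }
    if (any(is.na(fmin))) unresolved <- TRUE
  } else {
    penal <- function(par, cmp, sign) {
      sol <- .band_fvals(C, S, mk_T(par))
      if (is.null(sol)) return(1e6)
      sign * sol$f[cmp] + 1e6 * .band_violation(sol, constraints)
    }
    set.seed(seed)
    starts <- c(list(rep(0, length(off))),
                lapply(seq_len(n_starts - 1L), function(i)
                  stats::rnorm(length(off), 0, 0.1)))
    for (cmp in seq_len(k)) {
      for (sgn in c(1, -1)) {
        best <- Inf; best_par <- NULL
        for (st in starts) {
          o <- stats::optim(st, penal, cmp = cmp, sign = sgn,
                            method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-10))
          if (o$value < best) { best <- o$value; best_par <- o$par }
        }
        sol <- .band_fvals(C, S, mk_T(best_par))
        if (is.null(sol) || .band_violation(sol, constraints) > 1e-5) {
          unresolved <- TRUE
          next
        }
        add_sol(sol)
        if (sgn < 0) fmax[cmp] <- max(fmax[cmp], sol$f[cmp], na.rm = TRUE)
        else fmin[cmp] <- min(fmin[cmp], sol$f[cmp], na.rm = TRUE)
      }
    }
  }

  if (!length(sols) || any(is.na(fmin)) || any(is.na(fmax))) {
    return(structure(list(
      f_min = fmin, f_max = fmax, afs_percent = rep(NA_real_, k),
      max_rfs = NA_real_, avg_rfs = NA_real_,
      critical_wavelength = NA_real_, selectivity_index = rep(NA_real_, k),
      mean_afs = NA_real_, sd_afs = NA_real_, unresolved = TRUE),
      class = "ambiguity_result"))
  }

  afs <- 100 * (fmax - fmin)
  # feasible spectral band: per-wavelength range of the mean-sample
  # contribution of each component, in AU
  max_rfs <- numeric(k); avg_rfs <- numeric(k); crit <- numeric(k)
  for (cmp in seq_len(k)) {
    contrib <- vapply(sols, function(s)
      mean(s$Ct[, cmp]) * s$St[cmp, ], numeric(m))
    width <- apply(contrib, 1, max) - apply(contrib, 1, min)
    max_rfs[cmp] <- max(width); avg_rfs[cmp] <- mean(width)
    crit[cmp] <- wavelengths[which.max(width)]
  }
  structure(list(
    f_min = fmin, f_max = fmax, afs_percent = afs,
    max_rfs = max_rfs, avg_rfs = avg_rfs, critical_wavelength = crit,
    selectivity_index = ifelse(fmax > 0, 1 - (fmax - fmin) / fmax, NA_real_),
    mean_afs = mean(afs), sd_afs = stats::sd(afs),
    unresolved = unresolved), class = "ambiguity_result")
}

#' Local rank map
#'
#' Sliding-window SVD across the wavelength axis: the effective rank of
#' each window's submatrix under the same normalized log10-eigenvalue
#' threshold convention as [efa()] (normalization to the window's largest
#' eigenvalue).
#'
#' @param D Samples x wavelengths matrix.
#' @param window Window width in grid points (>= 3).
#' @param log10_threshold Threshold (default -4).
#' @param wavelengths Optional wavelength vector for labeling.
#' @return List with `rank` (one value per window position), `center`
#'   (window-center wavelengths).
#' @export
local_rank_map <- function(D, window = 11L, log10_threshold = -4,
                           wavelengths = NULL) {
  D <- as.matrix(D)
  window <- as.integer(window)
  if (window < 3L) stop("window must be >= 3 points", call. = FALSE)
  if (window > ncol(D)) stop("window exceeds grid", call. = FALSE)
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(D))
  npos <- ncol(D) - window + 1L
  rk <- integer(npos)
  for (i in seq_len(npos)) {
    sv <- svd(D[, i:(i + window - 1L), drop = FALSE], nu = 0, nv = 0)$d
    if (sv[1] == 0) { rk[i] <- 0L; next }
    rk[i] <- sum(log10(pmax(sv^2 / sv[1]^2, 1e-300)) > log10_threshold)
  }
  list(rank = rk,
       center = wavelengths[seq_len(npos) + (window - 1L) %/% 2L])
}
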