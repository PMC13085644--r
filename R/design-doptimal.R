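#' Specify the regression model for the information matrix
#'
#' Term set used to expand a design into the model matrix X whose
#' information matrix X'X the exchange algorithm maximizes (by determinant).
#'
#' @param intercept,linear,interactions,quadratic Logical flags for the
#'   intercept column, main effects, all two-factor interactions, and pure
#'   quadratic terms. The default full quadratic model has
#'   p = 1 + f + choose(f, 2) + f parameters.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(intercept = TRUE, linear = TRUE,
                       interactions = TRUE, quadratic = TRUE) {
  s <- list(intercept = isTRUE(intercept), linear = isTRUE(linear),
            interactions = isTRUE(interactions), quadratic = isTRUE(quadratic))
  if (!any(unlist(s)))
    stop("model_spec: term set must be non-empty", call. = FALSE)
  structure(s, class = "model_spec")
}

#' Number of parameters of a model spec for f factors
#' @param spec A [model_spec()].
#' @param f Number of factors.
#' @export
n_parameters <- function(spec, f) {
  spec$intercept + spec$linear * f + spec$interactions * choose(f, 2) +
    spec$quadratic * f
}

#' Expand a design into a model matrix
#'
#' Columns are ordered intercept, linear terms (factor order), two-factor
#' interactions (`combn` order), pure quadratics.
#'
#' @param design Runs x factors matrix (coded or concentration scale).
#' @param spec A [model_spec()].
#' @return Runs x p numeric model matrix.
#' @export
build_model_matrix <- function(design, spec = model_spec()) {
  design <- as.matrix(design)
  if (!nrow(design)) stop("empty design", call. = FALSE)
  f <- ncol(design)
  nms <- colnames(design)
  if (is.null(nms)) nms <- paste0("x", seq_len(f))
  cols <- list(); cn <- character(0)
  if (spec$intercept) { cols <- c(cols, list(rep(1, nrow(design)))); cn <- c(cn, "1") }
  if (spec$linear) { cols <- c(cols, lapply(seq_len(f), function(j) design[, j])); cn <- c(cn, nms) }
  if (spec$interactions && f >= 2) {
    for (pr in utils::combn(f, 2, simplify = FALSE)) {
      cols <- c(cols, list(design[, pr[1]] * design[, pr[2]]))
      cn <- c(cn, paste0(nms[pr[1]], ":", nms[pr[2]]))
    }
  }
  if (spec$quadratic) {
    cols <- c(cols, lapply(seq_len(f), function(j) design[, j]^2))
    cn <- c(cn, paste0(nms, "^2"))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- cn
  X
}

#' Enumerate the full-factorial candidate grid
#'
#' All coded level combinations of the factors, exactly once, in
#' lexicographic row order (last factor varying fastest).
#'
#' @param factors List of [factor_range()] objects.
#' @return List with `coded` (candidates x factors integer matrix) and
#'   `concentration` (same grid in ug/mL).
#' @export
enumerate_candidates <- function(factors) {
  .check_factor_list(factors)
  lev <- lapply(factors, function(f) {
    h <- (f$n_levels - 1) / 2
    seq(-h, h, by = 1)       # half-integer levels when n_levels is even
  })
  grid <- rev(expand.grid(rev(lev), KEEP.OUT.ATTRS = FALSE))
  coded <- as.matrix(grid)
  dimnames(coded) <- list(NULL, vapply(factors, `[[`, "", "name"))
  list(coded = structure(coded, class = c("coded_design", class(coded))),
       concentration = code_to_concentration(coded, factors),
       n_candidates = nrow(coded))
}

.logdet_xtx <- function(X) {
  M <- crossprod(X)
  d <- determinant(M, logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)
  as.numeric(d$modulus)
}

#' D-optimal subset selection by Fedorov row exchange
#'
#' Selects `n_select` rows of the candidate grid maximizing det(X'X) of the
#' expanded model matrix. Each start draws a seeded random non-singular
#' subset, then repeatedly applies the best-improvement single-row swap
#' (Fedorov delta criterion), ties broken by lowest candidate index, until
#' no swap improves the determinant; the best start wins.
#'
#' @param candidates Result of [enumerate_candidates()] (or any list with a
#'   `coded` matrix; selection operates on the coded scale).
#' @param n_select Number of rows to select (must be >= p and <= candidates).
#' @param spec A [model_spec()]; default full quadratic.
#' @param n_starts Number of random restarts (default 20).
#' @param seed Integer RNG seed; results are reproducible given the seed.
#' @param factors Optional factor list used to decode the selection; taken
#'   from `candidates$concentration` when present.
#' @return List of class `exchange_result`: `indices` (into the candidate
#'   grid), `coded`, `concentration` (if decodable), `log10_det` of X'X,
#'   `iterations` (accepted swaps, best start), `n_starts`, `seed`, and
#'   `trace` (log-det trajectory of the best start).
#' @export
d_optimal_select <- function(candidates, n_select, spec = model_spec(),
                             n_starts = 20L, seed = 1L, factors = NULL) {
  coded <- as.matrix(candidates$coded)
  Xall <- build_model_matrix(coded, spec)
  p <- ncol(Xall)
  N <- nrow(Xall)
  n_select <- as.integer(n_select)
  if (n_select < p)
    stop(sprintf("infeasible design: n_select (%d) < number of model parameters (%d)",
                 n_select, p), call. = FALSE)
  if (n_select > N)
    stop("n_select exceeds candidate count", call. = FALSE)

  best <- NULL
  rng <- .seeded_rng(seed)
  for (s in seq_len(n_starts)) {
    start_seed <- rng()
    res <- .fedorov_one_start(Xall, n_select, start_seed)
    if (is.null(res)) next
    if (is.null(best) || res$logdet > best$logdet) best <- res
  }
  if (is.null(best))
    stop("all starts singular: candidate set cannot support the model; ",
         "reduce the model order or enlarge the candidate grid", call. = FALSE)
  idx <- sort(best$idx)
  conc <- if (!is.null(candidates$concentration))
    candidates$concentration[idx, , drop = FALSE]
  else if (!is.null(factors)) code_to_concentration(coded[idx, , drop = FALSE], factors)
  structure(list(
    indices = idx,
    coded = coded[idx, , drop = FALSE],
    concentration = conc,
    log10_det = best$logdet / log(10),
    iterations = best$iterations,
    n_starts = n_starts, seed = seed,
    trace = best$trace / log(10)), class = "exchange_result")
}

# One Fedorov exchange start. Returns NULL if no non-singular initial
# subset is found. logdet values are natural-log.
.fedorov_one_start <- function(Xall, n_select, start_seed, max_sweeps = 200L) {
  N <- nrow(Xall)
  idx <- NULL
  ld <- -Inf
  withr_seed <- start_seed
  set.seed(withr_seed)
  for (try in 1:50) {
    cand <- sort(sample.int(N, n_select))
    l <- .logdet_xtx(Xall[cand, , drop = FALSE])
    if (is.finite(l)) { idx <- cand; ld <- l; break }
  }
  if (is.null(idx)) return(NULL)
  trace <- ld
  Minv <- solve(crossprod(Xall[idx, , drop = FALSE]))
  iterations <- 0L
  for (sweep in seq_len(max_sweeps)) {
    Xs <- Xall[idx, , drop = FALSE]
    # Fedorov delta for removing selected row i, adding candidate row j:
    # ratio = (1 + d_jj)(1 - d_ii) + d_ij^2
    H <- Xall %*% Minv              # N x p
    d_all <- rowSums(H * Xall)      # x' Minv x for every candidate
    d_sel <- d_all[idx]
    Dij <- Xs %*% t(H)              # n_select x N cross terms d(i, j)
    ratio <- outer(1 - d_sel, 1 + d_all) + Dij^2
    ratio[, idx] <- -Inf            # adding an already-selected row: skip
    jbest <- max.col(ratio, ties.method = "first")
    rbest <- ratio[cbind(seq_along(idx), jbest)]
    ibest <- which.max(rbest)       # lowest selected index on ties
    if (rbest[ibest] <= 1 + 1e-9) break
    iterations <- iterations + 1L
    drop_row <- idx[ibest]; add_row <- jbest[ibest]
    idx[ibest] <- add_row
    ld <- ld + log(rbest[ibest])
    trace <- c(trace, ld)
    Minv <- solve(crossprod(Xall[idx, , drop = FALSE]))
  }
  list(idx = idx, logdet = ld, iterations = iterations, trace = trace)
}

# Derive a stream of sub-seeds (< 2^31) from one integer seed without
# touching the caller's RNG state beyond set.seed calls inside workers.
.seeded_rng <- function(seed) {
  state <- as.integer(seed)
  function() {
    state <<- (as.numeric(state) * 48271) %% 2147483647
    state <<- as.integer(state)
    state
  }
}

#' Design diagnostics
#'
#' Pairwise factor correlations, per-factor level counts, and range-coverage
#' fractions of a concentration design.
#'
#' @param design A `concentration_design` (factor ranges attached) or plain
#'   matrix plus an explicit `factors` list.
#' @param factors Optional list of [factor_range()] objects.
#' @return List with `correlation` (factors x factors; NA flags an undefined
#'   correlation from a constant column), `level_counts` (list of tables),
#'   and `coverage` (observed range / factor range, in `[0, 1]`).
#' @export
design_diagnostics <- function(design, factors = attr(design, "factors")) {
  X <- as.matrix(design)
  if (nrow(X) < 2) stop("need at least 2 runs", call. = FALSE)
  f <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  corr <- suppressWarnings(stats::cor(X))
  corr[sds == 0, ] <- NA_real_; corr[, sds == 0] <- NA_real_
  diag(corr) <- ifelse(sds == 0, NA_real_, 1)
  counts <- lapply(seq_len(f), function(j) table(X[, j]))
  names(counts) <- colnames(X)
  coverage <- if (!is.null(factors)) {
    vapply(seq_len(f), function(j) {
      rng <- factors[[j]]$c_max - factors[[j]]$c_min
      (max(X[, j]) - min(X[, j])) / rng
    }, 0)
  } else rep(NA_real_, f)
  names(coverage) <- colnames(X)
  list(correlation = corr, level_counts = counts, coverage = coverage)
}
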