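#' Define a concentration factor
#'
#' A factor is one analyte varied over a closed concentration range on an
#' equally spaced grid of levels. The level step is
#' `(c_max - c_min) / (n_levels - 1)` and the midpoint carries coded level 0.
#'
#' @param name Analyte name.
#' @param c_min,c_max Lower and upper bound of the working range (ug/mL).
#' @param n_levels Number of equally spaced levels (default 5).
#' @return An object of class `factor_range`.
#' @examples
#' factor_range("CIN", 4, 20)
#' @export
factor_range <- function(name, c_min, c_max, n_levels = 5L) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(c_min) || !is.finite(c_max) || c_min >= c_max)
    stop("factor_range: need c_min < c_max", call. = FALSE)
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L)
    stop("factor_range: n_levels must be >= 2", call. = FALSE)
  structure(
    list(name = name, c_min = c_min, c_max = c_max, n_levels = n_levels,
         step = (c_max - c_min) / (n_levels - 1),
         midpoint = (c_min + c_max) / 2),
    class = "factor_range")
}

#' @export
print.factor_range <- function(x, ...) {
  cat(sprintf("<factor_range> %s: %g-%g ug/mL, %d levels (step %g)\n",
              x$name, x$c_min, x$c_max, x$n_levels, x$step))
  invisible(x)
}

# Canonical cyclic generators (coded levels for runs 2..L^2 of factor 1).
# The 5-level sequence is the one realized by the published 25-mixture
# calibration set; the 3-level sequence is the first balanced multiset
# permutation with zero cyclic lag-1 autocorrelation (exhaustive search).
.brereton_generators <- list(
  `3` = c(0L, -1L, 0L, -1L, 1L, 1L, 1L, -1L),
  `5` = c(0L, -2L, -2L, 2L, -1L, 2L, 0L, -1L, -1L, 1L, 2L, 1L,
          0L, 2L, 2L, -2L, 1L, -2L, 0L, 1L, 1L, -1L, -2L, -1L)
)

.check_factor_list <- function(factors) {
  if (!length(factors) || !all(vapply(factors, inherits, TRUE, "factor_range")))
    stop("expected a non-empty list of factor_range objects", call. = FALSE)
  invisible(factors)
}

#' Generate a multilevel multifactor (Brereton) calibration design
#'
#' Builds the cyclic L^2-run design for `f` factors at L levels: run 1 is the
#' all-center run, the first factor's remaining runs follow a fixed generator
#' sequence, and each subsequent factor column is the previous column with
#' runs 2..L^2 cyclically advanced by one. The construction yields balanced
#' (each level L times per column) and mutually orthogonal coded columns, so
#' analyte concentration profiles are uncorrelated.
#'
#' @param factors List of [factor_range()] objects, all with the same odd
#'   `n_levels` (3 or 5 supported).
#' @return A list with elements `coded` (runs x factors integer matrix,
#'   class `coded_design`) and `concentration` (runs x factors matrix in
#'   ug/mL, class `concentration_design` carrying the factor list).
#' @examples
#' fac <- list(factor_range("CIN", 4, 20), factor_range("DOM", 3, 15),
#'             factor_range("BNZ", 1, 5))
#' des <- generate_brereton_design(fac)
#' des$concentration[1, ]   # the all-midpoint run: 12, 9, 3
#' @export
generate_brereton_design <- function(factors) {
  .check_factor_list(factors)
  L <- unique(vapply(factors, function(f) f$n_levels, 1L))
  if (length(L) != 1L)
    stop("all factors must share the same number of levels", call. = FALSE)
  if (L %% 2L == 0L)
    stop("Brereton designs require an odd number of levels", call. = FALSE)
  f <- length(factors)
  if (f > L - 1L)
    stop(sprintf("unsupported design: at most %d factors at %d levels",
                 L - 1L, L), call. = FALSE)
  gen <- .brereton_generators[[as.character(L)]]
  if (is.null(gen))
    stop(sprintf("unsupported design: no generator for %d levels", L),
         call. = FALSE)
  n <- L * L
  coded <- matrix(0L, n, f,
                  dimnames = list(NULL, vapply(factors, `[[`, "", "name")))
  col <- c(0L, gen)
  for (j in seq_len(f)) {
    coded[, j] <- col
    col <- c(col[1L], col[c(3:n, 2L)])  # advance runs 2..n cyclically
  }
  conc <- code_to_concentration(coded, factors)
  list(coded = structure(coded, class = c("coded_design", class(coded))),
       concentration = conc)
}

#' Decode coded levels to concentrations
#'
#' Concentration = factor midpoint + coded level x level step. The map is
#' exactly invertible on the level grid; see [concentration_to_code()].
#'
#' @param coded Runs x factors matrix of coded levels.
#' @param factors List of [factor_range()] objects, one per column.
#' @return Runs x factors concentration matrix (class `concentration_design`
#'   with the factor list attached as attribute `factors`).
#' @export
code_to_concentration <- function(coded, factors) {
  .check_factor_list(factors)
  coded <- as.matrix(coded)
  if (ncol(coded) != length(factors))
    stop("column count does not match factor list", call. = FALSE)
  half <- vapply(factors, function(f) (f$n_levels - 1) / 2, 0)
  for (j in seq_along(factors)) {
    # levels live on {-h, -h+1, ..., h}: half-integers when n_levels even
    shifted <- coded[, j] + half[j]
    bad <- abs(coded[, j]) > half[j] + 1e-9 |
      abs(shifted - round(shifted)) > 1e-9
    if (any(bad))
      stop(sprintf("coded level out of range for factor '%s'",
                   factors[[j]]$name), call. = FALSE)
  }
  conc <- vapply(seq_along(factors), function(j)
    factors[[j]]$midpoint + coded[, j] * factors[[j]]$step,
    numeric(nrow(coded)))
  conc <- matrix(conc, nrow(coded), length(factors),
                 dimnames = list(NULL, vapply(factors, `[[`, "", "name")))
  structure(conc, factors = factors,
            class = c("concentration_design", class(conc)))
}

#' Encode concentrations back to coded levels
#'
#' Inverse of [code_to_concentration()]; errors if a value is off the level
#' grid (beyond floating-point tolerance).
#'
#' @inheritParams code_to_concentration
#' @param conc Runs x factors concentration matrix (ug/mL).
#' @export
concentration_to_code <- function(conc, factors = attr(conc, "factors")) {
  .check_factor_list(factors)
  conc <- as.matrix(conc)
  coded <- vapply(seq_along(factors), function(j) {
    h <- (factors[[j]]$n_levels - 1) / 2
    z <- (conc[, j] - factors[[j]]$midpoint) / factors[[j]]$step
    zi <- round(z + h) - h     # snap to the (possibly half-integer) grid
    if (any(abs(z - zi) > 1e-8))
      stop(sprintf("concentration off the level grid for factor '%s'",
                   factors[[j]]$name), call. = FALSE)
    zi
  }, numeric(nrow(conc)))
  coded <- matrix(coded, nrow(conc), length(factors),
                  dimnames = list(NULL, vapply(factors, `[[`, "", "name")))
  structure(coded, class = c("coded_design", class(coded)))
}
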