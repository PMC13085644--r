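#' Factor ranges of the cinnarizine / domperidone / benzophenone system
#'
#' The three working ranges used throughout the package examples and the
#' synthetic pipeline: CIN 4-20, DOM 3-15, BNZ 1-5 ug/mL, five levels each.
#' @return List of three [factor_range()] objects.
#' @export
cin_dom_bnz_factors <- function() {
  list(factor_range("CIN", 4, 20, 5L),
       factor_range("DOM", 3, 15, 5L),
       factor_range("BNZ", 1, 5, 5L))
}

#' Published 25-mixture calibration set
#'
#' The five-level, three-factor multilevel calibration design (ug/mL) as
#' printed; identical to `generate_brereton_design(cin_dom_bnz_factors())`.
#' @return A `concentration_design` matrix (25 x 3).
#' @export
calibration_design_25 <- function() {
  m <- matrix(c(
    12, 9, 3,   12, 3, 1,    4, 3, 5,    4, 15, 2,   20, 6, 5,
     8, 15, 3,  20, 9, 2,   12, 6, 2,    8, 6, 4,     8, 12, 5,
    16, 15, 4,  20, 12, 3,  16, 9, 5,   12, 15, 5,   20, 15, 1,
    20, 3, 4,    4, 12, 1,  16, 3, 3,    4, 9, 4,    12, 12, 4,
    16, 12, 2,  16, 6, 1,    8, 3, 2,    4, 6, 3,     8, 9, 1),
    ncol = 3, byrow = TRUE, dimnames = list(NULL, c("CIN", "DOM", "BNZ")))
  structure(m, factors = cin_dom_bnz_factors(),
            class = c("concentration_design", class(m)))
}

#' Published 13-mixture D-optimal validation set
#'
#' The 13 validation mixtures (ug/mL) as printed. Shipped as a fixture: the
#' exchange algorithm is not required to reproduce it (the original
#' candidate set and model are unknown), only to match or beat its log-det
#' under the package's default quadratic spec.
#' @return A `concentration_design` matrix (13 x 3).
#' @export
validation_design_13 <- function() {
  m <- matrix(c(
    13, 6, 4,   13, 11, 3,   6, 5, 3,   14, 5, 2,   10, 12, 4,
     5, 10, 1,   8, 14, 2,  10, 7, 1,  17, 3, 2,   18, 12, 4,
     7, 14, 4,  20, 8, 3,   15, 9, 5),
    ncol = 3, byrow = TRUE, dimnames = list(NULL, c("CIN", "DOM", "BNZ")))
  structure(m, factors = cin_dom_bnz_factors(),
            class = c("concentration_design", class(m)))
}

#' Serial dilution / solution preparation arithmetic
#'
#' Chains preparation steps exactly as done at the bench: the first step is
#' either a weighed mass dissolved to volume (`mass_mg` / `final_mL`) or an
#' existing stock (`stock_ugml`); every subsequent step transfers
#' `aliquot_mL` into a flask made up to `final_mL`, so
#' `c_out = c_in * aliquot / final`.
#'
#' @param steps List of steps. Each step is a list with either
#'   `mass_mg` + `final_mL` (dissolution), or `stock_ugml` (+ optional
#'   `aliquot_mL` + `final_mL`), or `aliquot_mL` + `final_mL` (dilution of
#'   the running concentration).
#' @return Final concentration in ug/mL.
#' @examples
#' # 5 mL of a 1250 ug/mL stock into a 250 mL flask -> 25 ug/mL
#' solution_prep(list(list(stock_ugml = 1250, aliquot_mL = 5, final_mL = 250)))
#' @export
solution_prep <- function(steps) {
  if (!length(steps)) stop("no steps given", call. = FALSE)
  conc <- NA_real_
  for (k in seq_along(steps)) {
    st <- steps[[k]]
    chk_vol <- function(v, what) {
      if (!is.null(v) && (!is.finite(v) || v <= 0))
        stop(sprintf("step %d: non-positive %s", k, what), call. = FALSE)
    }
    chk_vol(st$final_mL, "final volume"); chk_vol(st$aliquot_mL, "aliquot")
    if (!is.null(st$mass_mg)) {
      if (st$mass_mg < 0) stop("negative mass", call. = FALSE)
      conc <- st$mass_mg * 1000 / st$final_mL       # mg/mL -> ug/mL
    } else if (!is.null(st$stock_ugml)) {
      conc <- st$stock_ugml
      if (!is.null(st$aliquot_mL)) {
        if (st$aliquot_mL > st$final_mL)
          stop(sprintf("step %d: aliquot exceeds final volume", k), call. = FALSE)
        conc <- conc * st$aliquot_mL / st$final_mL
      }
    } else {
      if (is.na(conc)) stop("first step must define a mass or stock", call. = FALSE)
      if (st$aliquot_mL > st$final_mL)
        stop(sprintf("step %d: aliquot exceeds final volume", k), call. = FALSE)
      conc <- conc * st$aliquot_mL / st$final_mL
    }
  }
  conc
}
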