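#' Uniform wavelength grid
#'
#' @param start,end Grid limits in nm (default 220-300).
#' @param step Sampling interval in nm (default 1).
#' @return Object of class `wavelength_grid` with a `wavelengths` vector.
#'   The default grid has 81 points.
#' @export
wavelength_grid <- function(start = 220, end = 300, step = 1) {
  if (end <= start) stop("end must exceed start", call. = FALSE)
  npt <- (end - start) / step + 1
  if (abs(npt - round(npt)) > 1e-8)
    stop("grid length (end - start)/step must be integral", call. = FALSE)
  structure(list(start = start, end = end, step = step,
                 wavelengths = seq(start, end, by = step),
                 n = as.integer(round(npt))),
            class = "wavelength_grid")
}

#' Gaussian band model for one pure component
#'
#' A pure UV spectrum is modeled as a sum of Gaussian bands
#' `a * exp(-(lambda - mu)^2 / (2 w^2))` with amplitudes in absorptivity
#' units (AU mL/ug), so Beer-Lambert mixing is `D = C S`.
#'
#' @param name Component name.
#' @param centers,widths,amplitudes Equal-length numeric vectors: band
#'   centers (nm), standard widths (nm, > 0), amplitudes (>= 0).
#' @export
band_model <- function(name, centers, widths, amplitudes) {
  stopifnot(length(centers) == length(widths),
            length(centers) == length(amplitudes))
  if (any(widths <= 0)) stop("band widths must be > 0", call. = FALSE)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  structure(list(name = name, centers = centers, widths = widths,
                 amplitudes = amplitudes), class = "band_model")
}

#' Evaluate a band model on a wavelength grid
#'
#' @param bands A [band_model()].
#' @param grid A [wavelength_grid()].
#' @return Non-negative spectrum vector (AU mL/ug), one value per grid point.
#' @export
pure_spectrum <- function(bands, grid = wavelength_grid()) {
  lam <- grid$wavelengths
  s <- numeric(length(lam))
  for (b in seq_along(bands$centers))
    s <- s + bands$amplitudes[b] *
      exp(-(lam - bands$centers[b])^2 / (2 * bands$widths[b]^2))
  s
}

#' Default three-component band library
#'
#' Fixed named constants emulating the qualitative features of the real
#' system: a CIN-like component with a dual peak in 240-260 nm (maximum
#' near 250 nm), a DOM-like component with its main maximum near 285 nm
#' plus a secondary 225-235 nm feature, and a BNZ-like component with a
#' single band near 250 nm. A weak broad background band under each
#' component guarantees spectral overlap (pairwise cosine similarity
#' between 0.3 and 0.98) without collinearity.
#'
#' @param grid A [wavelength_grid()] (used only for validation).
#' @return Named list of three [band_model()] objects (CIN, DOM, BNZ).
#' @export
default_component_library <- function(grid = wavelength_grid()) {
  list(
    CIN = band_model("CIN",
                     centers = c(246, 257, 250),
                     widths = c(3.0, 3.0, 25),
                     amplitudes = c(0.055, 0.047, 0.012)),
    DOM = band_model("DOM",
                     centers = c(285, 230, 255),
                     widths = c(6.0, 5.0, 25),
                     amplitudes = c(0.060, 0.046, 0.014)),
    BNZ = band_model("BNZ",
                     centers = c(249, 255),
                     widths = c(11.0, 25),
                     amplitudes = c(0.060, 0.012)))
}

#' Noise / baseline model for simulated spectra
#'
#' @param sd Additive i.i.d. Gaussian noise standard deviation (AU,
#'   default 0.003).
#' @param baseline Constant baseline offset (AU, default 0).
#' @param slope Baseline slope (AU/nm, default 0), applied relative to the
#'   grid start.
#' @param seed Integer RNG seed.
#' @export
noise_model <- function(sd = 0.003, baseline = 0, slope = 0, seed = 1L) {
  if (sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  structure(list(sd = sd, baseline = baseline, slope = slope,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Simulate Beer-Lambert mixture spectra
#'
#' Bilinear mixing `D = C S + baseline + E` with `E ~ N(0, sd^2)` i.i.d.
#' (seeded). With `sd = 0` and no baseline the data are exactly bilinear.
#'
#' @param conc Samples x components concentration matrix (ug/mL, >= 0);
#'   column names must match the library components.
#' @param library Named list of [band_model()]s (see
#'   [default_component_library()]).
#' @param noise A [noise_model()].
#' @param grid A [wavelength_grid()].
#' @return Object of class `simulated_dataset`: `absorbance` (samples x
#'   wavelengths), `concentration` (truth), `pure_spectra` (components x
#'   wavelengths), `grid`, and `provenance`.
#' @export
simulate_mixtures <- function(conc, library = default_component_library(),
                              noise = noise_model(), grid = wavelength_grid()) {
  conc <- as.matrix(conc)
  if (any(conc < 0)) stop("negative concentration", call. = FALSE)
  comp <- names(library)
  if (!is.null(colnames(conc))) {
    if (!all(colnames(conc) %in% comp))
      stop("concentration columns do not match library components", call. = FALSE)
    library <- library[colnames(conc)]
    comp <- colnames(conc)
  } else if (ncol(conc) != length(library)) {
    stop("concentration columns do not match library components", call. = FALSE)
  }
  S <- t(vapply(library, pure_spectrum, numeric(grid$n), grid = grid))
  rownames(S) <- comp
  D <- conc %*% S
  lam <- grid$wavelengths
  base <- noise$baseline + noise$slope * (lam - grid$start)
  D <- sweep(D, 2, base, "+")
  if (noise$sd > 0) {
    set.seed(noise$seed)
    D <- D + matrix(stats::rnorm(length(D), 0, noise$sd), nrow(D), ncol(D))
  }
  colnames(D) <- lam
  structure(list(absorbance = D, concentration = conc, pure_spectra = S,
                 grid = grid,
                 provenance = list(library = library, noise = noise)),
            class = "simulated_dataset")
}

#' Instrument perturbations for robustness testing
#'
#' Three perturbation modes mimicking instrument-setting changes:
#' `"interval"` re-interpolates each spectrum onto a coarser wavelength
#' grid (default 1.1 nm) and back; `"bandwidth"` convolves each spectrum
#' with a Gaussian slit function of the stated width (nm); `"scan_speed"`
#' adds seeded Gaussian noise of the stated magnitude (AU).
#'
#' @param A Samples x wavelengths absorbance matrix on `grid`.
#' @param mode One of `"interval"`, `"bandwidth"`, `"scan_speed"`.
#' @param magnitude Interval (nm), slit width (nm), or noise sd (AU).
#'   Zero magnitude (or the native interval) is the identity.
#' @param grid A [wavelength_grid()].
#' @param seed RNG seed for `"scan_speed"`.
#' @return Perturbed absorbance matrix of the same shape.
#' @export
perturb_instrument <- function(A, mode = c("interval", "bandwidth", "scan_speed"),
                               magnitude = 1.1, grid = wavelength_grid(),
                               seed = 1L) {
  mode <- match.arg(mode)
  A <- as.matrix(A)
  lam <- grid$wavelengths
  if (ncol(A) != length(lam)) stop("grid mismatch", call. = FALSE)
  if (mode == "interval") {
    if (magnitude <= 0 || isTRUE(all.equal(magnitude, grid$step))) return(A)
    coarse <- seq(grid$start, grid$end, by = magnitude)
    t(apply(A, 1, function(y) {
      yc <- stats::approx(lam, y, xout = coarse, rule = 2)$y
      stats::approx(coarse, yc, xout = lam, rule = 2)$y
    }))
  } else if (mode == "bandwidth") {
    if (magnitude <= 0) return(A)
    half <- max(1L, ceiling(3 * magnitude / grid$step))
    x <- (-half:half) * grid$step
    k <- exp(-x^2 / (2 * magnitude^2))
    t(apply(A, 1, function(y) {
      ypad <- c(rep(y[1], half), y, rep(y[length(y)], half))
      out <- stats::filter(ypad, k / sum(k), sides = 2)
      as.numeric(out[(half + 1):(half + length(y))])
    }))
  } else {
    if (magnitude < 0) stop("negative noise magnitude", call. = FALSE)
    if (magnitude == 0) return(A)
    set.seed(seed)
    A + matrix(stats::rnorm(length(A), 0, magnitude), nrow(A), ncol(A))
  }
}
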