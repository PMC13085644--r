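#' Build a run configuration
#'
#' All tunables of the end-to-end pipeline with their defaults. Every
#' random element takes an explicit seed derived from `seed`.
#'
#' @param ranges List of `c(min, max)` pairs named by analyte (default the
#'   CIN/DOM/BNZ working ranges).
#' @param levels Number of design levels (default 5).
#' @param grid_start,grid_end,grid_step Wavelength grid (default 220-300 @ 1).
#' @param n_validation Validation-set size (default 13).
#' @param model Model order for the information matrix: `"quadratic"`,
#'   `"interaction"` or `"linear"` (default quadratic, 10 parameters for 3
#'   factors).
#' @param n_starts Exchange random starts (default 20).
#' @param noise_sd Additive spectral noise sd in AU (default 0.003).
#' @param baseline,baseline_slope Baseline offset (AU) and slope (AU/nm).
#' @param cls_widths CLS smoothing widths to scan, nm (default 5-29 odd).
#' @param cls_intercept Fit the CLS intercept spectrum (default TRUE).
#' @param pls_lv_range LV search range (default 1:10).
#' @param cv_scheme,cv_splits Cross-validation plan (venetian, 5).
#' @param mcr_init `"reference"` (pure spectra from the band library;
#'   pipeline default), `"efa"`, or `"random"`.
#' @param mcr_rel_tol,mcr_max_iter ALS convergence (0.20 percent, 50).
#' @param alpha Significance levels (default 0.05).
#' @param seed Master seed (default 20231201); stage seeds derive from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(ranges = list(CIN = c(4, 20), DOM = c(3, 15),
                                     BNZ = c(1, 5)),
                       levels = 5L,
                       grid_start = 220, grid_end = 300, grid_step = 1,
                       n_validation = 13L,
                       model = c("quadratic", "interaction", "linear"),
                       n_starts = 20L,
                       noise_sd = 0.003, baseline = 0, baseline_slope = 0,
                       cls_widths = seq(5, 29, by = 2), cls_intercept = TRUE,
                       pls_lv_range = 1:10,
                       cv_scheme = "venetian", cv_splits = 5L,
                       mcr_init = c("reference", "efa", "random"),
                       mcr_rel_tol = 0.20, mcr_max_iter = 50L,
                       alpha = 0.05,
                       seed = 20231201L) {
  model <- match.arg(model)
  mcr_init <- match.arg(mcr_init)
  cfg <- list(ranges = ranges, levels = as.integer(levels),
              grid_start = grid_start, grid_end = grid_end,
              grid_step = grid_step,
              n_validation = as.integer(n_validation), model = model,
              n_starts = as.integer(n_starts),
              noise_sd = noise_sd, baseline = baseline,
              baseline_slope = baseline_slope,
              cls_widths = cls_widths, cls_intercept = cls_intercept,
              pls_lv_range = pls_lv_range,
              cv_scheme = cv_scheme, cv_splits = as.integer(cv_splits),
              mcr_init = mcr_init, mcr_rel_tol = mcr_rel_tol,
              mcr_max_iter = as.integer(mcr_max_iter),
              alpha = alpha, seed = as.integer(seed))
  spec <- switch(model,
                 quadratic = model_spec(),
                 interaction = model_spec(quadratic = FALSE),
                 linear = model_spec(interactions = FALSE, quadratic = FALSE))
  p <- n_parameters(spec, length(ranges))
  if (cfg$n_validation < p)
    stop(sprintf("validation size %d < model parameter count %d",
                 cfg$n_validation, p), call. = FALSE)
  structure(cfg, class = "run_config")
}

.config_spec <- function(config) {
  switch(config$model,
         quadratic = model_spec(),
         interaction = model_spec(quadratic = FALSE),
         linear = model_spec(interactions = FALSE, quadratic = FALSE))
}

.config_factors <- function(config) {
  lapply(names(config$ranges), function(nm)
    factor_range(nm, config$ranges[[nm]][1], config$ranges[[nm]][2],
                 config$levels))
}

#' Run the full pipeline: design, simulate, fit, validate, diagnose
#'
#' Stages, in fixed order: (1) Brereton calibration design and D-optimal
#' validation selection; (2) Beer-Lambert simulation of both sets with the
#' configured noise; (3) the three calibration engines (CLS with
#' CV-selected smoothing, PLS with CV-selected latent variables, MCR-ALS
#' on the augmented matrix); (4) per-model, per-analyte figures of merit;
#' (5) diagnostics (EJCR per model and analyte, rotational-ambiguity bands
#' for MCR, design diagnostics). Identical configuration gives an
#' identical report.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory for intermediate artifacts (designs,
#'   spectra, report JSON).
#' @return Nested list of class `run_report`; see the vignette for the
#'   layout. On stage failure the report is truncated at the failed stage
#'   with an `error` record.
#' @export
run_end_to_end <- function(config = run_config(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  rng <- .seeded_rng(config$seed)
  seeds <- list(design = rng(), noise_calib = rng(), noise_valid = rng(),
                mcr = rng(), bands = rng())
  report <- list(provenance = list(
    config = unclass(config), seeds = seeds,
    package_version = as.character(utils::packageVersion("chemocal"))))
  stage <- "design"
  result <- tryCatch({
    factors <- .config_factors(config)
    spec <- .config_spec(config)
    grid <- wavelength_grid(config$grid_start, config$grid_end,
                            config$grid_step)
    des <- generate_brereton_design(factors)
    cand <- enumerate_candidates(factors)
    sel <- d_optimal_select(cand, config$n_validation, spec,
                            n_starts = config$n_starts,
                            seed = seeds$design)
    calib_conc <- des$concentration
    valid_conc <- sel$concentration
    report$design <- list(
      n_calibration = nrow(calib_conc), n_validation = nrow(valid_conc),
      log10_det = sel$log10_det, exchange_iterations = sel$iterations,
      diagnostics_calibration = design_diagnostics(calib_conc),
      diagnostics_validation = design_diagnostics(valid_conc, factors))

    stage <- "simulate"
    lib <- default_component_library(grid)
    calib <- simulate_mixtures(calib_conc, lib,
                               noise_model(config$noise_sd, config$baseline,
                                           config$baseline_slope,
                                           seeds$noise_calib), grid)
    valid <- simulate_mixtures(valid_conc, lib,
                               noise_model(config$noise_sd, config$baseline,
                                           config$baseline_slope,
                                           seeds$noise_valid), grid)

    stage <- "fit"
    cv <- cv_plan(config$cv_scheme, config$cv_splits)
    mw <- moving_window_select(calib$absorbance, calib_conc,
                               widths = config$cls_widths, cv = cv,
                               grid_step = grid$step,
                               intercept = config$cls_intercept)
    cls_pred_c <- predict_cls(mw$model, calib$absorbance)
    cls_pred_v <- predict_cls(mw$model, valid$absorbance)

    curve <- rmsecv_curve(calib$absorbance, calib_conc,
                          lv_range = config$pls_lv_range, cv = cv)
    n_lv <- select_lv(curve)
    pls <- fit_pls(calib$absorbance, calib_conc, n_lv)
    pls_pred_c <- predict_pls(pls, calib$absorbance)
    pls_pred_v <- predict_pls(pls, valid$absorbance)

    ref_S <- t(vapply(lib, pure_spectrum, numeric(grid$n), grid = grid))
    D_aug <- rbind(calib$absorbance, valid$absorbance)
    mcr_init <- if (config$mcr_init == "reference") ref_S else config$mcr_init
    mcr <- fit_mcr_als(D_aug, ncomp = length(lib), init = mcr_init,
                       constraints = constraint_set(),
                       rel_tol = config$mcr_rel_tol,
                       max_iter = config$mcr_max_iter, seed = seeds$mcr)
    ncal <- nrow(calib_conc)
    mcr_pred_c <- mcr_quantify(mcr, calib_conc, seq_len(ncal), seq_len(ncal),
                               ref_S)
    mcr_pred_v <- mcr_quantify(mcr, calib_conc, seq_len(ncal),
                               ncal + seq_len(nrow(valid_conc)), ref_S)

    stage <- "figures_of_merit"
    models <- list(
      CLS = list(pred_c = cls_pred_c, pred_v = cls_pred_v,
                 b = .cls_b_matrix(mw$model)),
      PLS = list(pred_c = pls_pred_c, pred_v = pls_pred_v, b = pls$b),
      MCR = list(pred_c = mcr_pred_c, pred_v = mcr_pred_v,
                 b = .mcr_b_matrix(mcr, calib_conc, seq_len(ncal), ref_S)))
    analytes <- colnames(calib_conc)
    fom <- lapply(models, function(mo) {
      recs <- lapply(analytes, function(a) {
        fom_record(
          prediction_set(calib_conc[, a], mo$pred_c[, a], a, "calibration"),
          prediction_set(valid_conc[, a], mo$pred_v[, a], a, "validation"),
          b = mo$b[, a], noise_sd = config$noise_sd)
      })
      names(recs) <- analytes
      recs
    })
    report$figures_of_merit <- fom

    stage <- "diagnostics"
    ej <- lapply(models, function(mo) {
      out <- lapply(analytes, function(a) {
        e <- ejcr(prediction_set(valid_conc[, a], mo$pred_v[, a], a),
                  alpha = config$alpha[1])
        e$boundary <- NULL  # keep the report compact
        e
      })
      names(out) <- analytes
      out
    })
    bands <- ambiguity_bands(mcr, wavelengths = grid$wavelengths,
                             n_starts = 8L, seed = seeds$bands)
    report$diagnostics <- list(
      ejcr = ej, ambiguity = unclass(bands),
      mcr = list(iterations = mcr$iterations, converged = mcr$converged,
                 explained_variance = mcr$explained_variance,
                 lack_of_fit = mcr$lack_of_fit,
                 cosine_to_reference = vapply(seq_along(analytes), function(i)
                   cosine_similarity(mcr$S[i, ], ref_S[i, ]), 0)),
      cls = list(window = mw$width, rmsecv = mw$rmsecv),
      pls = list(n_lv = n_lv, rmsecv = curve))

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_design_csv(calib_conc, file.path(out_dir, "calibration_design.csv"))
      write_design_csv(valid_conc, file.path(out_dir, "validation_design.csv"))
      write_spectra_csv(calib$absorbance, grid,
                        file.path(out_dir, "calibration_spectra.csv"))
      write_spectra_csv(valid$absorbance, grid,
                        file.path(out_dir, "validation_spectra.csv"))
    }
    TRUE
  }, error = function(e) {
    report$error <<- list(stage = stage, message = conditionMessage(e))
    FALSE
  })
  report$provenance$elapsed_seconds <- proc.time()[["elapsed"]] - t0
  report <- structure(report, class = "run_report")
  if (!is.null(out_dir) && result)
    write_report_json(.report_serializable(report),
                      file.path(out_dir, "report.json"))
  report
}

# effective regression vectors (wavelengths x analytes)

.cls_b_matrix <- function(model) {
  K <- model$K
  B <- t(K) %*% solve(tcrossprod(K))   # pseudo-inverse columns
  colnames(B) <- model$components
  B
}

.mcr_b_matrix <- function(mcr, calib_conc, calib_rows, ref_S) {
  # concentration estimate is slope * (D S+ ) + const per analyte; the
  # wavelength-space vector is the pseudo-inverse column times the slope
  Sp <- t(mcr$S) %*% solve(tcrossprod(mcr$S))
  B <- matrix(0, nrow(Sp), ncol(calib_conc),
              dimnames = list(NULL, colnames(calib_conc)))
  for (a in seq_len(ncol(calib_conc))) {
    cmp <- which.max(vapply(seq_len(nrow(mcr$S)), function(i)
      cosine_similarity(mcr$S[i, ], ref_S[a, ]), 0))
    slope <- stats::coef(stats::lm.fit(cbind(1, mcr$C[calib_rows, cmp]),
                                       calib_conc[, a]))[2]
    B[, a] <- Sp[, cmp] * slope
  }
  B
}

# drop matrix classes jsonlite can't restore losslessly
.report_serializable <- function(report) {
  strip <- function(x) {
    if (inherits(x, "table")) as.list(stats::setNames(as.numeric(x),
                                                      names(x)))
    else if (is.list(x)) lapply(x, strip)
    else if (is.matrix(x)) apply(x, 1, identity, simplify = FALSE)
    else x
  }
  strip(unclass(report))
}
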