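#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()]. The input is either a
#' survey CSV path or a [sim_config()]; all other fields have the package
#' defaults described on the individual stage functions.
#'
#' @param input Path to a survey CSV, or a [sim_config()] to generate one.
#' @param group Demographic group analysed spatially (default `"WRA"`, the
#'   group with the largest sample and with established adult thresholds).
#' @param thresholds Named thresholds in ug/L, see [se_thresholds()].
#' @param outlier_ids Person ids excluded as marginal outliers before any
#'   analysis (the individual-level screen); `NULL` for none.
#' @param n_bins,min_pairs Lag binning for [estimate_variogram()].
#' @param estimators Estimators to run (first must be `"matheron"`).
#' @param fit_weights,n_starts Settings for [fit_variogram()].
#' @param cv_n_sim Simulations for the SSPE validity interval.
#' @param grid_spacing_km Prediction grid spacing (default 10 km; a national
#'   survey of ~350 clusters does not support a finer resolution).
#' @param boundary Optional boundary polygon for the grid (`lon`, `lat`
#'   columns); default [ethiopia_polygon()].
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory for artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, group = "WRA", thresholds = se_thresholds(),
                            outlier_ids = NULL,
                            n_bins = 25, min_pairs = 30,
                            estimators = c("matheron", "cressie_hawkins", "dowd"),
                            fit_weights = "npairs", n_starts = 3,
                            cv_n_sim = 1000,
                            grid_spacing_km = 10, boundary = ethiopia_polygon(),
                            seed, out_dir) {
  if (is.character(input) && !file.exists(input)) {
    stop("input file does not exist: ", input, call. = FALSE)
  }
  if (estimators[1] != "matheron") stop("the first estimator must be matheron", call. = FALSE)
  structure(list(
    input = input, group = group, thresholds = thresholds,
    outlier_ids = outlier_ids,
    n_bins = n_bins, min_pairs = min_pairs, estimators = estimators,
    fit_weights = fit_weights, n_starts = n_starts, cv_n_sim = cv_n_sim,
    grid_spacing_km = grid_spacing_km, boundary = boundary,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full survey-to-risk-map pipeline
#'
#' Executes, in order: exclusions, stratified summaries, aggregation to EA
#' means, the Tukey outer-fence outlier screen of the EA means, empirical
#' variograms under each configured estimator (plus directional variograms
#' for the isotropy check), weighted-least-squares exponential fits,
#' cross-validation-based model selection, grid kriging, and
#' probability-of-deficiency surfaces for the GPx3 and IDI thresholds. The
#' EA mean flagged by the outlier screen is excluded from variogram
#' estimation but reinstated for kriging and cross-validation targets.
#'
#' Every artifact is written under `config$out_dir` and listed in the
#' returned manifest with an md5 checksum; the same seed and configuration
#' reproduce identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the manifest tibble (`file`, `md5`) and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, code) {
    message("[", name, "] ...")
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  records <- stage("input", {
    if (is.character(config$input)) read_survey(config$input)
    else simulate_survey(config$input)
  })

  excl <- stage("exclusions", {
    apply_exclusions(records, outlier_ids = config$outlier_ids %||% character())
  })
  write_exclusion_log(excl$log, out("exclusion_log.json"))

  stage("summaries", {
    for (by in c("national", "region", "group")) {
      readr::write_csv(summarize_se(excl$records, by = by,
                                    thresholds = config$thresholds),
                       out(paste0("summary_", by, ".csv")), progress = FALSE)
    }
  })

  ea <- stage("aggregate", aggregate_by_ea(excl$records, group = config$group))
  readr::write_csv(ea, out("ea_means.csv"), progress = FALSE)

  screen <- stage("outlier_screen", tukey_fences(ea$mean_se))
  ea_vario <- ea[!screen$probable, , drop = FALSE]
  if (any(screen$probable)) {
    message(sum(screen$probable),
            " EA mean(s) beyond the Tukey outer fences: excluded from the ",
            "variogram, reinstated for kriging")
  }

  cloud <- stage("variogram_cloud", build_cloud(ea_vario))
  bins <- default_lag_bins(cloud, n_bins = config$n_bins)
  fits <- stage("variograms", {
    fits <- list()
    for (est in config$estimators) {
      emp <- estimate_variogram(cloud, bins = bins, estimator = est,
                                min_pairs = config$min_pairs)
      fit <- fit_variogram(emp, weights = config$fit_weights,
                           n_starts = config$n_starts)
      write_variogram(emp, out(paste0("variogram_", est, ".csv")), fit = fit)
      fits[[est]] <- fit
    }
    dir_v <- directional_variograms(cloud, bins = bins,
                                    min_pairs = config$min_pairs)
    readr::write_csv(
      purrr::imap(dir_v, function(v, nm) {
        dplyr::mutate(tibble::as_tibble(v), direction = nm)
      }) |> dplyr::bind_rows(),
      out("variogram_directional.csv"), progress = FALSE
    )
    fits
  })

  sel <- stage("model_selection", {
    select_model(fits, ea_vario, n_sim = config$cv_n_sim, seed = config$seed)
  })
  jsonlite::write_json(list(status = sel$status, chosen = sel$chosen,
                            audit = sel$audit),
                       out("model_selection.json"), auto_unbox = TRUE, digits = NA)
  if (sel$status != "ok") {
    stop("pipeline stage 'model_selection' failed: no candidate variogram model ",
         "passed cross-validation", call. = FALSE)
  }

  cv <- stage("cross_validation", {
    # targets include the reinstated outlier EA; the model does not
    iv <- sspe_interval(sel$model, ea, n_sim = config$cv_n_sim,
                        seed = config$seed + 101L)
    loo_cv(sel$model, ea, interval = iv)
  })
  write_cv_report(cv, out("cv_report.csv"))

  grid <- stage("grid", make_grid(config$boundary, config$grid_spacing_km))
  pred <- stage("kriging", krige_ok(sel$model, ea, grid))
  readr::write_csv(pred[, c("lon", "lat", "prediction", "kriging_variance")],
                   out("predictions.csv"), progress = FALSE)

  stage("risk_maps", {
    for (nm in c("gpx3", "idi")) {
      surf <- build_surface(pred, config$thresholds[[nm]])
      write_surface(surf, out(paste0("probability_", nm, ".csv")))
    }
  })

  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  readr::write_csv(manifest, out("manifest.csv"), progress = FALSE)
  message("pipeline complete: ", nrow(manifest), " artifacts in ", config$out_dir)
  invisible(list(manifest = manifest, exclusions = excl$log, ea = ea,
                 fits = fits, selection = sel, cv = cv, predictions = pred))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
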