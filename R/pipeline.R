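#' Run the full exposure-assessment pipeline
#'
#' Chains the four processing stages — preprocessing, context
#' identification, in-situ calibration, exposure assessment — and
#' optionally the mixed-model inference stage, writing every product as
#' tidy text files into `out_dir`: the stage-accounting ledger, labels,
#' the cut-off scan and calibration fit, exposure summaries (overall, by
#' microenvironment, by setting, by season, by hour), dose apportionment,
#' time budgets, the home-address IDW series, the personal-vs-home
#' comparison, the model tables when requested, and a manifest with the
#' seed, configuration hash and per-file checksums. Outputs are
#' deterministic given the study and configuration.
#'
#' On a stage failure the ledger and the outputs produced so far are left
#' in place and the error names the failing stage.
#'
#' @param study a [simulate_study()] result or a [read_study()] list.
#' @param out_dir output directory.
#' @param params [context_params()].
#' @param cutoff_grid_km calibration cut-off grid.
#' @param min_outdoor_minutes collocation support rule.
#' @param min_pairs minimum collocation pairs for a calibration fit.
#' @param idw_power,idw_max_radius_km IDW settings.
#' @param infer fit the spatiotemporal mixed model (default FALSE; needs
#'   enough participants for the demographic factors).
#' @param adjustment passed to [fit_exposure_model()] when `infer = TRUE`.
#' @param force overwrite a non-empty `out_dir`.
#' @return (invisibly) a list of in-memory stage products.
#' @export
run_pipeline <- function(study, out_dir,
                         params = context_params(),
                         cutoff_grid_km = c(0.5, 0.6, 0.75, 1, 1.5, 2, 3, 4, 5),
                         min_outdoor_minutes = 30, min_pairs = 50,
                         idw_power = 2, idw_max_radius_km = 50,
                         infer = FALSE, adjustment = "full",
                         force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory is not empty; use force = TRUE", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  tz <- if (!is.null(study$config$tz)) study$config$tz else
    (study$manifest$tz %||% "Etc/GMT+8")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- preprocess ----------------------------------------------------------
  clean <- stage("preprocess", {
    out <- preprocess_stream(study$stream)
    readr::write_csv(stage_log(out), p("stage_log.csv"))
    out
  })

  # -- context identification ---------------------------------------------
  labels <- stage("context", {
    lab <- identify_context(clean, study$landscape, params = params, tz = tz)
    write_labels_csv(lab, p("labels.csv"))
    lab
  })

  # -- calibration ---------------------------------------------------------
  calib <- stage("calibrate", {
    if (is.null(study$stations) || nrow(study$stations) == 0) {
      stop("no station series available")
    }
    sc <- suppressWarnings(
      scan_cutoffs(labels, clean, study$stations, study$landscape$origin,
                   grid_km = cutoff_grid_km,
                   min_outdoor_minutes = min_outdoor_minutes,
                   min_pairs = min_pairs))
    readr::write_csv(sc$scan, p("cutoff_scan.csv"))
    jsonlite::write_json(
      list(coef = as.list(sc$fit$coef), r2 = sc$fit$r2, rmse = sc$fit$rmse,
           n_pairs = sc$fit$n_pairs, cutoff_km = sc$fit$cutoff_km,
           var_participant = sc$fit$var_participant,
           var_residual = sc$fit$var_residual, singular = sc$fit$singular),
      p("calibration.json"), auto_unbox = TRUE, digits = NA)
    sc
  })
  calibrated <- apply_calibration(calib$fit, clean)

  # -- exposure assessment --------------------------------------------------
  exposure <- stage("assess", {
    lm_dat <- labelled_minutes(labels, calibrated)
    lc <- local_clock(lm_dat$timestamp_utc, tz)
    lm_dat$season <- meteorological_season(lc$month)
    lm_dat$hour_local <- lc$hour
    readr::write_csv(summarize_exposure(
      dplyr::rename(calibrated, conc = "pm25_cal")), p("summary_overall.csv"))
    readr::write_csv(summarize_exposure(lm_dat, "microenv"),
                     p("summary_microenv.csv"))
    readr::write_csv(summarize_exposure(
      dplyr::mutate(lm_dat, setting = ifelse(.data$indoor, "indoor",
                                             "outdoor")), "setting"),
      p("summary_setting.csv"))
    readr::write_csv(summarize_exposure(lm_dat, "season"),
                     p("summary_season.csv"))
    readr::write_csv(summarize_exposure(lm_dat, "hour_local"),
                     p("summary_hour.csv"))
    dose <- apportion_dose(lm_dat,
                           breathing_rate = study$config$breathing_rate %||% 0.012)
    readr::write_csv(dose$microenv, p("dose_microenv.csv"))
    readr::write_csv(dose$indoor_outdoor, p("dose_setting.csv"))
    tb <- time_budget(labels)
    readr::write_csv(tb$microenv, p("time_budget_microenv.csv"))
    readr::write_csv(tb$indoor_outdoor, p("time_budget_setting.csv"))
    home <- idw_home_cohort(study$stations, study$participants,
                            study$landscape, power = idw_power,
                            max_radius_km = idw_max_radius_km)
    home_out <- dplyr::mutate(home, hour = format(.data$hour,
                                                  "%Y-%m-%dT%H:%M:%SZ",
                                                  tz = "UTC"))
    readr::write_csv(home_out, p("home_series.csv"))
    cmp <- compare_personal_home(calibrated, home)
    jsonlite::write_json(
      list(r_minute = cmp$r_minute, r_hour = cmp$r_hour,
           po_median = cmp$po_median, po_iqr = cmp$po_iqr, n = cmp$n),
      p("personal_vs_home.json"), auto_unbox = TRUE, digits = NA)
    list(minutes = lm_dat, dose = dose, budget = tb, home = home,
         comparison = cmp)
  })

  # -- inference ------------------------------------------------------------
  model <- NULL
  if (infer) {
    model <- stage("infer", {
      design <- make_design(exposure$minutes, exposure$home,
                            study$participants, tz = tz)
      fit <- fit_exposure_model(design, adjustment = adjustment,
                                p_method = "normal")
      readr::write_csv(fit$coefficients, p("model_coefficients.csv"))
      readr::write_csv(fit$emms, p("model_emms.csv"))
      fit
    })
  }

  files <- setdiff(dir(out_dir), "manifest.json")
  manifest <- list(
    seed = study$config$seed %||% study$manifest$seed,
    config_hash = if (!is.null(study$config)) config_hash(study$config)
                  else study$manifest$config_hash,
    params = params, cutoff_grid_km = cutoff_grid_km,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(clean = clean, labels = labels, calibration = calib,
                 calibrated = calibrated, exposure = exposure,
                 model = model, manifest = manifest))
}

#' Hash an output tree
#'
#' MD5 of every file under `dir` (sorted relative paths), then a hash of
#' the concatenation — a cheap way to assert that two runs produced
#' identical output trees.
#'
#' @param dir directory.
#' @return a single hash string.
#' @export
hash_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  sums <- tools::md5sum(file.path(dir, files))
  rlang::hash(paste(files, unname(sums), collapse = "\n"))
}
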