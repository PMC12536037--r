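#' Build opportunistic collocation pairs
#'
#' In-situ calibration exploits hours in which the worn sensor is outdoors:
#' for every (participant, UTC hour) with at least `min_outdoor_minutes`
#' outdoor-labelled minutes, the hourly means of the raw mass channel,
#' relative humidity, temperature and position are paired with the
#' *nearest* regulatory station, provided that station lies within
#' `cutoff_km` of the hour's mean outdoor position and reports a value for
#' that hour.
#'
#' @param labels context labels (only `indoor == FALSE` minutes are used).
#' @param stream the minute stream carrying raw `pm25`, `rh_pct`, `temp_c`,
#'   `lat`, `lon`.
#' @param stations hourly station tibble (`station_id`, `lat`, `lon`,
#'   `timestamp_utc`, `pm25`).
#' @param origin projection origin (use `landscape$origin`).
#' @param cutoff_km pairing cut-off distance, km.
#' @param min_outdoor_minutes minimum outdoor support per hour (default
#'   30).
#' @return a tibble of collocation pairs: participant, hour, `raw`, `rh`,
#'   `temp`, `station_id`, `ref` (station PM2.5), `dist_m`.
#' @export
build_pairs <- function(labels, stream, stations, origin, cutoff_km,
                        min_outdoor_minutes = 30) {
  if (nrow(stations) == 0) stop("no stations supplied", call. = FALSE)
  outdoor <- labels[!labels$indoor, c("participant_id", "timestamp_utc")]
  dat <- dplyr::inner_join(outdoor, stream,
                           by = c("participant_id", "timestamp_utc"))
  xy <- project_lonlat(dat$lon, dat$lat, origin)
  dat$x <- xy$x; dat$y <- xy$y
  hourly <- dat |>
    dplyr::mutate(hour = floor_hour(.data$timestamp_utc)) |>
    dplyr::group_by(.data$participant_id, .data$hour) |>
    dplyr::summarise(
      n_outdoor = dplyr::n(),
      raw = mean(.data$pm25), rh = mean(.data$rh_pct),
      temp = mean(.data$temp_c),
      mx = mean(.data$x, na.rm = TRUE), my = mean(.data$y, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::filter(.data$n_outdoor >= min_outdoor_minutes,
                  is.finite(.data$mx))

  st_coords <- dplyr::distinct(stations, .data$station_id, .data$lat,
                               .data$lon)
  st_xy <- project_lonlat(st_coords$lon, st_coords$lat, origin)
  dmat <- outer(hourly$mx, st_xy$x, "-")^2 + outer(hourly$my, st_xy$y, "-")^2
  nearest <- max.col(-dmat, ties.method = "first")
  hourly$station_id <- st_coords$station_id[nearest]
  hourly$dist_m <- sqrt(dmat[cbind(seq_len(nrow(hourly)), nearest)])

  hourly |>
    dplyr::filter(.data$dist_m <= cutoff_km * 1000) |>
    dplyr::inner_join(
      stations[c("station_id", "timestamp_utc", "pm25")],
      by = c("station_id", hour = "timestamp_utc")) |>
    dplyr::rename(ref = "pm25") |>
    dplyr::select("participant_id", "hour", "n_outdoor", "raw", "rh",
                  "temp", "station_id", "ref", "dist_m")
}

#' Fit the in-situ calibration mixed model
#'
#' Regresses the reference (station) PM2.5 on the raw sensor channel, with
#' relative humidity and temperature as optical-sensor nuisance covariates
#' and a random intercept per participant, by REML. If the mixed fit is
#' singular or the grouping is degenerate, the model falls back to ordinary
#' least squares with a warning flag. Goodness of fit (R-squared as the
#' squared Pearson correlation of fitted vs reference, and RMSE) is
#' computed on the training pairs.
#'
#' @param pairs a [build_pairs()] tibble.
#' @param covariates nuisance covariate names among the pair columns
#'   (default `c("rh", "temp")`).
#' @param min_pairs minimum number of pairs required (default 50).
#' @return a `pm_calibration` object: `coef` (named fixed effects),
#'   `r2`, `rmse`, `n_pairs`, `var_participant`, `var_residual`,
#'   `singular`, `cutoff_km` (filled by [scan_cutoffs()]), and the fitted
#'   model.
#' @export
fit_calibration <- function(pairs, covariates = c("rh", "temp"),
                            min_pairs = 50) {
  if (nrow(pairs) < min_pairs) {
    stop("only ", nrow(pairs), " collocation pairs; need >= ", min_pairs,
         call. = FALSE)
  }
  rhs <- paste(c("raw", covariates), collapse = " + ")
  singular <- FALSE
  fit <- tryCatch({
    m <- suppressMessages(
      lme4::lmer(stats::as.formula(paste0("ref ~ ", rhs,
                                          " + (1 | participant_id)")),
                 data = pairs, REML = TRUE))
    if (lme4::isSingular(m)) singular <- TRUE
    m
  }, error = function(e) {
    singular <<- TRUE
    NULL
  })
  if (is.null(fit) || singular) {
    fit <- stats::lm(stats::as.formula(paste0("ref ~ ", rhs)), data = pairs)
    warning("singular mixed fit; falling back to ordinary least squares")
  }
  coefs <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  fitted_vals <- stats::fitted(fit)
  vc <- if (inherits(fit, "merMod")) {
    v <- as.data.frame(lme4::VarCorr(fit))
    list(part = v$vcov[v$grp == "participant_id"][1],
         resid = v$vcov[v$grp == "Residual"][1])
  } else {
    list(part = 0, resid = summary(fit)$sigma^2)
  }
  structure(list(
    coef = coefs,
    covariates = covariates,
    r2 = stats::cor(fitted_vals, pairs$ref)^2,
    rmse = sqrt(mean((fitted_vals - pairs$ref)^2)),
    n_pairs = nrow(pairs),
    var_participant = vc$part,
    var_residual = vc$resid,
    singular = singular,
    cutoff_km = NA_real_,
    diag = tibble::tibble(ref = pairs$ref, fitted = as.numeric(fitted_vals)),
    model = fit
  ), class = "pm_calibration")
}

#' @export
print.pm_calibration <- function(x, ...) {
  cat("<pm_calibration> n =", x$n_pairs,
      " R2 =", round(x$r2, 3), " RMSE =", round(x$rmse, 3), "ug/m3\n")
  cat("  fixed effects:",
      paste(names(x$coef), round(x$coef, 4), sep = " = ", collapse = ", "),
      "\n")
  if (!is.na(x$cutoff_km)) cat("  cut-off:", x$cutoff_km, "km\n")
  if (x$singular) cat("  (singular mixed fit; OLS fallback)\n")
  invisible(x)
}

#' Scan pairing cut-off distances
#'
#' Refits the calibration at each cut-off in `grid_km` and selects the one
#' maximising R-squared; ties go to the smallest cut-off. The full
#' diagnostic table is always reported (R-squared need not be monotone in
#' the cut-off).
#'
#' @inheritParams build_pairs
#' @param grid_km cut-off grid, km. The default covers 0.5-5 km and
#'   includes a 0.6 km point for sub-km reporting granularity.
#' @param covariates,min_pairs passed to [fit_calibration()].
#' @return a list: `scan` (tibble of cutoff_km, n_pairs, r2, rmse),
#'   `selected_km`, and `fit` (the calibration at the selected cut-off,
#'   with `cutoff_km` filled in).
#' @export
scan_cutoffs <- function(labels, stream, stations, origin,
                         grid_km = c(0.5, 0.6, 0.75, 1, 1.5, 2, 3, 4, 5),
                         min_outdoor_minutes = 30,
                         covariates = c("rh", "temp"), min_pairs = 50) {
  stopifnot(length(grid_km) >= 1)
  rows <- purrr::map(sort(grid_km), function(ck) {
    pairs <- build_pairs(labels, stream, stations, origin, ck,
                         min_outdoor_minutes)
    fit <- tryCatch(
      suppressWarnings(fit_calibration(pairs, covariates, min_pairs)),
      error = function(e) NULL)
    tibble::tibble(
      cutoff_km = ck, n_pairs = nrow(pairs),
      r2 = if (is.null(fit)) NA_real_ else fit$r2,
      rmse = if (is.null(fit)) NA_real_ else fit$rmse)
  })
  scan <- dplyr::bind_rows(rows)
  if (all(is.na(scan$r2))) {
    stop("no cut-off yields enough collocation pairs", call. = FALSE)
  }
  best <- scan$cutoff_km[which.max(scan$r2)] # first max = smallest cutoff
  pairs <- build_pairs(labels, stream, stations, origin, best,
                       min_outdoor_minutes)
  fit <- suppressWarnings(fit_calibration(pairs, covariates, min_pairs))
  fit$cutoff_km <- best
  list(scan = scan, selected_km = best, fit = fit)
}

#' Apply a calibration to a minute stream
#'
#' Every minute's mass channel is replaced by the fixed-effects prediction
#' (random intercepts are excluded so the correction generalises to
#' non-collocated conditions). Negative predictions are floored at zero and
#' counted.
#'
#' @param fit a `pm_calibration`.
#' @param stream a minute stream with `pm25`, `rh_pct`, `temp_c`.
#' @return the stream with an added `pm25_cal` column; attribute
#'   `n_floored`.
#' @export
apply_calibration <- function(fit, stream) {
  stopifnot(inherits(fit, "pm_calibration"))
  co <- fit$coef
  pred <- co[["(Intercept)"]] + co[["raw"]] * stream$pm25
  cov_map <- c(rh = "rh_pct", temp = "temp_c")
  for (cv in fit$covariates) {
    col <- if (cv %in% names(cov_map)) cov_map[[cv]] else cv
    pred <- pred + co[[cv]] * stream[[col]]
  }
  n_floored <- sum(pred < 0, na.rm = TRUE)
  stream$pm25_cal <- pmax(pred, 0)
  structure(stream, n_floored = n_floored)
}

#' Simulate hourly collocation pairs from the sensor-distortion model
#'
#' Emulates the pair-building stage directly: hourly reference
#' concentrations drawn from a seasonal/diurnal AR background, raw hourly
#' sensor means obtained by inverting the linear distortion
#' `ref = slope * raw + intercept` with mean-one lognormal noise shrunk by
#' the square root of the minutes averaged per hour, plus humidity and
#' temperature columns that carry no signal. Useful for parameter-recovery
#' checks of [fit_calibration()] without a full world.
#'
#' @param n number of pairs.
#' @param slope,intercept true distortion.
#' @param noise_sd minute-level lognormal sigma (default 0.2).
#' @param minutes_per_hour minutes averaged per pair (default 45).
#' @param n_participants pairs are spread over this many participants.
#' @param seed RNG seed.
#' @return a tibble shaped like [build_pairs()] output.
#' @export
simulate_collocation_pairs <- function(n, slope = 0.5, intercept = 2,
                                       noise_sd = 0.2,
                                       minutes_per_hour = 45,
                                       n_participants = 20, seed = 1) {
  with_seed(seed, {
    hour <- seq_len(n)
    truth <- pmax(6 + 3 * cos(2 * pi * hour / (24 * 365)) +
                    2 * cos(2 * pi * (hour %% 24 - 19) / 24) +
                    as.numeric(stats::arima.sim(list(ar = 0.7), n, sd = 1)),
                  1)
    sd_h <- noise_sd / sqrt(minutes_per_hour)
    raw <- (truth - intercept) / slope * exp(stats::rnorm(n, 0, sd_h) -
                                               sd_h^2 / 2)
    tibble::tibble(
      participant_id = sprintf("P%03d", 1 + (hour %% n_participants)),
      hour = as.POSIXct("2019-01-01", tz = "UTC") + hour * 3600,
      n_outdoor = minutes_per_hour,
      raw = raw,
      rh = 70 + stats::rnorm(n, 0, 5),
      temp = 10 + stats::rnorm(n, 0, 5),
      station_id = "S01", ref = truth, dist_m = 400)
  })
}
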