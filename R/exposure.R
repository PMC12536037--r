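#' Join calibrated minutes to their context labels
#'
#' @param labels context labels.
#' @param stream a calibrated stream (with `pm25_cal`).
#' @return labelled minutes with concentration column `conc`
#'   (`pm25_cal`).
#' @export
labelled_minutes <- function(labels, stream) {
  dplyr::inner_join(
    labels,
    dplyr::select(stream, "participant_id", "timestamp_utc",
                  conc = "pm25_cal"),
    by = c("participant_id", "timestamp_utc"))
}

quantile_linear <- function(x, p) {
  # linear interpolation between order statistics (quantile type 7)
  unname(stats::quantile(x, p, type = 7, names = FALSE))
}

#' Distribution summaries of exposure concentrations
#'
#' The standard descriptive set: n, mean, sd, the 2.5/25/50/75/97.5th
#' percentiles (linear interpolation between order statistics), minimum and
#' maximum, per group. Empty groups are omitted.
#'
#' @param data a tibble with a concentration column.
#' @param group_by character vector of grouping columns (may be empty for
#'   an overall summary).
#' @param value name of the concentration column (default `"conc"`).
#' @return a tibble, one row per group.
#' @export
summarize_exposure <- function(data, group_by = character(), value = "conc") {
  if (!value %in% names(data)) stop("no column `", value, "`", call. = FALSE)
  missing_keys <- setdiff(group_by, names(data))
  if (length(missing_keys)) {
    stop("unknown grouping key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sd = stats::sd(.data[[value]]),
      p2.5 = quantile_linear(.data[[value]], 0.025),
      p25 = quantile_linear(.data[[value]], 0.25),
      p50 = quantile_linear(.data[[value]], 0.50),
      p75 = quantile_linear(.data[[value]], 0.75),
      p97.5 = quantile_linear(.data[[value]], 0.975),
      min = min(.data[[value]]),
      max = max(.data[[value]]),
      .groups = "drop")
}

#' Microenvironment dose apportionment
#'
#' Inhaled dose in microenvironment k is `breathing_rate` times the sum of
#' the minute concentrations spent there (ug, with the rate in m3/min and
#' 1-minute sampling); the dose proportion is its share of the total. The
#' indoor/outdoor split is computed the same way. Proportions are invariant
#' to the (constant) breathing rate and sum to one.
#'
#' @param data labelled, calibrated minutes ([labelled_minutes()]),
#'   normally after the valid-day filter.
#' @param breathing_rate m3/min (default 0.012).
#' @return a `pm_dose` list of two tibbles: `microenv` (minutes,
#'   time_fraction, mean_conc, dose_ug, dose_prop) and `indoor_outdoor`.
#' @export
apportion_dose <- function(data, breathing_rate = 0.012) {
  stopifnot(breathing_rate > 0)
  total <- breathing_rate * sum(data$conc)
  if (!isTRUE(total > 0)) {
    stop("zero total dose; proportions undefined", call. = FALSE)
  }
  by_micro <- data |>
    dplyr::group_by(microenv = .data$microenv) |>
    dplyr::summarise(minutes = dplyr::n(),
                     mean_conc = mean(.data$conc),
                     dose_ug = breathing_rate * sum(.data$conc),
                     .groups = "drop") |>
    dplyr::mutate(time_fraction = .data$minutes / sum(.data$minutes),
                  dose_prop = .data$dose_ug / sum(.data$dose_ug))
  by_io <- data |>
    dplyr::group_by(setting = ifelse(.data$indoor, "indoor", "outdoor")) |>
    dplyr::summarise(minutes = dplyr::n(),
                     mean_conc = mean(.data$conc),
                     dose_ug = breathing_rate * sum(.data$conc),
                     .groups = "drop") |>
    dplyr::mutate(time_fraction = .data$minutes / sum(.data$minutes),
                  dose_prop = .data$dose_ug / sum(.data$dose_ug))
  stopifnot(abs(sum(by_micro$dose_prop) - 1) < 1e-9,
            abs(sum(by_io$dose_prop) - 1) < 1e-9)
  structure(list(microenv = by_micro, indoor_outdoor = by_io,
                 breathing_rate = breathing_rate, total_dose_ug = total),
            class = "pm_dose")
}

#' @export
print.pm_dose <- function(x, ...) {
  cat("<pm_dose> total", round(x$total_dose_ug, 1), "ug over",
      sum(x$microenv$minutes), "labelled minutes\n")
  print(x$microenv)
  invisible(x)
}

#' Time budgets across microenvironments and indoor/outdoor
#'
#' @param labels context labels.
#' @return a list of tibbles `microenv` and `indoor_outdoor` with time
#'   fractions over labelled minutes (each partition sums to 1).
#' @export
time_budget <- function(labels) {
  micro <- labels |>
    dplyr::count(microenv = .data$microenv, name = "minutes") |>
    dplyr::mutate(fraction = .data$minutes / sum(.data$minutes))
  io <- labels |>
    dplyr::count(setting = ifelse(.data$indoor, "indoor", "outdoor"),
                 name = "minutes") |>
    dplyr::mutate(fraction = .data$minutes / sum(.data$minutes))
  stopifnot(abs(sum(micro$fraction) - 1) < 1e-9,
            abs(sum(io$fraction) - 1) < 1e-9)
  list(microenv = micro, indoor_outdoor = io)
}

#' Inverse-distance-weighted home-address exposure series
#'
#' Reconstructs the hourly outdoor concentration at a home coordinate from
#' the station network: weights proportional to distance to the negative
#' `power` over all in-radius stations reporting that hour (weights sum to
#' 1). A station at the home location returns its own series. Hours with no
#' in-radius reporting station are missing and counted.
#'
#' @param stations hourly station tibble.
#' @param home_lonlat length-2 `c(lon, lat)` of the home.
#' @param origin projection origin.
#' @param hours POSIXct vector of UTC hours to interpolate (default: all
#'   station hours).
#' @param power IDW power (default 2).
#' @param max_radius_km station search radius (default 50).
#' @return a tibble `hour`, `pm25_idw`; attribute `n_missing_hours`.
#' @export
idw_home <- function(stations, home_lonlat, origin, hours = NULL,
                     power = 2, max_radius_km = 50) {
  st <- dplyr::distinct(stations, .data$station_id, .data$lat, .data$lon)
  st_xy <- project_lonlat(st$lon, st$lat, origin)
  home <- project_lonlat(home_lonlat[1], home_lonlat[2], origin)
  d <- sqrt((st_xy$x - home$x)^2 + (st_xy$y - home$y)^2)
  st$d <- d
  in_radius <- st$station_id[d <= max_radius_km * 1000]
  if (length(in_radius) == 0) {
    stop("no station within ", max_radius_km, " km of the home", call. = FALSE)
  }
  if (is.null(hours)) hours <- sort(unique(stations$timestamp_utc))

  wtab <- stations |>
    dplyr::filter(.data$station_id %in% in_radius,
                  .data$timestamp_utc %in% hours) |>
    dplyr::left_join(st[c("station_id", "d")], by = "station_id")
  eps <- 1e-9
  zero_d <- wtab$d < eps
  series <- wtab |>
    dplyr::mutate(w = ifelse(.data$d < eps, Inf, .data$d^(-power))) |>
    dplyr::group_by(hour = .data$timestamp_utc) |>
    dplyr::summarise(pm25_idw = if (any(is.infinite(.data$w))) {
      mean(.data$pm25[is.infinite(.data$w)])
    } else {
      sum(.data$w * .data$pm25) / sum(.data$w)
    }, .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(hour = hours), series, by = "hour")
  structure(out, n_missing_hours = sum(is.na(out$pm25_idw)))
}

#' Home-address IDW series for every participant
#'
#' @param stations hourly station tibble.
#' @param participants participant table with `home_x`, `home_y` (or
#'   lon/lat via `home_lonlat_cols`).
#' @param landscape the landscape (projection origin).
#' @param ... passed to [idw_home()].
#' @return a tibble `participant_id`, `hour`, `pm25_idw`.
#' @export
idw_home_cohort <- function(stations, participants, landscape, ...) {
  purrr::map_dfr(seq_len(nrow(participants)), function(i) {
    pr <- participants[i, ]
    ll <- unproject_xy(pr$home_x, pr$home_y, landscape$origin)
    hs <- idw_home(stations, c(ll$lon, ll$lat), landscape$origin, ...)
    dplyr::mutate(hs, participant_id = pr$participant_id, .before = 1)
  })
}

#' Compare personal exposure with the home-based reconstruction
#'
#' Aligns each calibrated minute with its hour's home-address IDW value and
#' reports the Pearson correlation at the minute scale and on hourly means
#' (temporal aggregation typically inflates the correlation), plus the
#' participant-level P/O ratio distribution: each participant's mean
#' personal exposure over their mean home-based exposure.
#'
#' @param stream calibrated stream (with `pm25_cal`).
#' @param home_series [idw_home_cohort()] output.
#' @return a list: `r_minute`, `r_hour`, `po` (per-participant tibble),
#'   `po_median`, `po_iqr` (length-2), and `n`.
#' @export
compare_personal_home <- function(stream, home_series) {
  dat <- stream |>
    dplyr::mutate(hour = floor_hour(.data$timestamp_utc)) |>
    dplyr::inner_join(home_series, by = c("participant_id", "hour")) |>
    dplyr::filter(!is.na(.data$pm25_idw), !is.na(.data$pm25_cal))
  if (nrow(dat) < 2) stop("fewer than 2 overlapping points", call. = FALSE)
  if (stats::sd(dat$pm25_idw) == 0 || stats::sd(dat$pm25_cal) == 0) {
    warning("constant series; correlation undefined")
    r_min <- NA_real_
  } else {
    r_min <- stats::cor(dat$pm25_cal, dat$pm25_idw)
  }
  hourly <- dat |>
    dplyr::group_by(.data$participant_id, .data$hour) |>
    dplyr::summarise(personal = mean(.data$pm25_cal),
                     home = mean(.data$pm25_idw), .groups = "drop")
  r_hour <- if (stats::sd(hourly$home) == 0 || stats::sd(hourly$personal) == 0)
    NA_real_ else stats::cor(hourly$personal, hourly$home)
  po <- dat |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(personal_mean = mean(.data$pm25_cal),
                     home_mean = mean(.data$pm25_idw), .groups = "drop") |>
    dplyr::mutate(po_ratio = .data$personal_mean / .data$home_mean)
  list(r_minute = r_min, r_hour = r_hour, po = po,
       po_median = stats::median(po$po_ratio),
       po_iqr = quantile_linear(po$po_ratio, c(0.25, 0.75)),
       n = nrow(dat))
}
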