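#' Default context-identification parameters
#'
#' Tunables of the GPS-to-microenvironment stage. Values are the package
#' defaults (the upstream literature on stay-point detection and trip-mode
#' rules does not pin them down); all are exposed here.
#'
#' @param median_window odd width (fixes) of the moving median filter.
#' @param max_gap_min longest GPS gap (minutes) filled by linear
#'   interpolation; longer gaps are excluded from context analysis.
#' @param eps_m stay-cluster radius: every member fix must lie within this
#'   distance of the cluster centroid.
#' @param min_duration_min minimum stay duration.
#' @param max_time_gap_min temporal contiguity is broken by gaps longer than
#'   this.
#' @param speed_threshold_ms trip-mode mean-speed threshold (m/s).
#' @param distance_threshold_m trip-mode path-length threshold (m).
#' @param buffer_m building buffer for the indoor test (the 10-m rule).
#' @param min_hours valid-day threshold: participant-days with less than
#'   this many labelled hours are removed (strictly less).
#' @return a named list.
#' @export
context_params <- function(median_window = 5L, max_gap_min = 10L,
                           eps_m = 30, min_duration_min = 5,
                           max_time_gap_min = 10,
                           speed_threshold_ms = 2.5,
                           distance_threshold_m = 500,
                           buffer_m = 10, min_hours = 6) {
  as.list(environment())
}

#' Project a wearable stream into the landscape's metric plane
#'
#' @param stream a minute stream with `lat`/`lon` columns (NA on gap
#'   minutes).
#' @param origin projection origin `c(lon0, lat0)` (use
#'   `landscape$origin`).
#' @return a fixes tibble: `participant_id`, `timestamp_utc`, `x`, `y`.
#' @export
project_stream <- function(stream, origin) {
  xy <- project_lonlat(stream$lon, stream$lat, origin)
  tibble::tibble(participant_id = stream$participant_id,
                 timestamp_utc = stream$timestamp_utc,
                 x = xy$x, y = xy$y)
}

#' Moving-median smoothing of GPS fixes
#'
#' Replaces each coordinate by the component-wise median over a centered
#' window of `window` fixes, shrunk at the track edges. Missing fixes stay
#' missing and are skipped when forming their neighbours' medians.
#'
#' @param fixes a [project_stream()] tibble, time-ordered within
#'   participant.
#' @param window odd integer >= 3.
#' @return the smoothed fixes tibble.
#' @export
smooth_gps <- function(fixes, window = 5L) {
  if (window %% 2 == 0 || window < 3) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  half <- (window - 1L) %/% 2L
  roll_med <- function(v) {
    n <- length(v)
    if (n == 1) return(v)
    mat <- vapply(-half:half, function(o) {
      idx <- seq_len(n) + o
      idx[idx < 1 | idx > n] <- NA_integer_
      v[idx]
    }, numeric(n))
    out <- apply(mat, 1, stats::median, na.rm = TRUE)
    out[is.na(v)] <- NA_real_ # gaps preserved
    out[is.nan(out)] <- NA_real_
    out
  }
  fixes |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(x = roll_med(.data$x), y = roll_med(.data$y)) |>
    dplyr::ungroup()
}

#' Linear imputation of short GPS gaps
#'
#' Gaps of at most `max_gap` minutes are filled by linear interpolation of
#' the projected coordinates against time; longer gaps (and leading or
#' trailing gaps) remain missing, and those minutes are excluded from the
#' context analysis while staying in the overall-exposure stream.
#'
#' @param fixes smoothed fixes.
#' @param max_gap longest imputable gap, minutes.
#' @return the fixes tibble with an added logical column `imputed`;
#'   attributes `n_imputed` and `n_unimputable`.
#' @export
impute_gps <- function(fixes, max_gap = 10L) {
  was_na <- is.na(fixes$x)
  out <- fixes |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      x = zoo::na.approx(.data$x, x = as.numeric(.data$timestamp_utc),
                         maxgap = max_gap, na.rm = FALSE),
      y = zoo::na.approx(.data$y, x = as.numeric(.data$timestamp_utc),
                         maxgap = max_gap, na.rm = FALSE)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(imputed = was_na & !is.na(.data$x))
  structure(out,
            n_imputed = sum(out$imputed),
            n_unimputable = sum(was_na & is.na(out$x)))
}

# Longest prefix-valid stay window starting at `i` on a chunk of fixes:
# grow j while every fix in [i, j] lies within eps of the running window
# centroid; stop at the first j that violates it.
grow_stay <- function(x, y, i, eps) {
  n <- length(x)
  j <- i
  while (j < n) {
    k <- j + 1L
    cx <- mean(x[i:k]); cy <- mean(y[i:k])
    if (max((x[i:k] - cx)^2 + (y[i:k] - cy)^2) > eps^2) break
    j <- k
  }
  j
}

#' Stay/trip segmentation of a GPS trajectory
#'
#' Density-based trajectory segmentation that enforces temporal contiguity:
#' a stay is a maximal temporally contiguous run of fixes that all lie
#' within `eps` metres of the run's centroid and that spans at least
#' `min_duration` minutes; remaining fixes are grouped into maximal
#' contiguous trip segments. Contiguity is broken by time gaps longer than
#' `max_time_gap` minutes (e.g. unimputable GPS outages).
#'
#' @param fixes imputed fixes (rows with missing coordinates are ignored).
#' @param eps stay radius, metres.
#' @param min_duration minimum stay span, minutes.
#' @param max_time_gap contiguity break, minutes.
#' @return the GPS-bearing fixes annotated with `segment_id` (per
#'   participant) and `segment_kind` ("stay"/"trip").
#' @export
detect_stays_trips <- function(fixes, eps = 30, min_duration = 5,
                               max_time_gap = 10) {
  fx <- fixes[!is.na(fixes$x) & !is.na(fixes$y), , drop = FALSE]
  if (nrow(fx) == 0) {
    return(dplyr::mutate(fx, segment_id = integer(0),
                         segment_kind = character(0)))
  }
  segment_one <- function(df) {
    tmin <- as.numeric(df$timestamp_utc) / 60
    n <- nrow(df)
    chunk <- cumsum(c(1, diff(tmin) > max_time_gap))
    kind <- character(n)
    seg <- integer(n)
    next_id <- 0L
    for (ch in unique(chunk)) {
      idx <- which(chunk == ch)
      x <- df$x[idx]; y <- df$y[idx]; tt <- tmin[idx]
      m <- length(idx)
      k <- rep(NA_character_, m)
      s <- rep(NA_integer_, m)
      i <- 1L
      while (i <= m) {
        j <- grow_stay(x, y, i, eps)
        if (j > i && (tt[j] - tt[i] + 1) >= min_duration) {
          next_id <- next_id + 1L
          k[i:j] <- "stay"; s[i:j] <- next_id
          i <- j + 1L
        } else {
          k[i] <- "trip"
          i <- i + 1L
        }
      }
      # maximal contiguous runs of trip fixes become trip segments
      is_trip <- k == "trip"
      if (any(is_trip)) {
        run <- cumsum(c(TRUE, diff(is_trip) != 0 | diff(seq_len(m)) != 1))
        for (r in unique(run[is_trip])) {
          sel <- which(run == r & is_trip)
          next_id <- next_id + 1L
          s[sel] <- next_id
        }
      }
      kind[idx] <- k; seg[idx] <- s
    }
    df$segment_id <- seg
    df$segment_kind <- kind
    df
  }
  fx |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~segment_one(.x)) |>
    dplyr::ungroup()
}

#' Segment summary table
#'
#' @param fixes output of [detect_stays_trips()].
#' @return one row per segment: participant, id, kind, fix count, start/end
#'   timestamps, duration (minutes) and centroid.
#' @export
summarize_segments <- function(fixes) {
  fixes |>
    dplyr::group_by(.data$participant_id, .data$segment_id,
                    .data$segment_kind) |>
    dplyr::summarise(
      n_fixes = dplyr::n(),
      start = min(.data$timestamp_utc), end = max(.data$timestamp_utc),
      duration_min = as.numeric(difftime(max(.data$timestamp_utc),
                                         min(.data$timestamp_utc),
                                         units = "mins")) + 1,
      cx = mean(.data$x), cy = mean(.data$y), .groups = "drop")
}

#' Microenvironment and indoor/outdoor labels for stay segments
#'
#' Each stay takes the land-use class of the nearest parcel polygon
#' (distance 0 when the centroid lies inside one; nearest-feature ties are
#' broken by the smallest feature index). The stay is indoor iff its
#' centroid lies within `buffer_m` metres of any building polygon. Stays
#' whose centroid falls outside the region polygon are removed and counted.
#'
#' @param fixes segmented fixes ([detect_stays_trips()]).
#' @param landscape a `pm_landscape` (or any list with `parcels`,
#'   `buildings`, `region` in the same projection as the fixes).
#' @param buffer_m indoor buffer, metres (default 10).
#' @return labels for stay minutes: `participant_id`, `timestamp_utc`,
#'   `microenv`, `indoor`, `segment_id`, `segment_kind`; attribute
#'   `n_out_of_region` (stays removed).
#' @export
assign_stay_context <- function(fixes, landscape, buffer_m = 10) {
  if (nrow(landscape$parcels) == 0) {
    stop("empty land-use layer", call. = FALSE)
  }
  bad_geom <- purrr::map_lgl(landscape$parcels$geometry,
                             ~!is.matrix(.x) || nrow(.x) < 3 || anyNA(.x))
  if (any(bad_geom)) {
    stop("invalid land-use geometry at feature(s) ",
         paste(which(bad_geom), collapse = ", "), call. = FALSE)
  }
  stays <- fixes[fixes$segment_kind == "stay", , drop = FALSE]
  if (nrow(stays) == 0) {
    out <- tibble::tibble(participant_id = character(),
                          timestamp_utc = as.POSIXct(character(), tz = "UTC"),
                          microenv = character(), indoor = logical(),
                          segment_id = integer(), segment_kind = character())
    return(structure(out, n_out_of_region = 0L))
  }
  cent <- stays |>
    dplyr::group_by(.data$participant_id, .data$segment_id) |>
    dplyr::summarise(cx = mean(.data$x), cy = mean(.data$y),
                     .groups = "drop")
  inside <- point_in_ring(cent$cx, cent$cy, landscape$region)
  n_out <- sum(!inside)
  cent <- cent[inside, , drop = FALSE]
  nf <- nearest_feature(cent$cx, cent$cy, landscape$parcels)
  cent$microenv <- landscape$parcels$class[nf$feature]
  cent$indoor <- min_dist_to_layer(cent$cx, cent$cy,
                                   landscape$buildings) <= buffer_m
  out <- stays |>
    dplyr::inner_join(cent[c("participant_id", "segment_id", "microenv",
                             "indoor")],
                      by = c("participant_id", "segment_id")) |>
    dplyr::select("participant_id", "timestamp_utc", "microenv", "indoor",
                  "segment_id", "segment_kind")
  structure(out, n_out_of_region = n_out)
}

#' Trip-mode classification and trip-minute labels
#'
#' Per-trip features are the mean and standard deviation of the
#' fix-to-fix speeds and the path length. A trip is vehicle-based iff the
#' mean speed exceeds `speed_threshold`, or the path is longer than
#' `distance_threshold` metres and mean + sd speed exceeds the threshold;
#' otherwise it is a walking trip. Vehicle minutes are labelled
#' (`vehicle`, indoor); walking minutes take the nearest land-use class at
#' each fix and are outdoor. Zero-duration trips are dropped with a
#' warning.
#'
#' @param fixes segmented fixes ([detect_stays_trips()]).
#' @param landscape a `pm_landscape`.
#' @param speed_threshold m/s (default 2.5).
#' @param distance_threshold metres (default 500).
#' @return labels for trip minutes in the same schema as
#'   [assign_stay_context()].
#' @export
classify_trip_mode <- function(fixes, landscape, speed_threshold = 2.5,
                               distance_threshold = 500) {
  trips <- fixes[fixes$segment_kind == "trip", , drop = FALSE]
  if (nrow(trips) == 0) {
    return(tibble::tibble(participant_id = character(),
                          timestamp_utc = as.POSIXct(character(), tz = "UTC"),
                          microenv = character(), indoor = logical(),
                          segment_id = integer(), segment_kind = character()))
  }
  feat <- trips |>
    dplyr::group_by(.data$participant_id, .data$segment_id) |>
    dplyr::arrange(.data$timestamp_utc, .by_group = TRUE) |>
    dplyr::summarise(
      n_fixes = dplyr::n(),
      path_m = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)),
      span_s = as.numeric(difftime(max(.data$timestamp_utc),
                                   min(.data$timestamp_utc), units = "secs")),
      mean_speed = {
        dt <- diff(as.numeric(.data$timestamp_utc))
        dd <- sqrt(diff(.data$x)^2 + diff(.data$y)^2)
        if (length(dd) == 0) NA_real_ else mean(dd / dt)
      },
      sd_speed = {
        dt <- diff(as.numeric(.data$timestamp_utc))
        dd <- sqrt(diff(.data$x)^2 + diff(.data$y)^2)
        if (length(dd) < 2) 0 else stats::sd(dd / dt)
      },
      .groups = "drop"
    )
  degenerate <- feat$n_fixes < 2 | feat$span_s <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-duration trip(s) dropped")
    feat <- feat[!degenerate, , drop = FALSE]
  }
  feat$vehicle <- feat$mean_speed > speed_threshold |
    (feat$path_m > distance_threshold &
       feat$mean_speed + feat$sd_speed > speed_threshold)

  labelled <- trips |>
    dplyr::inner_join(feat[c("participant_id", "segment_id", "vehicle")],
                      by = c("participant_id", "segment_id"))
  walk <- !labelled$vehicle
  microenv <- rep("vehicle", nrow(labelled))
  if (any(walk)) {
    nf <- nearest_feature(labelled$x[walk], labelled$y[walk],
                          landscape$parcels)
    microenv[walk] <- landscape$parcels$class[nf$feature]
  }
  labelled |>
    dplyr::mutate(microenv = microenv, indoor = .data$vehicle) |>
    dplyr::select("participant_id", "timestamp_utc", "microenv", "indoor",
                  "segment_id", "segment_kind")
}

#' Valid-day filter
#'
#' Removes participant-days (local calendar days under `tz`) carrying
#' strictly less than `min_hours` hours of labelled minutes.
#'
#' @param labels a context-label tibble.
#' @param min_hours threshold in hours (default 6; a day with exactly 6
#'   labelled hours is retained).
#' @param tz study timezone used to form calendar days.
#' @return the filtered labels; attribute `dropped_days` (tibble of
#'   participant_id, date, n_minutes).
#' @export
filter_valid_days <- function(labels, min_hours = 6, tz = "Etc/GMT+8") {
  day <- as.Date(format(as.POSIXlt(labels$timestamp_utc, tz = tz),
                        "%Y-%m-%d"))
  counts <- tibble::tibble(participant_id = labels$participant_id,
                           date = day) |>
    dplyr::count(.data$participant_id, .data$date, name = "n_minutes")
  bad <- counts[counts$n_minutes < min_hours * 60, , drop = FALSE]
  keep <- !paste(labels$participant_id, day) %in%
    paste(bad$participant_id, bad$date)
  structure(labels[keep, , drop = FALSE], dropped_days = bad)
}

#' Full context-identification stage
#'
#' Chains projection, median smoothing, gap imputation, stay/trip
#' segmentation, stay labelling, trip-mode classification and the valid-day
#' filter.
#'
#' @param stream a preprocessed minute stream.
#' @param landscape a `pm_landscape`.
#' @param params a [context_params()] list.
#' @param tz study timezone.
#' @param valid_days apply the valid-day filter (default TRUE).
#' @return the labels tibble (one row per labelled minute), sorted by
#'   participant and time; attributes `n_imputed`, `n_unimputable`,
#'   `n_out_of_region`, `dropped_days`.
#' @export
identify_context <- function(stream, landscape, params = context_params(),
                             tz = "Etc/GMT+8", valid_days = TRUE) {
  fixes <- project_stream(stream, landscape$origin) |>
    smooth_gps(window = params$median_window) |>
    impute_gps(max_gap = params$max_gap_min)
  n_imputed <- attr(fixes, "n_imputed")
  n_unimputable <- attr(fixes, "n_unimputable")
  segmented <- detect_stays_trips(fixes, eps = params$eps_m,
                                  min_duration = params$min_duration_min,
                                  max_time_gap = params$max_time_gap_min)
  stay_labels <- assign_stay_context(segmented, landscape,
                                     buffer_m = params$buffer_m)
  trip_labels <- classify_trip_mode(segmented, landscape,
                                    speed_threshold = params$speed_threshold_ms,
                                    distance_threshold = params$distance_threshold_m)
  labels <- dplyr::bind_rows(stay_labels, trip_labels) |>
    dplyr::arrange(.data$participant_id, .data$timestamp_utc)
  dropped_days <- NULL
  if (valid_days) {
    labels <- filter_valid_days(labels, min_hours = params$min_hours, tz = tz)
    dropped_days <- attr(labels, "dropped_days")
  }
  structure(labels,
            n_imputed = n_imputed, n_unimputable = n_unimputable,
            n_out_of_region = attr(stay_labels, "n_out_of_region"),
            dropped_days = dropped_days)
}

#' Minute-level context accuracy against ground truth
#'
#' @param labels context labels.
#' @param truth the generator's ground-truth tibble.
#' @return a one-row tibble: minutes compared, microenvironment accuracy,
#'   indoor accuracy, and joint accuracy (all in percent).
#' @export
context_accuracy <- function(labels, truth) {
  j <- dplyr::inner_join(
    labels, truth,
    by = c("participant_id", "timestamp_utc"),
    suffix = c("", "_true"))
  tibble::tibble(
    n = nrow(j),
    microenv_pct = 100 * mean(j$microenv == j$microenv_true),
    indoor_pct = 100 * mean(j$indoor == j$indoor_true),
    joint_pct = 100 * mean(j$microenv == j$microenv_true &
                             j$indoor == j$indoor_true)
  )
}
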