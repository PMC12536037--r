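#' Configuration of a synthetic personal-monitoring study
#'
#' Defines every knob of the synthetic world: cohort and monitoring window,
#' landscape and station network, GPS error process, the linear distortion of
#' the low-cost optical sensor, indoor infiltration and episodic indoor
#' sources, and behavioural time-budget targets. The defaults describe a
#' two-week, 168-participant cohort wearing 1-minute optical particle
#' sensors in a Pacific-Northwest urban region; tests and examples pass
#' smaller cohorts explicitly.
#'
#' The true sensor distortion is linear on the mass channel: the reference
#' concentration satisfies `ref = sensor_slope * raw + sensor_intercept`, so
#' the generator emits `raw = (truth - sensor_intercept) / sensor_slope`
#' times mean-one multiplicative lognormal noise. A linear fit of truth on
#' raw therefore recovers `(sensor_slope, sensor_intercept)`.
#'
#' @param seed integer master seed; every stochastic choice derives from it.
#' @param n_participants cohort size.
#' @param n_days monitoring days per participant (default 14).
#' @param region_center lon/lat of the study region centre.
#' @param region_size_km side length of the square study region.
#' @param region optional polygon ring (2-column lon/lat matrix) overriding
#'   the square region.
#' @param n_stations number of regulatory monitoring stations.
#' @param station_offsets_km optional n x 2 matrix of station offsets (km,
#'   east/north of the region centre); overrides automatic placement.
#' @param station_indep logical vector flagging stations whose series is
#'   independent of the regional ambient field (a detached airshed).
#' @param station_indep_sd standard deviation of the independent stations'
#'   AR(1) series (ug/m3).
#' @param gps_noise_sd isotropic GPS error, metres.
#' @param gps_gap_rate per-minute probability that the GPS fix is missing.
#' @param sensor_slope,sensor_intercept true linear distortion (unitless,
#'   ug/m3).
#' @param sensor_noise_sd sigma of the mean-one lognormal multiplicative
#'   sensor noise.
#' @param indoor_infiltration fraction of ambient PM2.5 penetrating indoors
#'   (0-1].
#' @param cooking_peak_hour local hour of the evening cooking peak.
#' @param cooking_boost mean amplitude of the cooking source (ug/m3).
#' @param winter_heating_boost additive indoor boost in meteorological
#'   winter (ug/m3).
#' @param breathing_rate inhalation rate, m3/min.
#' @param indoor_target,home_target behavioural targets: fraction of time
#'   indoors (vehicle counts as indoors) and in the residential
#'   microenvironment.
#' @param employed_prob probability a participant has a weekday workplace.
#' @param walk_speed,vehicle_speed nominal trip speeds, m/s.
#' @param ambient_mean,ambient_seasonal_amp,ambient_diurnal_amp closed-form
#'   ambient field: hourly mean `A0 + As*cos(2*pi*doy/365.25) +
#'   Ad*cos(2*pi*(hour-19)/24)` (ug/m3), floored at 1.
#' @param ambient_ar_phi,ambient_ar_sd AR(1) noise added to the ambient
#'   field (sd 0 switches it off).
#' @param start_date first possible local monitoring start date.
#' @param stagger_days participants start uniformly within this many days of
#'   `start_date` (0 = simultaneous; spreads the cohort across seasons).
#' @param tz IANA timezone of the study region (local clock for schedules,
#'   seasons and calendar days).
#' @return a `pm_world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_participants = 168L,
                         n_days = 14L,
                         region_center = c(-122.3, 47.6),
                         region_size_km = 20,
                         region = NULL,
                         n_stations = 3L,
                         station_offsets_km = NULL,
                         station_indep = NULL,
                         station_indep_sd = 6,
                         gps_noise_sd = 5,
                         gps_gap_rate = 0.02,
                         sensor_slope = 0.5,
                         sensor_intercept = 2.0,
                         sensor_noise_sd = 0.2,
                         indoor_infiltration = 0.6,
                         cooking_peak_hour = 19L,
                         cooking_boost = 15,
                         winter_heating_boost = 3,
                         breathing_rate = 0.012,
                         indoor_target = 0.78,
                         home_target = 0.67,
                         employed_prob = 0.5,
                         walk_speed = 1.4,
                         vehicle_speed = 12,
                         ambient_mean = 6,
                         ambient_seasonal_amp = 3,
                         ambient_diurnal_amp = 2,
                         ambient_ar_phi = 0.7,
                         ambient_ar_sd = 1,
                         start_date = as.Date("2019-01-07"),
                         stagger_days = 336L,
                         tz = "Etc/GMT+8") {
  stopifnot(
    n_days >= 1, n_participants >= 1,
    gps_gap_rate >= 0, gps_gap_rate < 1,
    indoor_infiltration > 0, indoor_infiltration <= 1,
    sensor_slope != 0, n_stations >= 1,
    indoor_target > 0, indoor_target <= 1,
    home_target > 0, home_target <= indoor_target
  )
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$landuse_classes <- landuse_classes()
  structure(cfg, class = "pm_world_config")
}

region_ring <- function(config) {
  if (!is.null(config$region)) {
    ring <- as.matrix(config$region)
    stopifnot(ncol(ring) == 2, nrow(ring) >= 3)
    return(ring)
  }
  half_deg_lat <- (config$region_size_km * 1000 / 2) / 111194.9
  half_deg_lon <- half_deg_lat / cos(config$region_center[2] * pi / 180)
  cx <- config$region_center[1]; cy <- config$region_center[2]
  cbind(lon = c(cx - half_deg_lon, cx + half_deg_lon, cx + half_deg_lon, cx - half_deg_lon),
        lat = c(cy - half_deg_lat, cy - half_deg_lat, cy + half_deg_lat, cy + half_deg_lat))
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Generate the synthetic landscape
#'
#' Lays out a deterministic (given the seed) urban landscape: a grid of
#' non-overlapping land-use parcels covering the core of the region, one
#' building footprint in every built-up parcel (all classes except parks and
#' "other"), and the regulatory station network. All geometry is kept in the
#' local metric projection with lon/lat available through the stored origin.
#'
#' @param config a [world_config()].
#' @return a `pm_landscape` list with tibbles `parcels` (id, class,
#'   geometry), `buildings` (id, parcel_id, geometry), `stations`
#'   (station_id, x, y, lon, lat, indep), the `region` ring, the projection
#'   `origin`, and the parcel size.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "pm_world_config"))
  ring_ll <- region_ring(config)
  if (ring_area(ring_ll) <= 0) {
    stop("region polygon has zero area; provide a non-degenerate region",
         call. = FALSE)
  }
  origin <- c(mean(range(ring_ll[, 1])), mean(range(ring_ll[, 2])))
  region <- as.matrix(project_lonlat(ring_ll[, 1], ring_ll[, 2], origin))

  parcel_m <- 500
  # enough residential parcels for the cohort's homes
  n_cells_needed <- max(81, ceiling(config$n_participants / 0.35))
  grid_n <- ceiling(sqrt(n_cells_needed))
  half_extent <- grid_n * parcel_m / 2
  stopifnot(half_extent < max(region[, 1])) # parcels must fit in the region

  centers <- expand.grid(
    cx = (seq_len(grid_n) - (grid_n + 1) / 2) * parcel_m,
    cy = (seq_len(grid_n) - (grid_n + 1) / 2) * parcel_m
  )
  class_weights <- c(commercial = 0.10, industrial = 0.08, office = 0.10,
                     park_open_space = 0.12, public_facilities = 0.10,
                     residential = 0.40, other = 0.10)
  classes <- with_seed(sub_seed(config$seed, "landscape"), {
    sample(names(class_weights), nrow(centers), replace = TRUE,
           prob = class_weights)
  })
  # guarantee at least one parcel of each class
  for (k in seq_along(class_weights)) {
    if (!names(class_weights)[k] %in% classes) classes[k] <- names(class_weights)[k]
  }
  parcels <- tibble::tibble(
    id = seq_len(nrow(centers)),
    class = classes,
    cx = centers$cx, cy = centers$cy,
    geometry = purrr::map2(centers$cx, centers$cy,
                           ~rect_ring(.x, .y, parcel_m, parcel_m))
  )
  built <- parcels$class %in% c("commercial", "industrial", "office",
                                "public_facilities", "residential")
  buildings <- parcels[built, ] |>
    dplyr::transmute(
      parcel_id = .data$id,
      id = dplyr::row_number(),
      cx = .data$cx, cy = .data$cy,
      geometry = purrr::map2(.data$cx, .data$cy, ~rect_ring(.x, .y, 20, 20))
    )

  if (!is.null(config$station_offsets_km)) {
    off <- as.matrix(config$station_offsets_km) * 1000
    indep <- config$station_indep %||% rep(FALSE, nrow(off))
  } else {
    k <- config$n_stations
    ang <- 2 * pi * (seq_len(k) - 1) / max(k, 1)
    rad <- ifelse(seq_len(k) == 1, 0, half_extent * 0.7)
    off <- cbind(rad * cos(ang), rad * sin(ang))
    indep <- rep(FALSE, k)
  }
  ll <- unproject_xy(off[, 1], off[, 2], origin)
  stations <- tibble::tibble(
    station_id = sprintf("S%02d", seq_len(nrow(off))),
    x = off[, 1], y = off[, 2], lon = ll$lon, lat = ll$lat,
    indep = indep
  )
  inside <- point_in_ring(stations$x, stations$y, region)
  stopifnot(all(inside))

  structure(
    list(parcels = parcels, buildings = buildings, stations = stations,
         region = region, origin = origin, parcel_m = parcel_m),
    class = "pm_landscape"
  )
}

#' Generate the participant table
#'
#' Assigns each participant a home (a residential building, preferring
#' parcels with a walkable park nearby), a weekday destination (workplace or
#' errand parcel at least ~1 km from home), a staggered monitoring start
#' date, and demographic attributes with cohort frequencies typical of a
#' volunteer twin registry (predominantly female, white, 30-59).
#'
#' @param config a [world_config()].
#' @param landscape a [generate_landscape()] result.
#' @return a tibble, one row per participant.
#' @export
generate_participants <- function(config, landscape) {
  p <- landscape$parcels
  parks <- p[p$class == "park_open_space", ]
  res <- p[p$class == "residential", ]
  stopifnot(nrow(res) > 0, nrow(parks) > 0)
  near_park <- purrr::map_dbl(seq_len(nrow(res)), function(i) {
    min(sqrt((parks$cx - res$cx[i])^2 + (parks$cy - res$cy[i])^2))
  })
  res <- res[order(near_park, res$id), ]
  work_pool <- p[p$class %in% c("office", "commercial", "industrial"), ]
  errand_pool <- p[p$class %in% c("public_facilities", "commercial"), ]

  n <- config$n_participants
  with_seed(sub_seed(config$seed, "participants"), {
    home_idx <- rep(seq_len(nrow(res)), length.out = n)
    pick_far <- function(pool, hx, hy, i) {
      d <- sqrt((pool$cx - hx)^2 + (pool$cy - hy)^2)
      far <- which(d >= 900)
      if (length(far) == 0) far <- which.max(d)
      far[1 + (i %% length(far))]
    }
    rows <- purrr::map_dfr(seq_len(n), function(i) {
      hr <- res[home_idx[i], ]
      wi <- pick_far(work_pool, hr$cx, hr$cy, i)
      ei <- pick_far(errand_pool, hr$cx, hr$cy, i)
      pk <- which.min(sqrt((parks$cx - hr$cx)^2 + (parks$cy - hr$cy)^2))
      tibble::tibble(
        participant_id = sprintf("P%03d", i),
        home_parcel = hr$id, home_x = hr$cx, home_y = hr$cy,
        work_parcel = work_pool$id[wi], work_x = work_pool$cx[wi],
        work_y = work_pool$cy[wi], work_class = work_pool$class[wi],
        errand_parcel = errand_pool$id[ei], errand_x = errand_pool$cx[ei],
        errand_y = errand_pool$cy[ei], errand_class = errand_pool$class[ei],
        park_parcel = parks$id[pk], park_x = parks$cx[pk],
        park_y = parks$cy[pk],
        employed = stats::runif(1) < config$employed_prob,
        start_date = config$start_date +
          sample.int(max(config$stagger_days, 1L), 1) - 1L
      )
    })
    demo <- tibble::tibble(
      age_group = sample(c("0-29", "30-39", "40-49", "50-59", "60+"), n,
                         replace = TRUE, prob = c(.13, .51, .09, .21, .06)),
      sex = sample(c("female", "male"), n, TRUE, prob = c(.79, .21)),
      marital = sample(c("unmarried", "married"), n, TRUE, prob = c(.41, .59)),
      race = sample(c("non-white", "white"), n, TRUE, prob = c(.06, .94)),
      edu = sample(c("lower than BA", "BA", "higher than BA"), n, TRUE,
                   prob = c(.21, .44, .35)),
      income = sample(c("low", "high"), n, TRUE, prob = c(.36, .64))
    )
    dplyr::bind_cols(rows, demo)
  })
}

# travel time in whole minutes at a nominal speed, at least 2 so every trip
# has >= 2 fixes
travel_minutes <- function(dist_m, speed) max(2L, as.integer(ceiling(dist_m / (speed * 60))))

#' Generate one participant's ground-truth schedule
#'
#' Builds an ordered sequence of visits (stays) joined by trips covering the
#' whole monitoring window, day by day: home overnight, a weekday indoor
#' destination (workplace or errand), an outdoor park visit sized so the
#' realized indoor-time fraction matches `indoor_target`, and evenings at
#' home. Trips to the park are walked when the park is within 600 m of home,
#' otherwise driven; destination trips are driven. Consecutive same-place
#' stays (across midnight) are merged.
#'
#' @param config a [world_config()].
#' @param landscape a [generate_landscape()] result.
#' @param participant one row of [generate_participants()].
#' @return a tibble of segments: `seg`, `kind` ("stay"/"trip"), `class`,
#'   `indoor`, `mode` (NA/"walk"/"vehicle"), endpoints `x`,`y` (stay
#'   location, or trip origin `x0`,`y0` -> destination `x1`,`y1`), and
#'   minute indices `start` (inclusive) / `end` (exclusive) from the local
#'   midnight of the participant's first monitoring day.
#' @export
generate_schedule <- function(config, landscape, participant) {
  stopifnot(nrow(participant) == 1)
  pr <- participant
  parcels <- landscape$parcels
  class_of <- function(pid) parcels$class[match(pid, parcels$id)]
  out_min <- round((1 - config$indoor_target) * 1440)
  home_min <- round(config$home_target * 1440)

  park_dist <- sqrt((pr$park_x - pr$home_x)^2 + (pr$park_y - pr$home_y)^2)
  walkable <- park_dist <= 600
  park_mode <- if (walkable) "walk" else "vehicle"
  wt <- travel_minutes(park_dist, if (walkable) config$walk_speed else config$vehicle_speed)
  walk_out <- if (walkable) 2L * wt else 0L

  segs <- list()
  with_seed(sub_seed(config$seed, pr$participant_id), {
    for (d in seq_len(config$n_days) - 1L) {
      base <- d * 1440L
      dow <- as.integer(format(pr$start_date + d, "%u")) # 1 = Monday
      weekday <- dow <= 5
      dest_is_work <- pr$employed && weekday
      dx <- if (dest_is_work) pr$work_x else pr$errand_x
      dy <- if (dest_is_work) pr$work_y else pr$errand_y
      dclass <- if (dest_is_work) pr$work_class else pr$errand_class
      vdist <- sqrt((dx - pr$home_x)^2 + (dy - pr$home_y)^2)
      vt <- travel_minutes(vdist, config$vehicle_speed)

      leave1 <- max(480L, min(600L, 540L + as.integer(round(stats::rnorm(1, 0, 15)))))
      mid <- max(20L, 60L + as.integer(round(stats::rnorm(1, 0, 10))))
      do <- out_min - walk_out
      have_park <- do >= 30
      if (!have_park) do <- 0L
      di <- 1440L - home_min - do -
        (if (have_park) 2L * wt else 0L) - 2L * vt
      have_dest <- di >= 30
      if (!have_dest) di <- 0L

      cur <- base
      add <- function(kind, class, indoor, mode, x, y, x1, y1, dur) {
        segs[[length(segs) + 1]] <<- tibble::tibble(
          kind = kind, class = class, indoor = indoor, mode = mode,
          x = x, y = y, x1 = x1, y1 = y1,
          start = cur, end = cur + as.integer(dur))
        cur <<- cur + as.integer(dur)
      }
      add("stay", "residential", TRUE, NA, pr$home_x, pr$home_y, NA, NA, leave1)
      if (have_dest) {
        add("trip", NA, NA, "vehicle", pr$home_x, pr$home_y, dx, dy, vt)
        add("stay", dclass, TRUE, NA, dx, dy, NA, NA, di)
        add("trip", NA, NA, "vehicle", dx, dy, pr$home_x, pr$home_y, vt)
        add("stay", "residential", TRUE, NA, pr$home_x, pr$home_y, NA, NA, mid)
      }
      if (have_park) {
        add("trip", NA, NA, park_mode, pr$home_x, pr$home_y, pr$park_x, pr$park_y, wt)
        add("stay", "park_open_space", FALSE, NA, pr$park_x, pr$park_y, NA, NA, do)
        add("trip", NA, NA, park_mode, pr$park_x, pr$park_y, pr$home_x, pr$home_y, wt)
      }
      add("stay", "residential", TRUE, NA, pr$home_x, pr$home_y, NA, NA,
          base + 1440L - cur)
    }
  })
  sched <- dplyr::bind_rows(segs)
  if (any(sched$end - sched$start < 1)) {
    stop("monitoring window shorter than one visit granule", call. = FALSE)
  }
  # merge consecutive same-location stays (e.g. across midnight)
  same_as_prev <- with(sched,
    kind == "stay" & dplyr::lag(kind) == "stay" &
      x == dplyr::lag(x) & y == dplyr::lag(y) &
      start == dplyr::lag(end))
  same_as_prev[is.na(same_as_prev)] <- FALSE
  grp <- cumsum(!same_as_prev)
  sched <- sched |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      kind = dplyr::first(.data$kind), class = dplyr::first(.data$class),
      indoor = dplyr::first(.data$indoor), mode = dplyr::first(.data$mode),
      x = dplyr::first(.data$x), y = dplyr::first(.data$y),
      x1 = dplyr::last(.data$x1), y1 = dplyr::last(.data$y1),
      start = dplyr::first(.data$start), end = dplyr::last(.data$end),
      .groups = "drop"
    ) |>
    dplyr::select(-".grp") |>
    dplyr::mutate(seg = dplyr::row_number(),
                  participant_id = pr$participant_id, .before = 1)
  stopifnot(sched$start[1] == 0,
            utils::tail(sched$end, 1) == config$n_days * 1440L,
            all(sched$start == dplyr::lag(sched$end, default = 0L)))
  sched
}

# Regional hourly ambient field over a span of UTC hours:
# closed-form seasonal + diurnal sinusoids plus optional AR(1) noise,
# floored at 1 ug/m3. The independent variant replaces the shared AR noise
# with its own, larger AR series (a detached airshed).
ambient_series <- function(config, hours_utc, seed_key = "ambient",
                           independent = FALSE) {
  lc <- local_clock(hours_utc, config$tz)
  det <- config$ambient_mean +
    config$ambient_seasonal_amp * cos(2 * pi * lc$yday / 365.25) +
    config$ambient_diurnal_amp * cos(2 * pi * (lc$hour - 19) / 24)
  n <- length(hours_utc)
  sd <- if (independent) config$station_indep_sd else config$ambient_ar_sd
  noise <- if (sd > 0) {
    with_seed(sub_seed(config$seed, seed_key), {
      as.numeric(stats::arima.sim(list(ar = config$ambient_ar_phi), n,
                                  sd = sd))
    })
  } else rep(0, n)
  pmax(det + noise, 1)
}

#' Generate minute streams, station series and ground truth
#'
#' Expands a schedule into the three downstream inputs: (1) the personal
#' minute stream exactly as the wearable device would log it (six particle
#' count channels, three mass channels, temperature, relative humidity, and
#' a noisy, gappy GPS fix); (2) the hourly regulatory-station series
#' (stations report the regional ambient field without error; stations
#' flagged `indep` report an independent series); and (3) the per-minute
#' ground truth of microenvironment, indoor flag, trip mode, segment id and
#' true exposure concentration.
#'
#' True exposure is the ambient field outdoors, 0.8 x ambient in vehicles,
#' and `indoor_infiltration x ambient` plus episodic cooking (triangular
#' pulse around `cooking_peak_hour` at home) and winter heating boosts
#' indoors. The raw sensor mass channel inverts the configured linear
#' distortion with mean-one lognormal noise and is floored at zero.
#'
#' @param config a [world_config()].
#' @param participants the [generate_participants()] tibble.
#' @param landscape the [generate_landscape()] result.
#' @return list with tibbles `stream`, `stations`, `truth`.
#' @export
generate_streams <- function(config, participants, landscape) {
  tz <- config$tz
  starts <- as.POSIXct(paste(participants$start_date, "00:00:00"), tz = tz)
  span <- range(c(starts, starts + config$n_days * 86400))
  hours_utc <- seq(floor_hour(span[1]) - 3600, floor_hour(span[2]) + 3600,
                   by = 3600)
  ambient <- ambient_series(config, hours_utc)
  ambient_indep <- ambient_series(config, hours_utc, "ambient-indep",
                                  independent = TRUE)
  lc_h <- local_clock(hours_utc, tz)

  station_tbl <- purrr::map_dfr(seq_len(nrow(landscape$stations)), function(i) {
    st <- landscape$stations[i, ]
    tibble::tibble(
      station_id = st$station_id, lat = st$lat, lon = st$lon,
      timestamp_utc = hours_utc,
      pm25 = if (isTRUE(st$indep)) ambient_indep else ambient
    )
  })

  per_part <- purrr::map(seq_len(nrow(participants)), function(i) {
    pr <- participants[i, ]
    sched <- generate_schedule(config, landscape, pr)
    n_min <- config$n_days * 1440L
    minute_idx <- seq_len(n_min) - 1L
    ts <- starts[i] + minute_idx * 60
    attr(ts, "tzone") <- "UTC"

    # per-minute true position and labels from the schedule
    seg_at <- findInterval(minute_idx, sched$start)
    sg <- sched[seg_at, ]
    frac <- (minute_idx - sg$start + 1) / (sg$end - sg$start + 1)
    x_true <- ifelse(sg$kind == "stay", sg$x, sg$x + frac * (sg$x1 - sg$x))
    y_true <- ifelse(sg$kind == "stay", sg$y, sg$y + frac * (sg$y1 - sg$y))
    trip <- sg$kind == "trip"
    walk <- trip & sg$mode == "walk"
    vehicle <- trip & sg$mode == "vehicle"

    microenv <- sg$class
    if (any(walk)) {
      nf <- nearest_feature(x_true[walk], y_true[walk], landscape$parcels)
      microenv[walk] <- landscape$parcels$class[nf$feature]
    }
    microenv[vehicle] <- "vehicle"
    indoor <- ifelse(vehicle, TRUE, ifelse(walk, FALSE, sg$indoor))
    mode <- ifelse(trip, sg$mode, "stay")

    lc <- local_clock(ts, tz)
    hidx <- match(floor_hour(ts), hours_utc)
    amb <- ambient[hidx]

    pseed <- sub_seed(config$seed, paste0("stream-", pr$participant_id))
    with_seed(pseed, {
      winter <- lc$month %in% c(12, 1, 2)
      at_home <- sg$kind == "stay" & sg$x == pr$home_x & sg$y == pr$home_y
      cook_amp_day <- config$cooking_boost *
        exp(stats::rnorm(config$n_days, 0, 0.4) - 0.4^2 / 2)
      day_i <- minute_idx %/% 1440L + 1L
      minute_of_day_local <- lc$hour * 60 + as.POSIXlt(ts, tz = tz)$min
      peak <- config$cooking_peak_hour * 60
      tri <- pmax(0, 1 - abs(minute_of_day_local - peak) / 60)
      cooking <- ifelse(indoor & at_home, cook_amp_day[day_i] * tri, 0)
      heating <- ifelse(indoor & at_home & winter, config$winter_heating_boost, 0)

      truth_conc <- ifelse(
        !indoor & !vehicle, amb,
        ifelse(vehicle, 0.8 * amb,
               config$indoor_infiltration * amb + cooking + heating))
      indoor_jitter <- exp(stats::rnorm(n_min, 0, 0.05) - 0.05^2 / 2)
      truth_conc <- ifelse(indoor & !vehicle, truth_conc * indoor_jitter,
                           truth_conc)

      raw_noise <- if (config$sensor_noise_sd > 0) {
        exp(stats::rnorm(n_min, 0, config$sensor_noise_sd) -
              config$sensor_noise_sd^2 / 2)
      } else rep(1, n_min)
      raw_pm25 <- pmax(
        (truth_conc - config$sensor_intercept) / config$sensor_slope * raw_noise,
        0)

      pnc_base <- raw_pm25 * 35
      fracs <- c(1, 0.35, 0.12, 0.02, 0.006, 0.001)
      pnc <- vapply(fracs, function(f) as.integer(round(pnc_base * f)),
                    integer(n_min))

      temp_out <- 10 + 8 * cos(2 * pi * (lc$yday - 200) / 365.25) +
        3 * cos(2 * pi * (lc$hour - 15) / 24)
      temp_c <- ifelse(indoor, 21 + stats::rnorm(n_min, 0, 0.5),
                       temp_out + stats::rnorm(n_min, 0, 0.5))
      rh_pct <- pmin(95, pmax(10, ifelse(indoor, 45, 70) +
                                stats::rnorm(n_min, 0, 3)))

      gx <- x_true + stats::rnorm(n_min, 0, config$gps_noise_sd)
      gy <- y_true + stats::rnorm(n_min, 0, config$gps_noise_sd)
      gap <- stats::runif(n_min) < config$gps_gap_rate
      ll <- unproject_xy(gx, gy, landscape$origin)
      lat <- ifelse(gap, NA_real_, ll$lat)
      lon <- ifelse(gap, NA_real_, ll$lon)

      stream <- tibble::tibble(
        participant_id = pr$participant_id,
        timestamp_utc = ts,
        pnc_gt0p3 = pnc[, 1], pnc_gt0p5 = pnc[, 2], pnc_gt1 = pnc[, 3],
        pnc_gt2p5 = pnc[, 4], pnc_gt5 = pnc[, 5], pnc_gt10 = pnc[, 6],
        pm1 = round(0.65 * raw_pm25, 3),
        pm25 = round(raw_pm25, 3),
        pm10 = round(1.25 * raw_pm25, 3),
        temp_c = round(temp_c, 2), rh_pct = round(rh_pct, 1),
        lat = lat, lon = lon
      )
      truth <- tibble::tibble(
        participant_id = pr$participant_id,
        timestamp_utc = ts,
        microenv = microenv, indoor = indoor, mode = mode,
        segment_id = sg$seg, conc_true = truth_conc,
        x_true = x_true, y_true = y_true
      )
      list(stream = stream, truth = truth)
    })
  })

  list(
    stream = dplyr::bind_rows(purrr::map(per_part, "stream")),
    stations = station_tbl,
    truth = dplyr::bind_rows(purrr::map(per_part, "truth"))
  )
}

#' Simulate a complete synthetic study
#'
#' One-call wrapper chaining [generate_landscape()],
#' [generate_participants()] and [generate_streams()]. The result carries
#' full ground truth for every downstream pipeline stage.
#'
#' @param config a [world_config()].
#' @return a `pm_study` list: `config`, `landscape`, `participants`,
#'   `stream`, `stations`, `truth`.
#' @export
simulate_study <- function(config = world_config()) {
  landscape <- generate_landscape(config)
  participants <- generate_participants(config, landscape)
  gs <- generate_streams(config, participants, landscape)
  structure(
    list(config = config, landscape = landscape, participants = participants,
         stream = gs$stream, stations = gs$stations, truth = gs$truth),
    class = "pm_study"
  )
}

#' @export
print.pm_study <- function(x, ...) {
  cat("<pm_study> ", nrow(x$participants), " participants x ",
      x$config$n_days, " days; ", nrow(x$stream), " minute records; ",
      nrow(x$landscape$stations), " stations\n", sep = "")
  invisible(x)
}

#' Configure a world with near and detached-airshed stations
#'
#' Builds a study configuration in which regulatory stations sit directly
#' at the outdoor (park) locations of roughly half the cohort, while the
#' remaining participants' nearest stations are placed 2.5 km away and
#' report a series independent of the regional ambient field (a detached
#' airshed). Under these conditions only collocations within about 1 km
#' share the sensor's airshed, so a calibration cut-off scan should settle
#' at or below 1 km.
#'
#' @param seed master seed.
#' @param n_participants,n_days cohort shape (defaults sized so the
#'   sub-kilometre cut-offs retain enough pairs to fit).
#' @param ... further arguments passed to [world_config()].
#' @return a `pm_world_config` with explicit station placement.
#' @export
world_decorrelated_stations <- function(seed = 1, n_participants = 6,
                                        n_days = 4, ...) {
  probe <- world_config(seed = seed, n_participants = n_participants,
                        n_days = n_days, stagger_days = 60, ...)
  ls <- generate_landscape(probe)
  pp <- generate_participants(probe, ls)
  parks <- dplyr::distinct(pp, .data$park_x, .data$park_y)
  # one correlated station at every outdoor (park) location, so all
  # airshed-sharing collocations already exist at the smallest cut-off
  near_xy <- cbind(parks$park_x, parks$park_y)
  # two detached-airshed stations, pushed east until >= 2 km from every
  # park; any pair they contribute (reachable only at cut-offs > 1 km)
  # carries an independent series
  far_xy <- cbind(mean(parks$park_x) + c(2500, 3500),
                  mean(parks$park_y) + c(0, 800))
  for (i in seq_len(nrow(far_xy))) {
    repeat {
      d <- sqrt((parks$park_x - far_xy[i, 1])^2 +
                  (parks$park_y - far_xy[i, 2])^2)
      if (min(d) >= 2000) break
      far_xy[i, 1] <- far_xy[i, 1] + 1000
    }
  }
  off <- rbind(near_xy, far_xy) / 1000
  world_config(seed = seed, n_participants = n_participants,
               n_days = n_days, stagger_days = 60,
               station_offsets_km = off,
               station_indep = c(rep(FALSE, nrow(near_xy)),
                                 rep(TRUE, nrow(far_xy))), ...)
}
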