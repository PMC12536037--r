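lab_conc <- function(conc, microenv = "residential", indoor = TRUE,
                     participant = "P001") {
  n <- length(conc)
  tibble::tibble(
    participant_id = participant,
    timestamp_utc = as.POSIXct("2019-01-07", tz = "UTC") + (seq_len(n) - 1) * 60,
    microenv = rep_len(microenv, n), indoor = rep_len(indoor, n),
    segment_id = 1L, segment_kind = "stay", conc = conc)
}

test_that("summaries reproduce the declared percentile rule", {
  s <- summarize_exposure(lab_conc(rep(5, 100)))
  expect_equal(s$mean, 5); expect_equal(s$sd, 0)
  expect_equal(unlist(s[c("p2.5", "p25", "p50", "p75", "p97.5")]),
               rep(5, 5), ignore_attr = TRUE)

  s2 <- summarize_exposure(lab_conc(sample(1:100)))
  expect_equal(s2$p50, 50.5)
  # independent oracle for the linear-interpolation rule: for sorted
  # 1..100, quantile p sits at 1 + 99p
  expect_equal(s2$p25, 1 + 99 * 0.25)
  expect_equal(s2$p97.5, 1 + 99 * 0.975)

  expect_error(summarize_exposure(lab_conc(1:5), "no_such_key"),
               "unknown grouping key")
  two <- dplyr::bind_rows(lab_conc(1:10, "residential"),
                          lab_conc(1:10, "office"))
  expect_equal(nrow(summarize_exposure(two, "microenv")), 2)
})

test_that("dose proportions equal time fractions under uniform concentration", {
  lab <- dplyr::bind_rows(
    lab_conc(rep(6, 300), "residential", TRUE),
    lab_conc(rep(6, 100), "office", TRUE),
    lab_conc(rep(6, 100), "park_open_space", FALSE))
  d <- apportion_dose(lab)
  expect_equal(d$microenv$dose_prop, d$microenv$time_fraction)
  expect_equal(sum(d$microenv$dose_prop), 1)

  # scale invariance in the breathing rate
  d2 <- apportion_dose(lab, breathing_rate = 0.024)
  expect_equal(d$microenv$dose_prop, d2$microenv$dose_prop)
  expect_equal(d2$total_dose_ug, 2 * d$total_dose_ug)

  solo <- apportion_dose(lab_conc(rep(4, 50)))
  expect_equal(solo$microenv$dose_prop, 1)
  expect_equal(solo$indoor_outdoor$dose_prop, 1)

  expect_error(apportion_dose(lab_conc(rep(0, 10))), "zero total dose")
})

test_that("time budgets are partitions", {
  lab <- dplyr::bind_rows(lab_conc(1:70, "residential", TRUE),
                          lab_conc(1:30, "park_open_space", FALSE))
  tb <- time_budget(lab)
  expect_equal(sum(tb$microenv$fraction), 1)
  expect_equal(sum(tb$indoor_outdoor$fraction), 1)
  expect_equal(tb$indoor_outdoor$fraction[tb$indoor_outdoor$setting == "indoor"],
               0.7)
  expect_equal(time_budget(lab_conc(1:5))$microenv$fraction, 1)
})

idw_scene <- function(st_lon, vals) {
  hours <- as.POSIXct("2019-01-07 00:00:00", tz = "UTC")
  purrr::imap_dfr(st_lon, function(lon, i) {
    tibble::tibble(station_id = sprintf("S%02d", i), lat = 47.6, lon = lon,
                   timestamp_utc = hours, pm25 = vals[i])
  })
}

test_that("IDW is exact at stations, symmetric at midpoints, matches arithmetic", {
  origin <- c(-122.3, 47.6)
  st <- idw_scene(c(-122.3, -122.28), c(4, 8))
  # home at the first station: its own value
  at_station <- idw_home(st, c(-122.3, 47.6), origin)
  expect_equal(at_station$pm25_idw, 4)
  # equidistant home: the mean
  mid <- idw_home(st, c(-122.29, 47.6), origin)
  expect_equal(mid$pm25_idw, 6)
  # as power grows IDW approaches nearest neighbour
  near <- idw_home(st, c(-122.295, 47.6), origin, power = 60)
  expect_equal(near$pm25_idw, 4, tolerance = 1e-6)

  # three stations at hand-set distances: sum(d^-2 x) / sum(d^-2)
  st3 <- idw_scene(c(-122.3, -122.28, -122.26), c(4, 8, 20))
  home <- c(-122.305, 47.6)
  xy <- project_lonlat(st3$lon[c(1, 2, 3)], st3$lat[c(1, 2, 3)], origin)
  h <- project_lonlat(home[1], home[2], origin)
  d <- sqrt((xy$x - h$x)^2 + (xy$y - h$y)^2)
  want <- sum(d^-2 * c(4, 8, 20)) / sum(d^-2)
  got <- idw_home(st3, home, origin)
  expect_equal(got$pm25_idw, want, tolerance = 1e-12)

  expect_error(idw_home(st3, c(-100, 30), origin, max_radius_km = 50),
               "no station")
})

test_that("IDW reports hours with no in-radius station as missing", {
  st <- idw_scene(c(-122.3), c(4))
  extra_hour <- st
  extra_hour$timestamp_utc <- st$timestamp_utc + 3600
  extra_hour$pm25 <- NA_real_
  out <- idw_home(dplyr::bind_rows(st, extra_hour), c(-122.3, 47.6),
                  c(-122.3, 47.6))
  expect_equal(attr(out, "n_missing_hours"), 1L)
})

test_that("personal-vs-home comparison handles identity and degeneracy", {
  hours <- as.POSIXct("2019-01-07 00:00:00", tz = "UTC") + (0:47) * 3600
  home <- tibble::tibble(participant_id = "P001", hour = hours,
                         pm25_idw = 5 + sin(seq_along(hours)))
  stream <- tibble::tibble(
    participant_id = "P001",
    timestamp_utc = rep(hours, each = 60) + rep(0:59 * 60, 48),
    pm25_cal = rep(home$pm25_idw, each = 60))
  cmp <- compare_personal_home(stream, home)
  expect_equal(cmp$r_minute, 1)
  expect_equal(cmp$r_hour, 1)
  expect_equal(cmp$po_median, 1)

  flat <- home; flat$pm25_idw <- 5
  expect_warning(cmp2 <- compare_personal_home(stream, flat), "constant")
  expect_true(is.na(cmp2$r_minute))
  expect_error(compare_personal_home(stream[1, ], home), "fewer than 2")
})

test_that("indoor spikes depress the correlation, more at minute scale", {
  hours <- as.POSIXct("2019-01-07 00:00:00", tz = "UTC") + (0:71) * 3600
  base <- 6 + 2 * sin(seq_along(hours) / 4)
  home <- tibble::tibble(participant_id = "P001", hour = hours,
                         pm25_idw = base)
  worse <- c()
  hour_ge_minute <- c()
  for (seed in 1:5) {
    set.seed(seed)
    minute_base <- rep(base, each = 60)
    spikes <- ifelse(runif(length(minute_base)) < 0.02,
                     rexp(length(minute_base), 1 / 30), 0)
    stream <- tibble::tibble(
      participant_id = "P001",
      timestamp_utc = rep(hours, each = 60) + rep(0:59 * 60, length(hours)),
      pm25_cal = minute_base + spikes)
    cmp <- compare_personal_home(stream, home)
    worse <- c(worse, cmp$r_minute < 1)
    hour_ge_minute <- c(hour_ge_minute, cmp$r_hour >= cmp$r_minute)
  }
  expect_true(all(worse))
  expect_gte(mean(hour_ge_minute), 0.6) # majority of seeds
})
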