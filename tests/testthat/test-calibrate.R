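# A hand-built collocation scene: one participant outdoors for a full hour
# at a known distance from each station.
pair_scene <- function(dist_km, n_outdoor = 60) {
  origin <- c(-122.3, 47.6)
  home <- project_lonlat(-122.3, 47.6, origin) # (0, 0)
  pos <- unproject_xy(dist_km * 1000, 0, origin)
  ts <- as.POSIXct("2019-01-07 10:00:00", tz = "UTC") +
    (seq_len(n_outdoor) - 1) * 60
  labels <- tibble::tibble(participant_id = "P001", timestamp_utc = ts,
                           microenv = "park_open_space", indoor = FALSE,
                           segment_id = 1L, segment_kind = "stay")
  stream <- tibble::tibble(participant_id = "P001", timestamp_utc = ts,
                           pm25 = 10, rh_pct = 50, temp_c = 15,
                           lat = pos$lat, lon = pos$lon)
  stations <- tibble::tibble(station_id = "S01", lat = 47.6, lon = -122.3,
                             timestamp_utc = as.POSIXct("2019-01-07 10:00:00",
                                                        tz = "UTC"),
                             pm25 = 7)
  list(labels = labels, stream = stream, stations = stations,
       origin = origin)
}

test_that("pairing respects the cut-off distance and the support rule", {
  sc <- pair_scene(0.4)
  p <- build_pairs(sc$labels, sc$stream, sc$stations, sc$origin,
                   cutoff_km = 0.6)
  expect_equal(nrow(p), 1)
  expect_equal(p$ref, 7)
  expect_equal(p$dist_m, 400, tolerance = 1e-6)

  far <- pair_scene(0.8)
  expect_equal(nrow(build_pairs(far$labels, far$stream, far$stations,
                                far$origin, cutoff_km = 0.6)), 0)

  short <- pair_scene(0.4, n_outdoor = 10)
  expect_equal(nrow(build_pairs(short$labels, short$stream, short$stations,
                                short$origin, cutoff_km = 0.6,
                                min_outdoor_minutes = 30)), 0)
  expect_error(build_pairs(sc$labels, sc$stream, sc$stations[0, ],
                           sc$origin, 0.6), "no stations")
})

test_that("calibration recovers the linear distortion and nuisance nulls", {
  pairs <- simulate_collocation_pairs(2000, slope = 0.5, intercept = 2,
                                      seed = 1)
  fit <- suppressWarnings(fit_calibration(pairs))
  expect_gt(fit$coef[["raw"]], 0.475)
  expect_lt(fit$coef[["raw"]], 0.525)
  expect_gt(fit$coef[["(Intercept)"]], 1.8)
  expect_lt(fit$coef[["(Intercept)"]], 2.2)
  # humidity and temperature carry no signal: their coefficients are
  # negligible next to the 0.5 mass-channel slope
  expect_lt(abs(fit$coef[["rh"]]), 0.01)
  expect_lt(abs(fit$coef[["temp"]]), 0.01)

  # noise-off limit: perfect fit
  exact <- simulate_collocation_pairs(500, noise_sd = 0, seed = 2)
  f0 <- suppressWarnings(fit_calibration(exact))
  expect_equal(f0$r2, 1, tolerance = 1e-9)
  expect_lt(f0$rmse, 1e-6)

  expect_error(fit_calibration(simulate_collocation_pairs(10, seed = 3)),
               "pairs")
})

test_that("holdout participants are predicted almost as well as training", {
  pairs <- simulate_collocation_pairs(2400, n_participants = 24, seed = 4)
  train <- pairs[pairs$participant_id <= "P012", ]
  test <- pairs[pairs$participant_id > "P012", ]
  fit <- suppressWarnings(fit_calibration(train))
  co <- fit$coef
  pred <- co[["(Intercept)"]] + co[["raw"]] * test$raw +
    co[["rh"]] * test$rh + co[["temp"]] * test$temp
  r2_test <- stats::cor(pred, test$ref)^2
  expect_lt(abs(r2_test - fit$r2), 0.1)
})

test_that("application floors negatives, preserves ranks, and identity is a no-op", {
  id_fit <- structure(list(coef = c("(Intercept)" = 0, raw = 1),
                           covariates = character()),
                      class = "pm_calibration")
  s <- make_stream(20)
  s$pm25 <- seq(1, 20)
  out <- apply_calibration(id_fit, s)
  expect_equal(out$pm25_cal, s$pm25)
  expect_equal(attr(out, "n_floored"), 0L)
  expect_equal(order(out$pm25_cal), order(s$pm25)) # monotone

  neg_fit <- structure(list(coef = c("(Intercept)" = -5, raw = 1),
                            covariates = character()),
                       class = "pm_calibration")
  s2 <- make_stream(3); s2$pm25 <- c(4.7, 10, 3)
  out2 <- apply_calibration(neg_fit, s2)
  expect_equal(out2$pm25_cal, c(0, 5, 0))
  expect_equal(attr(out2, "n_floored"), 2L)
})

test_that("calibration reduces minute-level error against truth", {
  cfg <- world_config(seed = 31, n_participants = 3, n_days = 2,
                      stagger_days = 20)
  st <- simulate_study(cfg)
  lab <- identify_context(st$stream, st$landscape, tz = cfg$tz)
  scn <- suppressWarnings(
    scan_cutoffs(lab, st$stream, st$stations, st$landscape$origin,
                 grid_km = c(2, 5), min_pairs = 20))
  cal <- apply_calibration(scn$fit, st$stream)
  j <- dplyr::inner_join(cal, st$truth,
                         by = c("participant_id", "timestamp_utc"))
  rmse_raw <- sqrt(mean((j$pm25 - j$conc_true)^2))
  rmse_cal <- sqrt(mean((j$pm25_cal - j$conc_true)^2))
  expect_lt(rmse_cal, rmse_raw)
})

test_that("cut-off scan reports the full grid and honours singletons", {
  sc <- pair_scene(0.4)
  # replicate the scene over many hours so a fit is possible
  hours <- 0:79
  labels <- purrr::map_dfr(hours, function(h) {
    l <- sc$labels; l$timestamp_utc <- l$timestamp_utc + h * 3600; l
  })
  stream <- purrr::map_dfr(hours, function(h) {
    s <- sc$stream; s$timestamp_utc <- s$timestamp_utc + h * 3600
    s$pm25 <- 10 + h %% 7 + stats::rnorm(nrow(s), 0, 0.05); s
  })
  stations <- purrr::map_dfr(hours, function(h) {
    st <- sc$stations; st$timestamp_utc <- st$timestamp_utc + h * 3600
    st$pm25 <- 2 + 0.5 * (10 + h %% 7); st
  })
  one <- suppressWarnings(scan_cutoffs(labels, stream, stations, sc$origin,
                                       grid_km = 1.5, min_pairs = 20))
  expect_equal(one$selected_km, 1.5)
  grid <- c(0.5, 1, 2)
  full <- suppressWarnings(scan_cutoffs(labels, stream, stations, sc$origin,
                                        grid_km = grid, min_pairs = 20))
  expect_equal(nrow(full$scan), length(grid))
  expect_error(
    suppressWarnings(scan_cutoffs(labels, stream, stations, sc$origin,
                                  grid_km = 0.1, min_pairs = 20)),
    "no cut-off")
})
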