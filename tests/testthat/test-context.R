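mini_fixes <- function(x, y, participant = "P001") {
  tibble::tibble(
    participant_id = participant,
    timestamp_utc = as.POSIXct("2019-01-07", tz = "UTC") +
      (seq_along(x) - 1) * 60,
    x = x, y = y)
}

# A hand-built landscape: residential parcel with a building at its centre,
# park parcel to the east, office parcel with building further east.
mini_landscape <- function() {
  parcels <- tibble::tibble(
    id = 1:3,
    class = c("residential", "park_open_space", "office"),
    cx = c(0, 500, 1000), cy = 0,
    geometry = list(rect_ring(0, 0, 500, 500), rect_ring(500, 0, 500, 500),
                    rect_ring(1000, 0, 500, 500)))
  buildings <- tibble::tibble(
    id = 1:2, parcel_id = c(1L, 3L), cx = c(0, 1000), cy = 0,
    geometry = list(rect_ring(0, 0, 20, 20), rect_ring(1000, 0, 20, 20)))
  structure(list(parcels = parcels, buildings = buildings,
                 stations = NULL, region = rect_ring(0, 0, 10000, 10000),
                 origin = c(-122.3, 47.6)),
            class = "pm_landscape")
}

test_that("median smoothing removes an isolated spike and respects edges", {
  # constant track unchanged
  fx <- mini_fixes(rep(10, 7), rep(20, 7))
  expect_equal(smooth_gps(fx, 5)$x, rep(10, 7))

  # a single 500 m spike in a window-5 track collapses to the neighbours'
  # median: window around index 4 is {0,0,500,0,0} -> median 0
  x <- c(0, 0, 0, 500, 0, 0, 0)
  sm <- smooth_gps(mini_fixes(x, x * 0), 5)
  expect_equal(sm$x[4], 0)

  # track of length 1 unchanged; even windows rejected
  expect_equal(smooth_gps(mini_fixes(3, 4), 5)$x, 3)
  expect_error(smooth_gps(fx, 4), "odd")
  expect_error(smooth_gps(fx, 1), "odd")
})

test_that("imputation fills short gaps linearly and flags long ones", {
  # constant-speed straight path with a 3-minute hole
  x <- seq(0, 900, by = 60)
  fx <- mini_fixes(x, x * 0.5)
  fx$x[c(5, 6, 7)] <- NA; fx$y[c(5, 6, 7)] <- NA
  out <- impute_gps(fx, max_gap = 10)
  expect_equal(out$x, x)
  expect_equal(out$y, x * 0.5)
  expect_equal(attr(out, "n_imputed"), 3L)
  expect_equal(attr(out, "n_unimputable"), 0L)

  # a 60-minute hole exceeds max_gap = 10
  fx2 <- mini_fixes(seq(0, 6000, by = 60), rep(0, 101))
  fx2$x[20:79] <- NA; fx2$y[20:79] <- NA
  out2 <- impute_gps(fx2, max_gap = 10)
  expect_equal(attr(out2, "n_unimputable"), 60L)
  expect_equal(sum(is.na(out2$x)), 60L)
})

test_that("imputation bookkeeping conserves the generator's dropped fixes", {
  cfg <- world_config(seed = 9, n_participants = 2, n_days = 1,
                      gps_gap_rate = 0.05, stagger_days = 10)
  st <- simulate_study(cfg)
  n_gap <- sum(is.na(st$stream$lat))
  fixes <- project_stream(st$stream, st$landscape$origin) |>
    smooth_gps(5) |>
    impute_gps(10)
  expect_equal(attr(fixes, "n_imputed") + attr(fixes, "n_unimputable"),
               n_gap)
})

test_that("a tight cluster forms a single stay", {
  set.seed(1)
  fx <- mini_fixes(rnorm(30, 0, 2), rnorm(30, 0, 2))
  seg <- detect_stays_trips(fx, eps = 30, min_duration = 5)
  expect_equal(unique(seg$segment_kind), "stay")
  expect_equal(unique(seg$segment_id), 1L)
})

test_that("stay-trip-stay structure is recovered on a noiseless commute", {
  cfg <- world_config(seed = 13, n_participants = 1, n_days = 1,
                      gps_noise_sd = 0, gps_gap_rate = 0, stagger_days = 5)
  st <- simulate_study(cfg)
  fixes <- project_stream(st$stream, st$landscape$origin) |>
    smooth_gps(5) |> impute_gps(10)
  seg <- detect_stays_trips(fixes)
  runs <- rle(seg$segment_kind)$values
  truth_runs <- rle(ifelse(st$truth$mode == "stay", "stay", "trip"))$values
  expect_equal(runs, truth_runs)
})

test_that("segmentation equals the exhaustive stay-enumeration oracle", {
  for (seed in 1:6) {
    n <- sample(50:200, 1)
    tr <- random_track(n, seed)
    got <- detect_stays_trips(tr, eps = 30, min_duration = 5,
                              max_time_gap = 10)
    want <- stays_bruteforce(tr$x, tr$y,
                             as.numeric(tr$timestamp_utc) / 60,
                             eps = 30, min_duration = 5, max_time_gap = 10)
    expect_equal(got$segment_kind, want, info = paste("seed", seed))
  }
})

test_that("stay context uses nearest parcel, 10-m building buffer, region", {
  ls <- mini_landscape()
  # three stays: at the residential building (indoor), in the park
  # (outdoor), and far outside the region
  fx <- dplyr::bind_rows(
    mini_fixes(rep(5, 10), rep(0, 10)),            # 5 m from building ring
    mini_fixes(rep(500, 10), rep(100, 10)),        # park, no building near
    mini_fixes(rep(50000, 10), rep(0, 10)))        # out of region
  fx$timestamp_utc <- as.POSIXct("2019-01-07", tz = "UTC") +
    (seq_len(nrow(fx)) - 1) * 60
  seg <- detect_stays_trips(fx, eps = 30, min_duration = 5,
                            max_time_gap = 2000)
  lab <- assign_stay_context(seg, ls, buffer_m = 10)
  expect_equal(attr(lab, "n_out_of_region"), 1L)
  got <- unique(lab[c("microenv", "indoor")])
  expect_equal(got$microenv, c("residential", "park_open_space"))
  expect_equal(got$indoor, c(TRUE, FALSE))

  # 15 m beyond the building ring is outdoor under a 10-m buffer, and
  # enlarging the buffer never flips indoor to outdoor
  fx2 <- mini_fixes(rep(25, 10), rep(0, 10)) # ring edge at x=10 -> 15 m out
  seg2 <- detect_stays_trips(fx2)
  expect_false(any(assign_stay_context(seg2, ls, buffer_m = 10)$indoor))
  expect_true(all(assign_stay_context(seg2, ls, buffer_m = 20)$indoor))
})

test_that("degenerate land-use layers are rejected", {
  ls <- mini_landscape()
  empty <- ls; empty$parcels <- empty$parcels[0, ]
  fx <- detect_stays_trips(mini_fixes(rep(0, 10), rep(0, 10)))
  expect_error(assign_stay_context(fx, empty), "empty land-use")
  broken <- ls; broken$parcels$geometry[[2]] <- matrix(1, 2, 2)
  expect_error(assign_stay_context(fx, broken), "feature")
})

test_that("trip-mode rule separates driving from strolling", {
  ls <- mini_landscape()
  # constant 12 m/s for 10 minutes -> vehicle, indoor
  drive <- mini_fixes(seq(0, by = 720, length.out = 10), rep(600, 10))
  drive$segment_id <- 1L; drive$segment_kind <- "trip"
  lab <- classify_trip_mode(drive, ls)
  expect_true(all(lab$microenv == "vehicle"))
  expect_true(all(lab$indoor))

  # 1.4 m/s stroll covering ~400 m through the park parcel -> outdoor park
  stroll <- mini_fixes(seq(320, by = 84, length.out = 6), rep(0, 6))
  stroll$segment_id <- 2L; stroll$segment_kind <- "trip"
  lab2 <- classify_trip_mode(stroll, ls)
  expect_true(all(lab2$microenv == "park_open_space"))
  expect_false(any(lab2$indoor))

  # single-fix trips are zero-duration and dropped with a warning
  lone <- mini_fixes(0, 0)
  lone$segment_id <- 3L; lone$segment_kind <- "trip"
  expect_warning(out <- classify_trip_mode(lone, ls), "zero-duration")
  expect_equal(nrow(out), 0)
})

test_that("valid-day filter is strict at six hours", {
  mk_day <- function(day, n) {
    tibble::tibble(
      participant_id = "P001",
      timestamp_utc = as.POSIXct(sprintf("2019-01-%02d 08:00:00", day),
                                 tz = "Etc/GMT+8") + (seq_len(n) - 1) * 60,
      microenv = "residential", indoor = TRUE,
      segment_id = day, segment_kind = "stay")
  }
  labels <- dplyr::bind_rows(mk_day(1, 359), mk_day(2, 360), mk_day(3, 500))
  out <- filter_valid_days(labels, min_hours = 6, tz = "Etc/GMT+8")
  expect_equal(nrow(out), 860)
  expect_equal(attr(out, "dropped_days")$n_minutes, 359)

  # 14 days with 2 sparse days -> 12 survive
  labels14 <- dplyr::bind_rows(lapply(1:14, function(d) {
    mk_day(d, if (d %in% c(4, 9)) 100 else 400)
  }))
  out14 <- filter_valid_days(labels14, tz = "Etc/GMT+8")
  days_left <- unique(as.Date(format(as.POSIXlt(out14$timestamp_utc,
                                                tz = "Etc/GMT+8"),
                                     "%Y-%m-%d")))
  expect_equal(length(days_left), 12)
})

test_that("every GPS-bearing in-region minute gets exactly one label, and a
           noiseless cohort is labelled perfectly", {
  cfg <- world_config(seed = 21, n_participants = 2, n_days = 2,
                      gps_noise_sd = 0, gps_gap_rate = 0, stagger_days = 20)
  st <- simulate_study(cfg)
  lab <- identify_context(st$stream, st$landscape, tz = cfg$tz,
                          valid_days = FALSE)
  expect_equal(nrow(lab), nrow(st$stream))
  expect_false(any(duplicated(lab[c("participant_id", "timestamp_utc")])))
  acc <- context_accuracy(lab, st$truth)
  expect_equal(acc$joint_pct, 100)
})
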