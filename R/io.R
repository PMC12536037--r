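#' Format readers and writers
#'
#' All on-disk formats are plain text: delimited CSV for the minute stream,
#' station series, labels and ground truth (timestamps always UTC
#' ISO-8601; lat/lon empty on gap minutes), and GeoJSON for the land-use,
#' building and region layers (WGS84 lon/lat on disk; all metric math
#' happens in the local projection). Readers are tolerant of unknown extra
#' columns (warn and ignore) but error on missing required columns, naming
#' them.
#'
#' @name pmtrace-io
NULL

stream_cols <- function() {
  c("participant_id", "timestamp_utc", pollution_cols(), "temp_c",
    "rh_pct", "lat", "lon")
}

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(what, ": ignoring unknown column(s): ",
            paste(extra, collapse = ", "))
    df <- df[required]
  }
  df
}

parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                   "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS"),
                    optional = TRUE)
  out
}

#' @rdname pmtrace-io
#' @param stream a minute-stream tibble.
#' @param path file path.
#' @export
write_stream_csv <- function(stream, path) {
  out <- stream
  out$timestamp_utc <- format(out$timestamp_utc, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname pmtrace-io
#' @export
read_stream_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                        col_types = readr::cols(
                          participant_id = readr::col_character(),
                          timestamp_utc = readr::col_character(),
                          .default = readr::col_double()))
  df <- check_schema(df, stream_cols(), "stream")
  df$timestamp_utc <- parse_utc(df$timestamp_utc)
  tibble::as_tibble(df)
}

#' @rdname pmtrace-io
#' @param stations hourly station tibble.
#' @export
write_stations_csv <- function(stations, path) {
  out <- stations
  out$timestamp_utc <- format(out$timestamp_utc, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname pmtrace-io
#' @export
read_stations_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          station_id = readr::col_character(),
                          timestamp_utc = readr::col_character(),
                          .default = readr::col_double()))
  df <- check_schema(df, c("station_id", "lat", "lon", "timestamp_utc",
                           "pm25"), "stations")
  df$timestamp_utc <- parse_utc(df$timestamp_utc)
  tibble::as_tibble(df)
}

#' @rdname pmtrace-io
#' @param labels a context-label tibble.
#' @export
write_labels_csv <- function(labels, path) {
  out <- labels
  out$timestamp_utc <- format(out$timestamp_utc, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  readr::write_csv(tibble::as_tibble(out), path, na = "")
  invisible(path)
}

#' @rdname pmtrace-io
#' @export
read_labels_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          participant_id = readr::col_character(),
                          timestamp_utc = readr::col_character(),
                          microenv = readr::col_character(),
                          indoor = readr::col_logical(),
                          .default = readr::col_guess()))
  df <- check_schema(df, c("participant_id", "timestamp_utc", "microenv",
                           "indoor", "segment_id", "segment_kind"),
                     "labels")
  df$timestamp_utc <- parse_utc(df$timestamp_utc)
  tibble::as_tibble(df)
}

ring_to_geojson_coords <- function(ring, origin) {
  ll <- unproject_xy(ring[, 1], ring[, 2], origin)
  coords <- cbind(round(ll$lon, 8), round(ll$lat, 8))
  coords <- rbind(coords, coords[1, , drop = FALSE]) # close the ring
  list(lapply(seq_len(nrow(coords)), function(i) c(coords[i, 1], coords[i, 2])))
}

geojson_coords_to_ring <- function(coords, origin) {
  pts <- do.call(rbind, lapply(coords[[1]], function(p) c(p[[1]], p[[2]])))
  # drop the closing vertex
  if (all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), , drop = FALSE]
  xy <- project_lonlat(pts[, 1], pts[, 2], origin)
  cbind(x = xy$x, y = xy$y)
}

#' @rdname pmtrace-io
#' @param landscape a `pm_landscape`.
#' @export
write_landuse_geojson <- function(landscape, path) {
  feats <- purrr::map(seq_len(nrow(landscape$parcels)), function(i) {
    list(type = "Feature",
         properties = list(id = landscape$parcels$id[i],
                           class = landscape$parcels$class[i]),
         geometry = list(
           type = "Polygon",
           coordinates = ring_to_geojson_coords(
             landscape$parcels$geometry[[i]], landscape$origin)))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pmtrace-io
#' @export
write_buildings_geojson <- function(landscape, path) {
  feats <- purrr::map(seq_len(nrow(landscape$buildings)), function(i) {
    list(type = "Feature",
         properties = list(id = landscape$buildings$id[i]),
         geometry = list(
           type = "Polygon",
           coordinates = ring_to_geojson_coords(
             landscape$buildings$geometry[[i]], landscape$origin)))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pmtrace-io
#' @export
write_region_geojson <- function(landscape, path) {
  obj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(name = "region"),
    geometry = list(type = "Polygon",
                    coordinates = ring_to_geojson_coords(
                      landscape$region, landscape$origin)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_geojson_features <- function(path, require_class = FALSE) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stopifnot(identical(obj$type, "FeatureCollection"))
  purrr::imap(obj$features, function(f, i) {
    props <- f$properties
    if (require_class && is.null(props$class)) {
      stop("GeoJSON feature ", i, " lacks a `class` property", call. = FALSE)
    }
    if (!identical(f$geometry$type, "Polygon")) {
      stop("GeoJSON feature ", i, " is not a Polygon", call. = FALSE)
    }
    list(properties = props, coordinates = f$geometry$coordinates)
  })
}

#' Read a landscape from its three GeoJSON layers
#'
#' @param landuse_path,buildings_path,region_path file paths.
#' @return a `pm_landscape` with geometry in the local projection about the
#'   region centroid.
#' @export
read_landscape_geojson <- function(landuse_path, buildings_path,
                                   region_path) {
  reg_feat <- read_geojson_features(region_path)
  reg_pts <- do.call(rbind, lapply(reg_feat[[1]]$coordinates[[1]],
                                   function(p) c(p[[1]], p[[2]])))
  origin <- c(mean(range(reg_pts[, 1])), mean(range(reg_pts[, 2])))
  region <- geojson_coords_to_ring(reg_feat[[1]]$coordinates, origin)

  lu <- read_geojson_features(landuse_path, require_class = TRUE)
  parcels <- tibble::tibble(
    id = purrr::map_int(lu, ~as.integer(.x$properties$id %||% NA)),
    class = purrr::map_chr(lu, ~.x$properties$class),
    geometry = purrr::map(lu, ~geojson_coords_to_ring(.x$coordinates, origin)))
  parcels$id[is.na(parcels$id)] <- which(is.na(parcels$id))
  parcels$cx <- purrr::map_dbl(parcels$geometry, ~mean(.x[, 1]))
  parcels$cy <- purrr::map_dbl(parcels$geometry, ~mean(.x[, 2]))

  bl <- read_geojson_features(buildings_path)
  buildings <- tibble::tibble(
    id = seq_along(bl),
    geometry = purrr::map(bl, ~geojson_coords_to_ring(.x$coordinates, origin)))
  buildings$cx <- purrr::map_dbl(buildings$geometry, ~mean(.x[, 1]))
  buildings$cy <- purrr::map_dbl(buildings$geometry, ~mean(.x[, 2]))

  structure(list(parcels = parcels, buildings = buildings,
                 stations = NULL, region = region, origin = origin),
            class = "pm_landscape")
}

config_hash <- function(config) {
  rlang::hash(lapply(unclass(config), function(v) {
    if (inherits(v, "Date")) as.character(v) else v
  }))
}

#' Write a complete synthetic study bundle to disk
#'
#' Emits the five data files (personal stream, station series, land-use,
#' building and region GeoJSON layers), the ground truth and participant
#' tables, and a manifest carrying the seed, a configuration hash and the
#' file list.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory.
#' @param force overwrite a non-empty directory (default FALSE: refuse).
#' @return the manifest (invisibly).
#' @export
write_study <- function(study, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force) {
    stop("output directory is not empty; use force = TRUE", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_stream_csv(study$stream, p("stream.csv"))
  write_stations_csv(study$stations, p("stations.csv"))
  write_landuse_geojson(study$landscape, p("landuse.geojson"))
  write_buildings_geojson(study$landscape, p("buildings.geojson"))
  write_region_geojson(study$landscape, p("region.geojson"))
  truth_out <- study$truth
  truth_out$timestamp_utc <- format(truth_out$timestamp_utc,
                                    "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(truth_out, p("ground_truth.csv"), na = "")
  part_out <- study$participants
  part_out$start_date <- as.character(part_out$start_date)
  readr::write_csv(part_out, p("participants.csv"), na = "")
  files <- c("stream.csv", "stations.csv", "landuse.geojson",
             "buildings.geojson", "region.geojson", "ground_truth.csv",
             "participants.csv")
  manifest <- list(seed = study$config$seed,
                   config_hash = config_hash(study$config),
                   n_participants = study$config$n_participants,
                   n_days = study$config$n_days,
                   tz = study$config$tz,
                   crs = "WGS84 lon/lat on disk; local equirectangular tangent plane for metric math",
                   files = files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a study bundle written by [write_study()]
#'
#' @param dir the bundle directory.
#' @return a list with `stream`, `stations`, `landscape`, `truth`,
#'   `participants`, `manifest`.
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  landscape <- read_landscape_geojson(p("landuse.geojson"),
                                      p("buildings.geojson"),
                                      p("region.geojson"))
  stations <- read_stations_csv(p("stations.csv"))
  st_coords <- dplyr::distinct(stations, .data$station_id, .data$lat,
                               .data$lon)
  st_xy <- project_lonlat(st_coords$lon, st_coords$lat, landscape$origin)
  landscape$stations <- dplyr::mutate(st_coords, x = st_xy$x, y = st_xy$y)
  truth <- readr::read_csv(p("ground_truth.csv"), show_col_types = FALSE)
  truth$timestamp_utc <- parse_utc(truth$timestamp_utc)
  participants <- readr::read_csv(p("participants.csv"),
                                  show_col_types = FALSE)
  participants$start_date <- as.Date(participants$start_date)
  list(stream = read_stream_csv(p("stream.csv")),
       stations = stations, landscape = landscape,
       truth = tibble::as_tibble(truth),
       participants = tibble::as_tibble(participants),
       manifest = jsonlite::fromJSON(p("manifest.json")))
}
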