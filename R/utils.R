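# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps every generator deterministic
# and independent of call order.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 32-bit sub-seed from a parent seed and an index/string.
sub_seed <- function(seed, key) {
  if (is.character(key)) key <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.double(seed) * 7919 + as.double(key) * 104729) %% 2147483629)
}

# Floor a POSIXct to the start of its UTC hour.
floor_hour <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 3600) * 3600,
             origin = "1970-01-01", tz = "UTC")
}

# Local-clock components of a UTC instant under the study timezone.
local_clock <- function(t, tz) {
  lt <- as.POSIXlt(t, tz = tz)
  list(
    date = as.Date(format(lt, "%Y-%m-%d")),
    hour = lt$hour,
    yday = lt$yday,
    month = lt$mon + 1L
  )
}

meteorological_season <- function(month) {
  dplyr::case_when(
    month %in% 3:5 ~ "spring",
    month %in% 6:8 ~ "summer",
    month %in% 9:11 ~ "autumn",
    TRUE ~ "winter"
  )
}

#' Microenvironment vocabulary
#'
#' The seven land-use classes plus the catch-all "other"; trips by vehicle
#' form the additional "vehicle" microenvironment.
#' @export
landuse_classes <- function() {
  c("commercial", "industrial", "office", "park_open_space",
    "public_facilities", "residential", "other")
}

#' @rdname landuse_classes
#' @export
microenv_levels <- function() c(landuse_classes(), "vehicle")
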