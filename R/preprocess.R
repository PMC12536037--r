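#' Record- and participant-level quality filtering
#'
#' Two sequential filters with full stage accounting: dropping records with
#' missing identity, timestamp or pollution channels, and dropping
#' participants whose particle channels are all-zero for more than 99% of
#' their monitoring time. GPS missingness never drops a record here: minutes
#' without a fix still contribute to the overall exposure assessment.
#'
#' Stage accounting follows the convention that percentages are always
#' expressed against the *raw* total, not the previous stage, so the ledger
#' reads like "dropped N records (x.x% of raw)".
#'
#' @name preprocess
NULL

pollution_cols <- function() {
  c("pnc_gt0p3", "pnc_gt0p5", "pnc_gt1", "pnc_gt2p5", "pnc_gt5", "pnc_gt10",
    "pm1", "pm25", "pm10")
}

new_stage_log <- function(raw_total) {
  tibble::tibble(stage = character(), dropped = integer(),
                 remaining = integer(), pct_of_raw = numeric(),
                 raw_total = integer()) |>
    structure(raw_total = as.integer(raw_total))
}

add_stage <- function(log, stage, dropped, remaining) {
  raw <- attr(log, "raw_total")
  out <- dplyr::bind_rows(log, tibble::tibble(
    stage = stage, dropped = as.integer(dropped),
    remaining = as.integer(remaining),
    pct_of_raw = round(100 * dropped / raw, 1),
    raw_total = raw))
  structure(out, raw_total = raw)
}

#' Format a stage percentage the way monitoring ledgers print it
#'
#' @param dropped,raw_total counts.
#' @return a string like `"0.9 %"` (one decimal, percent of the raw total).
#' @export
format_stage_pct <- function(dropped, raw_total) {
  sprintf("%.1f %%", 100 * dropped / raw_total)
}

#' Drop records with missing identity, timestamp or pollution data
#'
#' A record survives iff its `participant_id`, `timestamp_utc` and all nine
#' pollution channels (six particle-count bins, three mass bins) are
#' non-missing. By default *any* missing channel disqualifies the record
#' (conservative); set `rule = "all"` to require all nine to be missing.
#' Duplicate (participant, timestamp) pairs keep the first occurrence and
#' are counted in the diagnostic attribute `n_duplicates` without entering
#' the drop ledger.
#'
#' @param stream a minute-record tibble in the wearable-stream schema.
#' @param rule `"any"` (default) or `"all"`: how many of the nine channels
#'   must be missing before a record is dropped.
#' @return the filtered stream; attributes `stage_log` (a stage-accounting
#'   tibble) and `n_duplicates`.
#' @export
drop_invalid_records <- function(stream, rule = c("any", "all")) {
  rule <- match.arg(rule)
  raw_total <- attr(stream, "raw_total") %||% nrow(stream)
  log <- attr(stream, "stage_log") %||% new_stage_log(raw_total)

  pc <- pollution_cols()
  stopifnot(all(pc %in% names(stream)))
  miss_mat <- is.na(as.matrix(stream[pc]))
  pollution_missing <- if (rule == "any") rowSums(miss_mat) > 0
                       else rowSums(miss_mat) == length(pc)
  bad <- is.na(stream$participant_id) | stream$participant_id == "" |
    is.na(stream$timestamp_utc) | pollution_missing
  kept <- stream[!bad, , drop = FALSE]

  dup <- duplicated(kept[c("participant_id", "timestamp_utc")])
  n_dup <- sum(dup)
  kept <- kept[!dup, , drop = FALSE]

  log <- add_stage(log, "invalid_records", sum(bad), nrow(kept))
  structure(kept, stage_log = log, raw_total = raw_total,
            n_duplicates = n_dup)
}

#' Drop participants with near-total all-zero particle records
#'
#' A participant is removed iff the fraction of their records in which all
#' nine particle channels are simultaneously zero is strictly greater than
#' `threshold` (default 0.99, i.e. "over 99% of the monitoring time").
#' Exactly 99% is retained. Participants with zero records are removed and
#' flagged separately.
#'
#' @param stream output of [drop_invalid_records()].
#' @param threshold strict lower bound on the all-zero fraction.
#' @return the filtered stream; attributes `stage_log`,
#'   `dropped_participants` (ids), `empty_participants`.
#' @export
drop_zero_participants <- function(stream, threshold = 0.99) {
  raw_total <- attr(stream, "raw_total") %||% nrow(stream)
  log <- attr(stream, "stage_log") %||% new_stage_log(raw_total)

  pc <- pollution_cols()
  all_zero <- rowSums(as.matrix(stream[pc]) != 0, na.rm = TRUE) == 0
  frac <- tapply(all_zero, stream$participant_id, mean)
  dropped_ids <- names(frac)[frac > threshold]
  kept <- stream[!stream$participant_id %in% dropped_ids, , drop = FALSE]

  log <- add_stage(log, "zero_participants",
                   nrow(stream) - nrow(kept), nrow(kept))
  structure(kept, stage_log = log, raw_total = raw_total,
            dropped_participants = dropped_ids,
            empty_participants = character(0))
}

#' Run both preprocessing filters
#'
#' @param stream a raw minute-record tibble.
#' @inheritParams drop_invalid_records
#' @inheritParams drop_zero_participants
#' @return the filtered stream with the accumulated `stage_log` attribute.
#' @export
preprocess_stream <- function(stream, rule = "any", threshold = 0.99) {
  stream |>
    drop_invalid_records(rule = rule) |>
    drop_zero_participants(threshold = threshold)
}

#' Extract the stage-accounting ledger of a filtered stream
#'
#' @param stream a stream that has passed through the preprocessing filters.
#' @return a tibble with columns `stage`, `dropped`, `remaining`,
#'   `pct_of_raw` (percent of the raw total, 1 decimal), `raw_total`.
#' @export
stage_log <- function(stream) {
  log <- attr(stream, "stage_log")
  if (is.null(log)) stop("no stage log attached; run the filters first",
                         call. = FALSE)
  tibble::as_tibble(log)
}
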