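#' Convert calendar timestamps to study time in fractional days
#'
#' Study time is measured in days elapsed since midnight (UTC) of the epoch
#' date, so that hours map to fractions of a day. The transform is affine and
#' strictly order-preserving; times before the epoch come out negative (a
#' warning is raised so staggered monitoring windows are not silently mixed
#' with a too-late epoch).
#'
#' @param timestamps `POSIXct`, `Date`, or character timestamps. Character
#'   input is parsed as ISO 8601 (`"2013-10-15 14:00:00"`) or the compact
#'   `"M/D/YY H:MM"` dialect common in deposited telemetry tables; the dialect
#'   is auto-detected per element.
#' @param epoch The calendar date mapped to study time 0 (`Date` or a string
#'   accepted by [as.Date()] / the `M/D/YY` dialect).
#' @return Numeric vector of study times in fractional days.
#' @examples
#' to_study_days("2013-10-15 00:00", epoch = "2013-10-09")  # 6
#' to_study_days("5/29/15 0:00", epoch = "10/15/13")        # 591
#' @export
to_study_days <- function(timestamps, epoch) {
  ts <- parse_timestamps(timestamps)
  ep <- parse_epoch(epoch)
  out <- as.numeric(difftime(ts, ep, units = "days"))
  if (any(out < 0, na.rm = TRUE)) {
    warn("Some timestamps precede the epoch; study times are negative.")
  }
  out
}

# Parse a vector of timestamps, accepting ISO 8601 or "M/D/YY H:MM".
# Unparseable entries raise an error naming the first offending row.
parse_timestamps <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (inherits(x, "Date")) return(as.POSIXct(as.character(x), tz = "UTC"))
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  blank <- is.na(x) | !nzchar(trimws(x))
  slashy <- !blank & grepl("^\\s*\\d{1,2}/\\d{1,2}/\\d{2,4}", x)
  if (any(slashy)) {
    fmts <- c("%m/%d/%y %H:%M:%S", "%m/%d/%y %H:%M", "%m/%d/%y",
              "%m/%d/%Y %H:%M:%S", "%m/%d/%Y %H:%M", "%m/%d/%Y")
    parsed <- rep(as.POSIXct(NA), sum(slashy))
    sub <- x[slashy]
    for (f in fmts) {
      todo <- is.na(parsed)
      if (!any(todo)) break
      parsed[todo] <- as.POSIXct(sub[todo], format = f, tz = "UTC")
    }
    out[slashy] <- parsed
  }
  iso <- !blank & !slashy
  if (any(iso)) {
    fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
              "%Y-%m-%d %H:%M", "%Y-%m-%d")
    parsed <- rep(as.POSIXct(NA), sum(iso))
    sub <- x[iso]
    for (f in fmts) {
      todo <- is.na(parsed)
      if (!any(todo)) break
      parsed[todo] <- as.POSIXct(sub[todo], format = f, tz = "UTC")
    }
    out[iso] <- parsed
  }
  bad <- which(is.na(out) & !blank)
  if (length(bad)) {
    abort(sprintf("Unparseable timestamp at position %d: \"%s\"", bad[1], x[bad[1]]),
          class = "trackfda_parse_error")
  }
  out
}

parse_epoch <- function(epoch) {
  if (inherits(epoch, "POSIXct")) return(epoch)
  if (inherits(epoch, "Date")) {
    return(as.POSIXct(paste(format(epoch), "00:00:00"), tz = "UTC"))
  }
  ts <- parse_timestamps(as.character(epoch))
  as.POSIXct(trunc(ts, units = "days"), tz = "UTC")
}

#' Read telemetry CSV files into a tidy track table
#'
#' Reads one or more Movebank/Dryad-style CSV files and returns a tibble of
#' telemetry records normalized to the study day-scale, one row per retained
#' fix, with columns `animal_id`, `time` (fractional days since the epoch),
#' `lon`, `lat`. Rows with missing or unparseable coordinates, coordinates
#' outside the valid WGS84 range, or missing identifiers are dropped and
#' counted in the attached load report. Duplicate timestamps within an
#' individual are resolved per `duplicates` (default: average the positions).
#'
#' @param path Character vector of CSV file paths.
#' @param columns Named list mapping the roles `timestamp`, `lon`, `lat`,
#'   `id` to column names in the file; defaults are the Movebank names.
#' @param epoch Calendar date mapped to study time 0, or `NULL` (default) to
#'   use the earliest timestamp across the loaded files.
#' @param duplicates `"average"` (default) or `"first"`: how to resolve
#'   repeated timestamps within one individual.
#' @return A tibble (`animal_id`, `time`, `lon`, `lat`), ordered by animal and
#'   time, with attributes `epoch` (POSIXct) and `load_report` (see
#'   [load_report()]).
#' @seealso [summarize_monitoring()], [write_telemetry()]
#' @export
read_telemetry <- function(path,
                           columns = list(timestamp = "timestamp",
                                          lon = "location-long",
                                          lat = "location-lat",
                                          id = "individual-local-identifier"),
                           epoch = NULL,
                           duplicates = c("average", "first")) {
  duplicates <- match.arg(duplicates)
  defaults <- list(timestamp = "timestamp", lon = "location-long",
                   lat = "location-lat", id = "individual-local-identifier")
  columns <- utils::modifyList(defaults, as.list(columns))
  missing_files <- path[!file.exists(path)]
  if (length(missing_files)) {
    stop_input(sprintf("Telemetry file not found: %s", missing_files[1]))
  }
  raw <- purrr::map(path, function(p) {
    df <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    need <- unlist(columns[c("timestamp", "lon", "lat", "id")])
    absent <- setdiff(need, names(df))
    if (length(absent)) {
      stop_config(sprintf("File %s lacks required column(s): %s",
                          p, paste(absent, collapse = ", ")))
    }
    tibble(file = p,
           timestamp_raw = df[[columns$timestamp]],
           lon = suppressWarnings(as.numeric(df[[columns$lon]])),
           lat = suppressWarnings(as.numeric(df[[columns$lat]])),
           animal_id = as.character(df[[columns$id]]))
  })
  raw <- bind_rows(raw)
  n_input <- nrow(raw)
  if (n_input == 0) stop_input("No rows found in telemetry input.")

  ts <- suppressWarnings(tryCatch(parse_timestamps(raw$timestamp_raw),
                                  trackfda_parse_error = function(e) NULL))
  if (is.null(ts)) {
    # Per-row fallback: keep parseable rows, count the rest as rejected.
    ts <- as.POSIXct(rep(NA_real_, n_input), tz = "UTC")
    for (i in seq_len(n_input)) {
      ts[i] <- tryCatch(parse_timestamps(raw$timestamp_raw[i]),
                        trackfda_parse_error = function(e) as.POSIXct(NA))
    }
  }
  raw$ts <- ts
  ok <- !is.na(raw$ts) & !is.na(raw$lon) & !is.na(raw$lat) &
    !is.na(raw$animal_id) & nzchar(raw$animal_id) &
    raw$lat >= -90 & raw$lat <= 90 & raw$lon >= -180 & raw$lon <= 180
  kept <- raw[ok, , drop = FALSE]
  if (nrow(kept) == 0) stop_input("No valid telemetry rows after filtering.")

  if (is.null(epoch)) {
    ep <- as.POSIXct(trunc(min(kept$ts), units = "days"), tz = "UTC")
  } else {
    ep <- parse_epoch(epoch)
  }
  kept$time <- as.numeric(difftime(kept$ts, ep, units = "days"))

  n_before_dedup <- nrow(kept)
  out <- kept |>
    group_by(.data$animal_id, .data$time) |>
    summarise(lon = if (duplicates == "average") mean(.data$lon) else .data$lon[1],
              lat = if (duplicates == "average") mean(.data$lat) else .data$lat[1],
              .groups = "drop") |>
    arrange(.data$animal_id, .data$time) |>
    select("animal_id", "time", "lon", "lat")

  report <- raw |>
    mutate(kept = ok) |>
    group_by(.data$animal_id) |>
    summarise(n_input = n(), n_kept = sum(.data$kept),
              n_rejected = sum(!.data$kept), .groups = "drop")
  dups <- n_before_dedup - nrow(out)

  attr(out, "epoch") <- ep
  attr(out, "load_report") <- structure(report, n_input = n_input,
                                        n_duplicates_merged = dups,
                                        duplicates = duplicates)
  out
}

#' Retrieve the load report attached by [read_telemetry()]
#'
#' @param tracks A track table from [read_telemetry()].
#' @return A tibble with per-animal `n_input`, `n_kept`, `n_rejected` counts,
#'   plus attributes `n_input` (total rows) and `n_duplicates_merged`.
#' @export
load_report <- function(tracks) attr(tracks, "load_report")

#' Summarize monitoring coverage per animal
#'
#' One row per individual with fix count, first/last study times and the
#' monitoring span, mirroring the usual "monitoring statistics" table of a
#' tracking study.
#'
#' @param tracks A track table (`animal_id`, `time`, `lon`, `lat`).
#' @return Tibble with `animal_id`, `n_fixes`, `first_time`, `last_time`,
#'   `span_days`.
#' @export
summarize_monitoring <- function(tracks) {
  check_tracks(tracks)
  tracks |>
    group_by(.data$animal_id) |>
    summarise(n_fixes = n(),
              first_time = min(.data$time),
              last_time = max(.data$time),
              .groups = "drop") |>
    mutate(span_days = .data$last_time - .data$first_time)
}

#' Write a track table back to the telemetry CSV dialect
#'
#' Inverse of [read_telemetry()]: writes ISO 8601 timestamps reconstructed
#' from study time and the epoch, with Movebank default column names, so a
#' round trip reproduces times and coordinates.
#'
#' @param tracks Track table with `animal_id`, `time`, `lon`, `lat`.
#' @param path Output CSV path.
#' @param epoch Epoch used to reconstruct calendar timestamps; defaults to the
#'   `epoch` attribute of `tracks`.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(tracks, path, epoch = attr(tracks, "epoch")) {
  check_tracks(tracks)
  if (is.null(epoch)) stop_config("No epoch available to reconstruct timestamps.")
  ep <- parse_epoch(epoch)
  # microsecond-rounded timestamps (format() truncates, hence the half-unit
  # nudge); full-precision coordinates
  secs <- round(tracks$time * 86400, 6)
  out <- tibble(
    timestamp = format(ep + secs + 5e-7, "%Y-%m-%d %H:%M:%OS6", tz = "UTC"),
    `location-long` = sprintf("%.15g", tracks$lon),
    `location-lat` = sprintf("%.15g", tracks$lat),
    `individual-local-identifier` = tracks$animal_id
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Validate the minimal track-table contract shared by downstream functions.
check_tracks <- function(tracks, one_animal = FALSE) {
  if (!is.data.frame(tracks) ||
      !all(c("animal_id", "time", "lon", "lat") %in% names(tracks))) {
    stop_input("Expected a track table with columns animal_id, time, lon, lat.")
  }
  if (nrow(tracks) == 0) stop_input("Track table is empty.")
  if (one_animal && length(unique(tracks$animal_id)) > 1) {
    stop_input("Expected a single animal; filter the track table first.")
  }
  invisible(tracks)
}

# Extract one animal's ordered records (tibble) from a track table.
one_track <- function(tracks, animal = NULL) {
  check_tracks(tracks)
  if (!is.null(animal)) {
    tracks <- filter(tracks, .data$animal_id == animal)
    if (nrow(tracks) == 0) stop_input(sprintf("No records for animal '%s'.", animal))
  }
  check_tracks(tracks, one_animal = TRUE)
  arrange(tracks, .data$time)
}
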