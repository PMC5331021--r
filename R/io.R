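#' Read a minute-epoch activity recording
#'
#' Reads a CSV of minute-resolution activity counts (columns `subject_id`,
#' `timestamp`, `activity_count`, emulating 1-min epoch actigraph exports) and
#' validates it: per subject, timestamps must form consecutive minutes with no
#' gaps or duplicates, and counts must be non-negative integers.
#'
#' @param path Path to a CSV file with a header row, ISO-8601 timestamps at
#'   minute resolution, and integer counts.
#' @return A tibble with columns `subject_id` (character), `timestamp`
#'   (POSIXct, UTC), `activity_count` (integer), sorted by subject and time.
#' @export
read_activity_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "timestamp", "activity_count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("activity file is missing column(s): ", paste(miss, collapse = ", ")))
  }
  df <- tibble::tibble(
    subject_id = as.character(df$subject_id),
    timestamp = as.POSIXct(df$timestamp, tz = "UTC"),
    activity_count = df$activity_count
  )
  validate_activity(df)
}

#' Write a minute-epoch activity recording
#'
#' @param activity A validated activity tibble (see [read_activity_csv()]).
#' @param path Output CSV path.
#' @return `path`, invisibly. Timestamps are written as ISO-8601 at minute
#'   resolution so a write/read round trip is the identity.
#' @export
write_activity_csv <- function(activity, path) {
  activity <- validate_activity(activity)
  out <- dplyr::mutate(
    activity,
    timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:00", tz = "UTC")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate an activity tibble
#'
#' Checks the per-subject minute grid: sorted, consecutive, no duplicates or
#' gaps; counts finite, integer-valued and non-negative.
#'
#' @param activity Tibble with columns `subject_id`, `timestamp`,
#'   `activity_count`.
#' @return The validated tibble, sorted by subject and time, with
#'   `activity_count` as integer.
#' @export
validate_activity <- function(activity) {
  need <- c("subject_id", "timestamp", "activity_count")
  miss <- setdiff(need, names(activity))
  if (length(miss) > 0) {
    abort(paste0("activity table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(activity) == 0) abort("activity table is empty.")
  if (anyNA(activity$timestamp)) abort("unparseable or missing timestamps present.")
  x <- activity$activity_count
  if (anyNA(x) || any(!is.finite(x))) abort("activity counts must be finite and non-missing.")
  if (any(x < 0)) {
    bad <- activity[which(x < 0)[1], ]
    abort(paste0("negative activity count for subject ", bad$subject_id,
                 " at ", format(bad$timestamp, tz = "UTC"), "."))
  }
  if (any(x != round(x))) abort("activity counts must be integers.")

  activity <- activity |>
    dplyr::mutate(
      subject_id = as.character(.data$subject_id),
      timestamp = as.POSIXct(floor(as.numeric(.data$timestamp) / 60) * 60,
                             tz = "UTC"),
      activity_count = as.integer(round(.data$activity_count))
    ) |>
    dplyr::arrange(.data$subject_id, .data$timestamp)

  for (sid in unique(activity$subject_id)) {
    ts <- activity$timestamp[activity$subject_id == sid]
    dt <- diff(as.numeric(ts))
    if (any(dt == 0)) {
      abort(paste0("duplicate timestamp for subject ", sid, " at ",
                   format(ts[which(dt == 0)[1] + 1], tz = "UTC"), "."))
    }
    if (any(dt != 60)) {
      abort(paste0("gap in recording for subject ", sid, " after ",
                   format(ts[which(dt != 60)[1]], tz = "UTC"),
                   " (expected consecutive minutes)."))
    }
  }
  activity
}

#' Day-window definitions
#'
#' The analysis day runs 06:00 to midnight and is split into a morning window
#' (06:00 to 15:00) and an evening window (15:00 to 24:00). Windows are
#' half-open `[start, end)`, so the minute at 15:00 belongs to the evening
#' only.
#'
#' @return A tibble with columns `window`, `start_hour`, `end_hour`.
#' @export
day_windows <- function() {
  tibble::tibble(
    window = c("morning", "evening"),
    start_hour = c(6, 15),
    end_hour = c(15, 24)
  )
}

#' Slice one day-window out of each subject's recording
#'
#' Restricts each recording to the minutes whose clock time falls inside the
#' requested window. A ~22-h recording that starts mid-day can cover the same
#' clock window on two calendar days; `day_rule` resolves which instance is
#' used:
#' \describe{
#'   \item{`prefer_maximal_coverage`}{the calendar day with more recorded
#'     minutes in the window; ties break to the earlier day (default). This
#'     maximises the chance that the 64-min active-period search succeeds.}
#'   \item{`first`}{the earliest day with any coverage.}
#'   \item{`second`}{the second day with any coverage (empty if only one).}
#' }
#'
#' @param activity A validated activity tibble.
#' @param window `"morning"` or `"evening"`.
#' @param day_rule Day-selection rule, see Details.
#' @return A tibble of the selected rows with a `window` label column; a
#'   subject with no coverage contributes zero rows (not an error).
#' @export
slice_window <- function(activity,
                         window = c("morning", "evening"),
                         day_rule = c("prefer_maximal_coverage", "first", "second")) {
  window <- match.arg(window)
  day_rule <- match.arg(day_rule)
  activity <- validate_activity(activity)
  win <- day_windows()
  w <- win[win$window == window, ]

  tod <- function(ts) {
    lt <- as.POSIXlt(ts, tz = "UTC")
    lt$hour + lt$min / 60
  }

  picked <- activity |>
    dplyr::mutate(
      .date = as.Date(.data$timestamp, tz = "UTC"),
      .in_win = tod(.data$timestamp) >= w$start_hour &
        tod(.data$timestamp) < w$end_hour
    ) |>
    dplyr::filter(.data$.in_win)
  if (nrow(picked) == 0) {
    return(empty_window_slice())
  }

  cov <- picked |>
    dplyr::count(.data$subject_id, .data$.date, name = "minutes") |>
    dplyr::arrange(.data$subject_id, .data$.date)

  chosen <- cov |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      idx <- switch(day_rule,
        prefer_maximal_coverage = which.max(d$minutes),  # ties -> earlier day
        first = 1L,
        second = if (nrow(d) >= 2) 2L else NA_integer_
      )
      if (is.na(idx)) d[0, ] else d[idx, , drop = FALSE]
    }) |>
    dplyr::ungroup()

  picked |>
    dplyr::inner_join(chosen[c("subject_id", ".date")],
                      by = c("subject_id", ".date")) |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      window = window,
      timestamp = .data$timestamp,
      activity_count = .data$activity_count
    )
}

empty_window_slice <- function() {
  tibble::tibble(
    subject_id = character(0),
    window = character(0),
    timestamp = as.POSIXct(character(0), tz = "UTC"),
    activity_count = integer(0)
  )
}
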