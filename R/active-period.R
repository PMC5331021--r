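#' Longest run of consecutive zero counts
#'
#' @param x Numeric vector of activity counts.
#' @return Integer: the length of the longest run of consecutive exact zeros
#'   (0 when the sequence contains no zero).
#' @export
max_zero_run <- function(x) {
  if (length(x) == 0) abort("max_zero_run() requires a non-empty sequence.")
  r <- rle(x == 0)
  z <- r$lengths[r$values]
  if (length(z) == 0) 0L else as.integer(max(z))
}

#' Find the 64-minute continuous active period in a window
#'
#' Searches a windowed minute series for a contiguous segment of `seg_len`
#' minutes of sustained activity, using a zero-run relaxation rule: at
#' tolerance k = 2 the segment may contain at most two consecutive zero-count
#' minutes; if no such segment exists anywhere in the window the tolerance is
#' relaxed to 3, then 4, and so on. All start positions are tried at a given
#' tolerance before the tolerance is raised, so the returned `tolerance_used`
#' is the smallest at which any qualifying segment exists.
#'
#' The morning period is searched from the start of the series
#' (`direction = "forward"`: the earliest qualifying start wins) and the
#' evening period from the end (`direction = "backward"`: the latest
#' qualifying start wins). The search slides in 1-minute steps. A tolerance of
#' `seg_len` always qualifies, so the search terminates.
#'
#' @param x Numeric vector of activity counts for one day-window
#'   (length >= `seg_len`).
#' @param direction `"forward"` (morning convention) or `"backward"`
#'   (evening convention).
#' @param seg_len Segment length in minutes; a power of two (default 64) so
#'   the Fourier analysis applies directly.
#' @param start_tolerance Smallest permitted consecutive-zero run to try
#'   (default 2).
#' @return A list with `start` (1-based index into `x`), `counts` (the
#'   `seg_len` counts, a verbatim slice of the input) and `tolerance_used`.
#' @export
find_active_segment <- function(x, direction = c("forward", "backward"),
                                seg_len = 64L, start_tolerance = 2L) {
  direction <- match.arg(direction)
  check_counts(x, min_len = 1)
  n <- length(x)
  if (n < seg_len) {
    abort(paste0("window of ", n, " min is shorter than the ", seg_len,
                 "-min segment length."), class = "actiphase_insufficient_data")
  }
  starts <- seq_len(n - seg_len + 1L)
  if (direction == "backward") starts <- rev(starts)
  for (k in seq.int(start_tolerance, seg_len)) {
    ok <- qualifying_starts(x, seg_len, k)
    hit <- starts[ok[starts]]
    if (length(hit) > 0) {
      s <- hit[1]
      return(list(
        start = s,
        counts = x[s:(s + seg_len - 1L)],
        tolerance_used = as.integer(k)
      ))
    }
  }
  abort("internal error: active-period search failed to terminate.") # unreachable
}

# For each window start s, does x[s..s+seg_len-1] avoid any zero run longer
# than k? A window fails iff some run of k+1 consecutive zeros lies wholly
# inside it. Rolling sums keep this O(n).
qualifying_starts <- function(x, seg_len, k) {
  n <- length(x)
  ns <- n - seg_len + 1L
  z <- as.numeric(x == 0)
  if (k >= seg_len) return(rep(TRUE, ns))
  w <- k + 1L
  # run_start[t] == TRUE when z[t..t+k] are all zero-count minutes
  cz <- c(0, cumsum(z))
  run_start <- (cz[(w + 1):(n + 1)] - cz[1:(n - w + 1)]) == w
  # window s contains run start t iff s <= t <= s + seg_len - w
  span <- seg_len - w + 1L
  cr <- c(0, cumsum(as.numeric(run_start)))
  bad <- (cr[pmin(seq_len(ns) + span, length(cr))] - cr[seq_len(ns)]) > 0
  !bad
}

#' Extract active morning and evening segments for a cohort
#'
#' For every subject, slices the morning and evening day-windows
#' (see [slice_window()]) and runs the zero-run relaxation search
#' ([find_active_segment()]): morning forward from the start of the window,
#' evening backward from its end. Exactly one morning and one evening segment
#' per subject is attempted; subjects whose window is missing or shorter than
#' `seg_len` minutes are reported in the `"failures"` attribute rather than
#' silently dropped.
#'
#' @param activity A validated activity tibble (`subject_id`, `timestamp`,
#'   `activity_count`).
#' @param day_rule Day-selection rule passed to [slice_window()].
#' @param seg_len,start_tolerance Passed to [find_active_segment()].
#' @return A tibble with one row per found segment: `subject_id`, `window`,
#'   `start_time`, `tolerance_used`, and `counts` (a list-column of integer
#'   vectors of length `seg_len`). The attribute `"failures"` is a tibble
#'   (`subject_id`, `window`, `reason`) of unextractable segments.
#' @export
extract_segments <- function(activity, day_rule = "prefer_maximal_coverage",
                             seg_len = 64L, start_tolerance = 2L) {
  activity <- validate_activity(activity)
  subjects <- unique(activity$subject_id)
  rows <- list()
  fails <- list()
  for (wname in day_windows()$window) {
    sliced <- slice_window(activity, wname, day_rule = day_rule)
    direction <- if (wname == "morning") "forward" else "backward"
    for (sid in subjects) {
      sub <- sliced[sliced$subject_id == sid, ]
      res <- tryCatch(
        find_active_segment(sub$activity_count, direction,
                            seg_len = seg_len, start_tolerance = start_tolerance),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        fails[[length(fails) + 1]] <- tibble::tibble(
          subject_id = sid, window = wname, reason = conditionMessage(res)
        )
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = sid,
          window = wname,
          start_time = sub$timestamp[res$start],
          tolerance_used = res$tolerance_used,
          counts = list(res$counts)
        )
      }
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble(
    subject_id = character(0), window = character(0),
    start_time = as.POSIXct(character(0), tz = "UTC"),
    tolerance_used = integer(0), counts = list()
  )
  out <- dplyr::arrange(out, .data$subject_id, .data$window)
  failures <- if (length(fails) > 0) dplyr::bind_rows(fails) else
    tibble::tibble(subject_id = character(0), window = character(0),
                   reason = character(0))
  if (nrow(failures) > 0) {
    warn(paste0(nrow(failures), " segment(s) could not be extracted; ",
                'see attr(x, "failures").'))
  }
  attr(out, "failures") <- failures
  out
}

#' Write extracted segments as a flat CSV
#'
#' @param segments Output of [extract_segments()].
#' @param path Output CSV path; columns `subject_id`, `window`, `start_time`,
#'   `tolerance_used`, then `c0`...`c63` (the counts).
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(segments, path) {
  seg_len <- if (nrow(segments) > 0) length(segments$counts[[1]]) else 64L
  mat <- do.call(rbind, lapply(segments$counts, as.integer))
  if (is.null(mat)) mat <- matrix(integer(0), 0, seg_len)
  colnames(mat) <- paste0("c", seq_len(seg_len) - 1L)
  flat <- dplyr::bind_cols(
    dplyr::mutate(
      segments[c("subject_id", "window", "start_time", "tolerance_used")],
      start_time = format(.data$start_time, "%Y-%m-%dT%H:%M:00", tz = "UTC")
    ),
    tibble::as_tibble(mat)
  )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read segments written by [write_segments_csv()]
#'
#' @param path CSV path.
#' @return A segments tibble with a `counts` list-column, as from
#'   [extract_segments()].
#' @export
read_segments_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  flat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ccols <- grep("^c[0-9]+$", names(flat), value = TRUE)
  ccols <- ccols[order(as.integer(sub("^c", "", ccols)))]
  tibble::tibble(
    subject_id = as.character(flat$subject_id),
    window = flat$window,
    start_time = as.POSIXct(flat$start_time, tz = "UTC"),
    tolerance_used = as.integer(flat$tolerance_used),
    counts = lapply(seq_len(nrow(flat)),
                    function(i) as.integer(unlist(flat[i, ccols], use.names = FALSE)))
  )
}
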