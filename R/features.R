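#' Activity parameters for a 64-minute active segment
#'
#' Six summary parameters describe the level, variability, regularity and
#' spectral balance of an active period: mean counts per minute, standard
#' deviation and RMSSD as a percentage of the mean, lag-1 autocorrelation,
#' sample entropy (m = 2, r = 0.2), and the ratio of spectral variance in the
#' 2--8 min period band to that in the 8--64 min band.
#'
#' All relative measures use the sample standard deviation (n - 1 denominator),
#' and normalisation before sample entropy and Fourier analysis transforms the
#' series to sample mean 0, sample variance 1. `sd_pct`, `rmssd_pct`,
#' `sample_entropy` and `fourier_ratio` are therefore invariant under positive
#' rescaling of the counts, while `mean_cpm` scales linearly.
#'
#' @param x Numeric vector of non-negative activity counts (one per minute).
#' @return A single numeric value.
#' @name activity-parameters
#' @examples
#' x <- round(100 * exp(stats::rnorm(64, sd = 0.5)))
#' mean_cpm(x)
#' sd_pct(x)
#' rmssd_pct(x)
#' autocorr_lag1(x)
#' sample_entropy(x)
#' fourier_ratio(x)
NULL

#' @rdname activity-parameters
#' @export
mean_cpm <- function(x) {
  check_counts(x, min_len = 1)
  mean(x)
}

#' @rdname activity-parameters
#' @export
sd_pct <- function(x) {
  check_counts(x, min_len = 2)
  m <- mean(x)
  if (m == 0) abort("sd_pct is undefined for a segment with mean 0.")
  100 * sd(x) / m
}

#' @rdname activity-parameters
#' @export
rmssd_pct <- function(x) {
  check_counts(x, min_len = 2)
  m <- mean(x)
  if (m == 0) abort("rmssd_pct is undefined for a segment with mean 0.")
  d <- diff(x)
  100 * sqrt(mean(d^2)) / m
}

#' @rdname activity-parameters
#' @param method Estimator convention: `"correlogram"` (default; lag-1
#'   autocovariance about the overall mean divided by the variance, as in
#'   [stats::acf()]) or `"pearson"` (Pearson correlation of the n - 1 lagged
#'   pairs).
#' @export
autocorr_lag1 <- function(x, method = c("correlogram", "pearson")) {
  check_counts(x, min_len = 3)
  method <- match.arg(method)
  if (var(x) == 0) abort("autocorr_lag1 is undefined for a constant segment.")
  n <- length(x)
  if (method == "correlogram") {
    xc <- x - mean(x)
    sum(xc[-n] * xc[-1]) / sum(xc^2)
  } else {
    stats::cor(x[-n], x[-1])
  }
}

#' @rdname activity-parameters
#' @param m Template length for sample entropy (default 2).
#' @param r Match tolerance as a fraction of the (unit) standard deviation of
#'   the normalised series (default 0.2).
#' @return `sample_entropy()` returns `NA` (an undefined-entropy flag) when no
#'   template pairs match at length `m` or at length `m + 1`, since
#'   \eqn{-\ln(A/B)} is then undefined; no ceiling value is substituted.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2) {
  check_counts(x, min_len = m + 2)
  if (var(x) == 0) abort("sample_entropy is undefined for a constant segment.")
  z <- (x - mean(x)) / sd(x)
  n <- length(z)
  nt <- n - m   # templates of length m and m+1 both start at 1..n-m
  # Chebyshev distances between templates, built coordinate-by-coordinate
  dm <- abs(outer(z[1:nt], z[1:nt], "-"))
  for (k in 1:(m - 1)) {
    dk <- abs(outer(z[(1 + k):(nt + k)], z[(1 + k):(nt + k)], "-"))
    dm <- pmax(dm, dk)
  }
  dm1 <- pmax(dm, abs(outer(z[(1 + m):(nt + m)], z[(1 + m):(nt + m)], "-")))
  ut <- upper.tri(dm)                     # distinct pairs, self-matches excluded
  B <- sum(dm[ut] <= r)
  A <- sum(dm1[ut] <= r)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

#' Spectral band variances of a normalised segment
#'
#' Computes the periodogram of the segment after normalisation to sample mean 0
#' and sample variance 1, and attributes the variance of bins k = 1..n/2
#' (periods n/k minutes) to a low-frequency band (periods 8--64 min, bins
#' k = 1..8 for n = 64) and a high-frequency band (periods 2 to < 8 min, bins
#' k = 9..32, Nyquist included). The bin at the 8-min period sits on both
#' printed band edges and is assigned to the low-frequency band so the bands
#' partition the spectrum exactly; the DC bin is zero after mean removal.
#'
#' @param x Numeric vector of counts; length must be even (64 in the standard
#'   analysis, 1 sample per minute).
#' @return A tibble with one row per bin: `k`, `period_min`, `variance`, and
#'   `band` (`"low"` or `"high"`).
#' @seealso [fourier_ratio()]
#' @export
fourier_bands <- function(x) {
  check_counts(x, min_len = 4)
  n <- length(x)
  if (n %% 2 != 0) abort("fourier_bands() requires an even-length segment.")
  if (var(x) == 0) abort("spectral variance is undefined for a constant segment.")
  z <- (x - mean(x)) / sd(x)
  px <- Mod(fft(z))^2 / n^2
  k <- seq_len(n / 2)
  v <- 2 * px[k + 1]
  v[n / 2] <- px[n / 2 + 1]               # Nyquist bin is not doubled
  period <- n / k
  tibble::tibble(
    k = k,
    period_min = period,
    variance = v,
    band = ifelse(period >= 8, "low", "high")
  )
}

#' @rdname activity-parameters
#' @return `fourier_ratio()` returns `NA` (flagged undefined) when the
#'   low-frequency band carries zero variance, as the ratio is then infinite.
#' @export
fourier_ratio <- function(x) {
  b <- fourier_bands(x)
  lf <- sum(b$variance[b$band == "low"])
  hf <- sum(b$variance[b$band == "high"])
  # a band carrying only floating-point dust counts as empty
  if (lf <= 1e-12 * (lf + hf)) return(NA_real_)
  hf / lf
}

#' Compute all six activity parameters for one segment
#'
#' @param x Numeric vector of 64 activity counts.
#' @return A one-row tibble with columns `mean_cpm`, `sd_pct`, `rmssd_pct`,
#'   `autocorr_lag1`, `sampen`, `fourier_ratio`. Undefined non-linear measures
#'   are returned as `NA` rather than errors so callers can report exclusions.
#' @export
segment_features <- function(x) {
  check_counts(x, min_len = 4)
  degenerate <- mean(x) == 0 || var(x) == 0
  if (degenerate) {
    return(tibble::tibble(
      mean_cpm = mean(x), sd_pct = NA_real_, rmssd_pct = NA_real_,
      autocorr_lag1 = NA_real_, sampen = NA_real_, fourier_ratio = NA_real_
    ))
  }
  tibble::tibble(
    mean_cpm = mean_cpm(x),
    sd_pct = sd_pct(x),
    rmssd_pct = rmssd_pct(x),
    autocorr_lag1 = autocorr_lag1(x),
    sampen = sample_entropy(x),
    fourier_ratio = fourier_ratio(x)
  )
}

#' Build the subjects-by-predictors feature table
#'
#' Joins per-segment activity parameters (morning and evening) with the subject
#' table into one row per subject: 12 predictors (6 parameters x 2 day
#' periods) plus phase, age and gender. Subjects missing a segment, or with
#' any undefined parameter, are excluded and listed in the exclusion report
#' attached as the `"exclusions"` attribute (see [exclusion_report()]).
#'
#' @param segments Tibble of active segments as returned by
#'   [extract_segments()]: columns `subject_id`, `window`, `counts`
#'   (list-column of 64-count vectors).
#' @param subjects Subject table: columns `subject_id`, `phase`, `age`,
#'   `gender`.
#' @return A tibble with columns `subject_id`, `phase`, `age`, `gender`, then
#'   the morning block and the evening block, each ordered `mean_cpm`,
#'   `sd_pct`, `rmssd_pct`, `autocorr_lag1`, `sampen`, `fourier_ratio` and
#'   prefixed `morning_` / `evening_`.
#' @export
build_feature_table <- function(segments, subjects) {
  need <- c("subject_id", "window", "counts")
  if (!all(need %in% names(segments))) {
    abort(paste0("`segments` must have columns: ", paste(need, collapse = ", ")))
  }
  need_s <- c("subject_id", "phase", "age", "gender")
  if (!all(need_s %in% names(subjects))) {
    abort(paste0("`subjects` must have columns: ", paste(need_s, collapse = ", ")))
  }

  feats <- segments |>
    dplyr::mutate(.f = purrr::map(.data$counts, segment_features)) |>
    dplyr::select("subject_id", "window", ".f") |>
    tidyr::unnest(".f")

  wide <- feats |>
    tidyr::pivot_wider(
      id_cols = "subject_id",
      names_from = "window",
      values_from = c("mean_cpm", "sd_pct", "rmssd_pct", "autocorr_lag1",
                      "sampen", "fourier_ratio"),
      names_glue = "{window}_{.value}"
    )

  feature_cols <- as.vector(outer(
    c("morning_", "evening_"),
    c("mean_cpm", "sd_pct", "rmssd_pct", "autocorr_lag1", "sampen", "fourier_ratio"),
    paste0
  ))
  missing_cols <- setdiff(feature_cols, names(wide))
  for (mc in missing_cols) wide[[mc]] <- NA_real_

  tab <- subjects |>
    dplyr::select(dplyr::all_of(need_s)) |>
    dplyr::left_join(wide, by = "subject_id") |>
    dplyr::select(dplyr::all_of(c(need_s, feature_cols)))

  ok <- complete.cases(tab[feature_cols])
  exclusions <- tab[!ok, "subject_id", drop = FALSE]
  if (nrow(exclusions) > 0) {
    exclusions$reason <- vapply(exclusions$subject_id, function(sid) {
      row <- tab[tab$subject_id == sid, feature_cols]
      bad <- feature_cols[vapply(row, function(v) any(is.na(v)), logical(1))]
      paste0("undefined or missing: ", paste(bad, collapse = ", "))
    }, character(1))
    warn(paste0(
      nrow(exclusions), " subject(s) excluded from the feature table; ",
      "see exclusion_report()."
    ))
  } else {
    exclusions$reason <- character(0)
  }

  out <- tab[ok, , drop = FALSE]
  attr(out, "exclusions") <- tibble::as_tibble(exclusions)
  out
}

#' Exclusion report of a feature table
#'
#' @param x A feature table from [build_feature_table()].
#' @return A tibble with columns `subject_id` and `reason`, one row per
#'   excluded subject (zero rows when nothing was excluded).
#' @export
exclusion_report <- function(x) {
  attr(x, "exclusions") %||% tibble::tibble(subject_id = character(0),
                                            reason = character(0))
}

check_counts <- function(x, min_len = 1) {
  if (!is.numeric(x) || length(x) < min_len) {
    abort(paste0("expected a numeric vector of at least ", min_len, " counts."))
  }
  if (anyNA(x) || any(!is.finite(x))) abort("counts must be finite and non-missing.")
  if (any(x < 0)) abort("counts must be non-negative.")
  invisible(x)
}
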