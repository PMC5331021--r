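#' Simulate one subject's minute-epoch activity recording
#'
#' Generates a ~22-h recording of non-negative integer activity counts at
#' 1-min epochs, mimicking an inpatient actigraph export that starts mid-day.
#' Within each day-window regime (morning 06:00--15:00, evening 15:00--24:00,
#' night 00:00--06:00) the counts follow
#' \deqn{x_t = \mathrm{round}(\mu \exp(b y_t - b^2/2)),}
#' where the latent unit-variance signal
#' \eqn{y_t} mixes a 32-min sinusoid (variance share `v_lf`), a 4-min sinusoid
#' (share `v_hf`) and a standardised AR(1) noise process with coefficient
#' `phi` (share `1 - v_lf - v_hf`); sinusoid phases are drawn per regime
#' block. The circadian envelope is the regime-specific amplitude `mu`, low
#' at night. Each knob maps to one extracted activity parameter (see
#' `phase_profiles()` and the package vignette).
#'
#' @param phase One of `"bipolar_depression"`, `"mania"`, `"mixed"`.
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   series bit-identically.
#' @param n_minutes Recording length in minutes (default 22 h).
#' @param start_time Start timestamp (POSIXct or ISO-8601 string); default
#'   12:41 local clock, the study's mean recording start.
#' @param params Process-knob table, one row per phase and window
#'   (`default_process_params()` by default). Supplying a modified table
#'   makes every knob independently tunable.
#' @param night Night regime: list with `mu` (mean counts/min), `b`, `phi`
#'   and `p_zero` (per-minute probability that the count is zeroed,
#'   emulating sleep immobility).
#' @param zero_run_injection Optional list with `n_runs`, `run_len` and
#'   `window` (`"morning"`/`"evening"`): after generation, `n_runs` runs of
#'   `run_len` consecutive zero minutes are placed at random positions inside
#'   that day-window, to exercise the active-period tolerance relaxation.
#' @param subject_id Subject identifier for the output tibble.
#' @return A tibble with columns `subject_id`, `timestamp` (POSIXct UTC,
#'   minute grid), `activity_count` (integer >= 0), of exactly `n_minutes`
#'   rows.
#' @export
simulate_subject <- function(phase, seed,
                             n_minutes = 22L * 60L,
                             start_time = "2024-03-01 12:41:00",
                             params = default_process_params(),
                             night = list(mu = 15, b = 0.8, phi = 0.5, p_zero = 0.45),
                             zero_run_injection = NULL,
                             subject_id = "S1") {
  phase <- match.arg(phase, PHASE_LEVELS)
  pp <- params[params$phase == phase, , drop = FALSE]
  if (nrow(pp) != 2) abort(paste0("no process parameters for phase ", phase, "."))
  check_profile_params(pp)
  start <- as.POSIXct(start_time, tz = "UTC")
  ts <- start + 60 * (seq_len(n_minutes) - 1L)

  with_seed_(seed, {
    hr <- as.POSIXlt(ts, tz = "UTC")$hour
    regime <- ifelse(hr >= 6 & hr < 15, "morning",
                     ifelse(hr >= 15, "evening", "night"))
    counts <- integer(n_minutes)
    blocks <- rle(regime)
    pos <- 1L
    for (bi in seq_along(blocks$lengths)) {
      len <- blocks$lengths[bi]
      reg <- blocks$values[bi]
      idx <- pos:(pos + len - 1L)
      if (reg == "night") {
        y <- latent_signal(len, phi = night$phi, v_lf = 0, v_hf = 0)
        x <- round(night$mu * exp(night$b * y - night$b^2 / 2))
        x[runif(len) < night$p_zero] <- 0
      } else {
        p <- pp[pp$window == reg, ]
        y <- latent_signal(len, phi = p$phi, v_lf = p$v_lf, v_hf = p$v_hf)
        x <- round(p$mu * exp(p$b * y - p$b^2 / 2))
      }
      counts[idx] <- as.integer(pmax(x, 0))
      pos <- pos + len
    }
    if (!is.null(zero_run_injection)) {
      counts <- inject_zero_runs(counts, regime, zero_run_injection)
    }
    tibble::tibble(subject_id = subject_id, timestamp = ts,
                   activity_count = counts)
  })
}

# Unit-variance latent mixture: LF sinusoid (32-min period) + HF sinusoid
# (4-min period) + standardised AR(1). Phases are random per call.
latent_signal <- function(n, phi, v_lf, v_hf) {
  v_n <- 1 - v_lf - v_hf
  if (v_n < 0) abort("v_lf + v_hf must not exceed 1.")
  t <- seq_len(n)
  y <- numeric(n)
  if (v_lf > 0) {
    y <- y + sqrt(2 * v_lf) * sin(2 * pi * t / 32 + runif(1, 0, 2 * pi))
  }
  if (v_hf > 0) {
    y <- y + sqrt(2 * v_hf) * sin(2 * pi * t / 4 + runif(1, 0, 2 * pi))
  }
  if (v_n > 0) {
    e <- numeric(n)
    e[1] <- rnorm(1)
    if (n > 1) {
      innov <- rnorm(n - 1, sd = sqrt(1 - phi^2))
      for (i in 2:n) e[i] <- phi * e[i - 1] + innov[i - 1]
    }
    y <- y + sqrt(v_n) * e
  }
  y
}

inject_zero_runs <- function(counts, regime, rule) {
  need <- c("n_runs", "run_len", "window")
  if (!all(need %in% names(rule))) {
    abort("zero_run_injection needs fields n_runs, run_len, window.")
  }
  idx <- which(regime == rule$window)
  if (length(idx) < rule$run_len) return(counts)
  starts <- sample(idx[idx <= max(idx) - rule$run_len + 1L],
                   size = min(rule$n_runs, length(idx)), replace = FALSE)
  for (s in starts) counts[s:(s + rule$run_len - 1L)] <- 0L
  counts
}

check_profile_params <- function(pp) {
  num <- c("mu", "b", "phi", "v_lf", "v_hf")
  for (cn in num) {
    if (!all(is.finite(pp[[cn]]))) abort(paste0("non-finite process parameter ", cn, "."))
  }
  if (any(pp$phi <= -1 | pp$phi >= 1)) abort("phi must lie strictly inside (-1, 1).")
  if (any(pp$mu < 0) || any(pp$b < 0)) abort("mu and b must be non-negative.")
  if (any(pp$v_lf < 0) || any(pp$v_hf < 0) || any(pp$v_lf + pp$v_hf > 1)) {
    abort("sinusoid variance shares must be non-negative and sum to at most 1.")
  }
  invisible(pp)
}

#' Simulate a synthetic inpatient cohort
#'
#' Generates `n_subjects` minute-level recordings plus a subject table
#' (phase, age, gender). Phase group sizes follow the cohort fractions by
#' largest-remainder rounding; ages are drawn per phase from normal
#' distributions matching the study demographics, truncated at 18 years;
#' gender is Bernoulli with the cohort female fraction. Each subject consumes
#' an independent seeded random stream derived from `seed`, so adding
#' subjects or knobs never perturbs other subjects.
#'
#' @param n_subjects Number of subjects (default 34, the study sample size).
#' @param seed Integer master seed.
#' @param fractions Named numeric vector of cohort fractions per phase
#'   (defaults to the study's 12/34, 16/34, 6/34). Must sum to 1.
#' @param demographics Demographics table, `phase_demographics()` by default.
#' @param ... Further arguments passed to [simulate_subject()]
#'   (`n_minutes`, `start_time`, `params`, `night`, `zero_run_injection`).
#' @return A list with two tibbles: `activity` (`subject_id`, `timestamp`,
#'   `activity_count`, all subjects stacked) and `subjects` (`subject_id`,
#'   `phase`, `age`, `gender`).
#' @export
simulate_cohort <- function(n_subjects = 34L, seed = 1L,
                            fractions = NULL,
                            demographics = phase_demographics(),
                            ...) {
  if (n_subjects < 3) abort("n_subjects must be at least 3 (one per phase).")
  if (is.null(fractions)) {
    fractions <- setNames(demographics$fraction, demographics$phase)
  }
  fractions <- fractions[PHASE_LEVELS]
  if (anyNA(fractions) || abs(sum(fractions) - 1) > 1e-8) {
    abort("fractions must cover all three phases and sum to 1.")
  }
  sizes <- largest_remainder(fractions * n_subjects)
  if (any(sizes == 0)) abort("each phase needs at least one subject; increase n_subjects.")

  phases <- rep(names(sizes), sizes)
  ids <- sprintf("S%03d", seq_len(n_subjects))

  with_seed_(seed, {
    subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    ages <- numeric(n_subjects)
    for (ph in PHASE_LEVELS) {
      d <- demographics[demographics$phase == ph, ]
      k <- which(phases == ph)
      ages[k] <- rnorm_trunc(length(k), d$age_mean, d$age_sd, lower = 18)
    }
    female <- rbinom(n_subjects, 1, demographics$female_fraction[1]) == 1
    subjects <- tibble::tibble(
      subject_id = ids,
      phase = phases,
      age = round(ages, 1),
      gender = ifelse(female, "female", "male")
    )
  })

  activity <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    simulate_subject(phases[i], seed = subject_seeds[i], subject_id = ids[i], ...)
  })
  list(activity = activity, subjects = subjects)
}

# Integer apportionment: floor everything, then hand out the remaining units
# in order of decreasing fractional remainder.
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  setNames(as.integer(fl), names(x))
}

rnorm_trunc <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  for (i in seq_len(n)) {
    while (out[i] < lower) out[i] <- rnorm(1, mean, sd)
  }
  out
}

#' Write a cohort to CSV files
#'
#' @param cohort List with `activity` and `subjects` tibbles, as returned by
#'   [simulate_cohort()].
#' @param dir Output directory (created if needed); writes `activity.csv` and
#'   `subjects.csv`.
#' @return The directory path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_activity_csv(cohort$activity, file.path(dir, "activity.csv"))
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"), progress = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir Directory containing `activity.csv` and `subjects.csv`.
#' @return A list with `activity` and `subjects` tibbles.
#' @export
read_cohort_csv <- function(dir) {
  list(
    activity = read_activity_csv(file.path(dir, "activity.csv")),
    subjects = readr::read_csv(file.path(dir, "subjects.csv"),
                               show_col_types = FALSE, progress = FALSE)
  )
}

# Evaluate code under a local seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("seed must be a single finite integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Monte-Carlo means of extracted features per phase
#'
#' Simulates `n_per_phase` replicate subjects for each illness phase,
#' runs the real extraction path (window slicing, active-period search,
#' activity parameters) and averages each of the 12 features within phase.
#' This is the generator's calibration check: with the default process
#' parameters, every mean is expected to fall inside the corresponding CI in
#' [phase_profiles()].
#'
#' @param n_per_phase Replicate subjects per phase (200 for the calibration
#'   property).
#' @param seed_base Integer; per-subject seeds are derived from it.
#' @param params Process-parameter table passed to [simulate_subject()].
#' @return A long tibble: `phase`, `window`, `parameter`, `value` (the
#'   Monte-Carlo mean), `n_used` (replicates with a defined value).
#' @export
phase_feature_means <- function(n_per_phase = 200, seed_base = 1L,
                                params = default_process_params()) {
  res <- purrr::map_dfr(seq_along(PHASE_LEVELS), function(pi) {
    ph <- PHASE_LEVELS[pi]
    feats <- purrr::map_dfr(seq_len(n_per_phase), function(i) {
      s <- simulate_subject(
        ph, seed = (seed_base + i * 131L + pi * 1000003L) %% .Machine$integer.max,
        params = params, subject_id = sprintf("%s_%03d", ph, i)
      )
      seg <- suppressWarnings(extract_segments(s))
      f <- seg |>
        dplyr::mutate(.f = purrr::map(.data$counts, segment_features)) |>
        dplyr::select("window", ".f") |>
        tidyr::unnest(".f")
      f$phase <- ph
      f
    })
    feats
  })
  res |>
    tidyr::pivot_longer(c("mean_cpm", "sd_pct", "rmssd_pct", "autocorr_lag1",
                          "sampen", "fourier_ratio"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$phase, .data$window, .data$parameter) |>
    dplyr::summarise(n_used = sum(!is.na(.data$value)),
                     value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::select("phase", "window", "parameter", "value", "n_used")
}
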