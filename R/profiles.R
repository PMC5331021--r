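#' Phase-specific activity parameter targets
#'
#' Published group estimates (mean and 95% CI) of the six activity parameters
#' in the 64-min active morning and evening periods, for each acute phase of
#' bipolar disorder. These are the calibration targets of the synthetic-cohort
#' generator: with the default profiles, the phase mean of every extracted
#' feature is expected to fall inside the matching CI.
#'
#' @return A tibble with columns `phase`, `window`, `parameter` (one of
#'   `mean_cpm`, `sd_pct`, `rmssd_pct`, `autocorr_lag1`, `sampen`,
#'   `fourier_ratio`), `target`, `ci_low`, `ci_high`.
#' @export
phase_profiles <- function() {
  tab <- dplyr::tribble(
    ~parameter,       ~phase,               ~window,   ~target, ~ci_low, ~ci_high,
    "mean_cpm",       "bipolar_depression", "morning", 218.53, 132.02, 305.04,
    "mean_cpm",       "bipolar_depression", "evening", 154.86,  95.98, 213.75,
    "mean_cpm",       "mania",              "morning", 229.80, 154.24, 305.37,
    "mean_cpm",       "mania",              "evening", 239.34, 187.91, 290.78,
    "mean_cpm",       "mixed",              "morning", 281.72, 164.41, 399.02,
    "mean_cpm",       "mixed",              "evening", 254.49, 174.65, 334.33,
    "sd_pct",         "bipolar_depression", "morning", 117.42,  98.88, 135.96,
    "sd_pct",         "bipolar_depression", "evening", 129.48, 104.58, 154.37,
    "sd_pct",         "mania",              "morning",  90.04,  73.84, 106.24,
    "sd_pct",         "mania",              "evening",  92.11,  70.36, 113.85,
    "sd_pct",         "mixed",              "morning",  85.68,  60.54, 110.83,
    "sd_pct",         "mixed",              "evening", 111.13,  77.38, 144.88,
    "rmssd_pct",      "bipolar_depression", "morning", 108.12,  85.20, 131.05,
    "rmssd_pct",      "bipolar_depression", "evening", 124.81,  96.79, 152.84,
    "rmssd_pct",      "mania",              "morning",  88.75,  68.72, 108.78,
    "rmssd_pct",      "mania",              "evening",  90.75,  66.26, 115.23,
    "rmssd_pct",      "mixed",              "morning",  84.71,  53.62, 115.80,
    "rmssd_pct",      "mixed",              "evening",  97.61,  59.61, 135.61,
    "autocorr_lag1",  "bipolar_depression", "morning",   0.56,   0.46,   0.67,
    "autocorr_lag1",  "bipolar_depression", "evening",   0.53,   0.43,   0.62,
    "autocorr_lag1",  "mania",              "morning",   0.49,   0.40,   0.58,
    "autocorr_lag1",  "mania",              "evening",   0.49,   0.40,   0.58,
    "autocorr_lag1",  "mixed",              "morning",   0.51,   0.37,   0.65,
    "autocorr_lag1",  "mixed",              "evening",   0.60,   0.47,   0.74,
    "sampen",         "bipolar_depression", "morning",   1.05,   0.70,   1.40,
    "sampen",         "bipolar_depression", "evening",   1.03,   0.65,   1.41,
    "sampen",         "mania",              "morning",   1.41,   1.11,   1.72,
    "sampen",         "mania",              "evening",   1.36,   1.03,   1.69,
    "sampen",         "mixed",              "morning",   1.55,   1.08,   2.03,
    "sampen",         "mixed",              "evening",   0.96,   0.44,   1.47,
    "fourier_ratio",  "bipolar_depression", "morning",   0.67,   0.38,   0.96,
    "fourier_ratio",  "bipolar_depression", "evening",   0.77,   0.41,   1.14,
    "fourier_ratio",  "mania",              "morning",   0.90,   0.64,   1.15,
    "fourier_ratio",  "mania",              "evening",   1.05,   0.73,   1.37,
    "fourier_ratio",  "mixed",              "morning",   0.97,   0.58,   1.37,
    "fourier_ratio",  "mixed",              "evening",   0.58,   0.08,   1.07
  )
  dplyr::arrange(tab, factor(.data$phase, PHASE_LEVELS), .data$window,
                 .data$parameter)
}

#' Phase demographics of the study cohort
#'
#' Group sizes, cohort fractions and age distributions (mean with 95% CI) of
#' the three illness-phase groups, plus the cohort-level female fraction. Age
#' SDs are recovered from the printed CIs via
#' \eqn{SD = \mathrm{halfwidth}\sqrt{n}/t_{n-1,0.975}}. Simulated ages are
#' truncated at 18 years, matching the adult inclusion criterion.
#'
#' @return A tibble with columns `phase`, `n`, `fraction`, `age_mean`,
#'   `age_ci_low`, `age_ci_high`, `age_sd`, `female_fraction`.
#' @export
phase_demographics <- function() {
  d <- tibble::tibble(
    phase = PHASE_LEVELS,
    n = c(12L, 16L, 6L),
    age_mean = c(39.92, 51.22, 42.00),
    age_ci_low = c(29.99, 43.58, 26.65),
    age_ci_high = c(49.84, 58.86, 57.35)
  )
  d$fraction <- d$n / sum(d$n)
  half <- (d$age_ci_high - d$age_ci_low) / 2
  d$age_sd <- half * sqrt(d$n) / qt(0.975, d$n - 1)
  d$female_fraction <- 0.56
  d[c("phase", "n", "fraction", "age_mean", "age_ci_low", "age_ci_high",
      "age_sd", "female_fraction")]
}

# Process knobs of the generator, one row per phase x window regime.
# Each knob maps (approximately monotonically) to one extracted feature:
#   mu    -> mean_cpm           (lognormal amplitude mean)
#   b     -> sd_pct             (lognormal sigma)
#   phi   -> autocorr_lag1      (AR(1) coefficient of the latent noise;
#                                RMSSD follows via rmssd ~ sd*sqrt(2(1-ac1)))
#   v_lf  -> lowers sampen & fourier_ratio (32-min sinusoid variance share)
#   v_hf  -> raises fourier_ratio          (4-min sinusoid variance share)
# Values were calibrated by simulation so that, at 200 replicate subjects per
# phase, the mean of each of the 12 extracted features lies inside the CI in
# phase_profiles().
default_process_params <- function() {
  dplyr::tribble(
    ~phase,               ~window,   ~mu,     ~b,     ~phi,   ~v_lf, ~v_hf,
    "bipolar_depression", "morning", 213.863, 1.0891, 0.7785, 0.002, 0.0098,
    "bipolar_depression", "evening", 163.180, 1.2184, 0.7566, 0.002, 0.0107,
    "mania",              "morning", 233.078, 0.8343, 0.6186, 0.002, 0.0136,
    "mania",              "evening", 243.697, 0.8594, 0.6486, 0.002, 0.0315,
    "mixed",              "morning", 281.379, 0.8259, 0.6723, 0.002, 0.0308,
    "mixed",              "evening", 252.103, 1.0679, 0.7840, 0.002, 0.0108
  )
}
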