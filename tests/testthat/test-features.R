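test_that("mean and relative SD follow the sample-SD convention", {
  expect_equal(mean_cpm(rep(100, 64)), 100)
  expect_equal(sd_pct(rep(100, 64)), 0)
  # two-point alternating: population SD 100, sample SD 100*sqrt(64/63)
  x <- rep(c(0, 200), 32)
  expect_equal(mean_cpm(x), 100)
  expect_equal(sd_pct(x), 100 * sqrt(64 / 63))
  expect_error(sd_pct(rep(0, 64)), "mean 0")
})

test_that("RMSSD matches hand computation and forced constructions", {
  expect_equal(rmssd_pct(rep(7, 64)), 0)
  # [1,3,2]: sqrt((4+1)/2) = 1.5811, mean 2 -> 79.057%
  expect_equal(rmssd_pct(c(1, 3, 2)), 100 * sqrt(2.5) / 2)
  expect_equal(rmssd_pct(rep(c(0, 200), 32)), 200)
})

test_that("lag-1 autocorrelation has the correlogram convention and bias", {
  expect_lt(autocorr_lag1(rep(c(10, 200), 32)), -0.9)
  # matches stats::acf on arbitrary data
  withr::with_seed(11, {
    x <- rpois(64, 50)
    expect_equal(autocorr_lag1(x),
                 drop(stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]))
  })
  # long AR(1): estimate recovers the generating coefficient
  # (affine shift to positive counts leaves the autocorrelation unchanged)
  withr::with_seed(21, {
    e <- as.numeric(stats::arima.sim(list(ar = 0.5), 10000))
    expect_equal(autocorr_lag1(e - min(e) + 1), 0.5, tolerance = 0.03 / 0.5)
  })
  # small-sample bias of white noise at n = 64 is about -1/(n-1)
  withr::with_seed(31, {
    est <- replicate(1000, autocorr_lag1(rnorm(64, mean = 100, sd = 10)))
    expect_equal(mean(est), -1 / 63, tolerance = abs(3 * sd(est) / sqrt(1000) / (1 / 63)))
  })
  expect_error(autocorr_lag1(rep(5, 64)), "constant")
})

test_that("sample entropy is zero for a periodic series and scale invariant", {
  expect_equal(sample_entropy(rep(c(10, 90), 32)), 0)
  withr::with_seed(41, {
    x <- rpois(64, 30) + 1
    expect_equal(sample_entropy(x), sample_entropy(x * 17))
    expect_equal(sd_pct(x), sd_pct(x * 3))
    expect_equal(rmssd_pct(x), rmssd_pct(x * 3))
    expect_equal(fourier_ratio(x), fourier_ratio(x * 3))
    expect_equal(mean_cpm(x * 3), 3 * mean_cpm(x))
  })
})

test_that("sample entropy equals the brute-force template counter", {
  withr::with_seed(51, {
    for (i in 1:25) {
      x <- round(100 * exp(rnorm(64, sd = 0.7)))
      expect_equal(sample_entropy(x), sampen_brute(x))
    }
  })
})

test_that("an unmatched template set yields the undefined-entropy flag", {
  # the only matching pair of length-2 templates diverges at the next point,
  # so A = 0 and -ln(A/B) is undefined
  x <- c(10, 20, 10, 1000)
  expect_true(is.na(sample_entropy(x)))
})

test_that("Fourier band attribution handles sinusoid constructions", {
  t <- 1:64
  lf_only <- 100 + 50 * sin(2 * pi * t / 32)
  expect_equal(fourier_ratio(lf_only), 0, tolerance = 1e-9)
  hf_only <- 100 + 50 * sin(2 * pi * t / 4)
  expect_true(is.na(fourier_ratio(hf_only)))
  # equal-amplitude mixture splits variance evenly between the bands
  mix <- 100 + 50 * sin(2 * pi * t / 32 + 0.3) + 50 * sin(2 * pi * t / 4 + 1.1)
  expect_equal(fourier_ratio(mix), 1, tolerance = 1e-6)
})

test_that("the periodogram bins close under Parseval and partition into bands", {
  withr::with_seed(61, {
    for (i in 1:10) {
      x <- rpois(64, 40)
      b <- fourier_bands(x)
      z <- (x - mean(x)) / sd(x)
      expect_equal(sum(b$variance), mean(z^2), tolerance = 1e-9)
      expect_equal(sum(b$variance[b$band == "low"]) +
                     sum(b$variance[b$band == "high"]),
                   sum(b$variance))
    }
  })
  # band edges: 8-min period is low-frequency, Nyquist (2 min) high
  b <- fourier_bands(rpois(64, 20))
  expect_equal(b$band[b$period_min == 8], "low")
  expect_equal(b$band[b$k == 32], "high")
  expect_equal(sum(b$band == "low"), 8)
  expect_equal(sum(b$band == "high"), 24)
})

test_that("feature table has the fixed shape and reports exclusions", {
  withr::with_seed(71, {
    segs <- tibble::tibble(
      subject_id = rep(c("A", "B", "C"), each = 2),
      window = rep(c("morning", "evening"), 3),
      counts = lapply(1:6, function(i) rpois(64, 60) + 1)
    )
    subjects <- tibble::tibble(
      subject_id = c("A", "B", "C"),
      phase = c("mania", "mixed", "bipolar_depression"),
      age = c(40, 50, 35), gender = c("female", "male", "female")
    )
    ft <- build_feature_table(segs, subjects)
    expect_equal(nrow(ft), 3)
    expect_equal(names(ft)[1:4], c("subject_id", "phase", "age", "gender"))
    expect_equal(sum(grepl("^(morning|evening)_", names(ft))), 12)
    expect_equal(nrow(exclusion_report(ft)), 0)

    # a subject with a missing evening segment is excluded and reported
    expect_warning(build_feature_table(segs[-2, ], subjects), "excluded")
    ft2 <- suppressWarnings(build_feature_table(segs[-2, ], subjects))
    expect_equal(nrow(ft2), 2)
    expect_equal(exclusion_report(ft2)$subject_id, "A")
  })
})
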