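# Independent oracles used across the suite. These deliberately use naive
# brute-force formulations, not the package's own code paths.

# O(n^2) template-counting sample entropy, straight from the definition.
sampen_brute <- function(x, m = 2, r = 0.2) {
  z <- (x - mean(x)) / sd(x)
  n <- length(z)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(z[i:(i + m - 1)] - z[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1L
        if (max(dm, abs(z[i + m] - z[j + m])) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Exhaustive active-period search: every (tolerance, start) pair in the order
# the relaxation rule prescribes.
active_segment_brute <- function(x, direction, seg_len = 64, start_tol = 2) {
  n <- length(x)
  starts <- seq_len(n - seg_len + 1)
  if (direction == "backward") starts <- rev(starts)
  mzr <- function(v) {
    r <- rle(v == 0); z <- r$lengths[r$values]
    if (length(z) == 0) 0 else max(z)
  }
  for (k in start_tol:seg_len) {
    for (s in starts) {
      if (mzr(x[s:(s + seg_len - 1)]) <= k) {
        return(list(start = s, tolerance_used = k,
                    counts = x[s:(s + seg_len - 1)]))
      }
    }
  }
  stop("unreachable")
}

# Random count series with frequent zeros and occasional long zero runs, to
# stress the relaxation rule.
random_zeroish_series <- function(n, p_zero = 0.35, run_rate = 0.03) {
  x <- ifelse(runif(n) < p_zero, 0, rpois(n, 40))
  starts <- which(runif(n) < run_rate)
  for (s in starts) {
    len <- sample(2:8, 1)
    x[s:min(n, s + len - 1)] <- 0
  }
  x
}

# Hotelling T^2 two-group F statistic (closed form).
hotelling_F <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2); p <- ncol(X1)
  d <- colMeans(X1) - colMeans(X2)
  S <- (crossprod(scale(X1, scale = FALSE)) +
        crossprod(scale(X2, scale = FALSE))) / (n1 + n2 - 2)
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(S, d))
  (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * T2
}

# Small separated 3-group multivariate dataset for DFA tests.
make_groups <- function(n_per = c(12, 16, 6), p = 4, sep = 2, sd = 1) {
  g <- rep(c("bipolar_depression", "mania", "mixed"), n_per)
  centers <- rbind(rep(0, p), c(rep(sep, ceiling(p / 2)), rep(0, floor(p / 2))),
                   rep(-sep, p))
  X <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rnorm(n_per[k] * p, sd = sd), n_per[k], p) +
      matrix(centers[k, ], n_per[k], p, byrow = TRUE)
  }))
  d <- as.data.frame(X)
  names(d) <- paste0("x", seq_len(p))
  d$phase <- g
  d
}
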