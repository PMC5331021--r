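test_that("residual scores reduce to z-scores without covariates", {
  withr::with_seed(201, {
    d <- make_groups()
    d$age <- rnorm(nrow(d), 45, 10)
    d$gender <- sample(c("female", "male"), nrow(d), replace = TRUE)
    rs <- residual_scores(d, covariates = character(0))
    for (cn in paste0("x", 1:4)) {
      expect_equal(rs[[cn]], as.vector(scale(d[[cn]])), tolerance = 1e-12)
    }
  })
})

test_that("residual scores are standardized and orthogonal to covariates", {
  withr::with_seed(202, {
    d <- make_groups()
    d$age <- rnorm(nrow(d), 45, 10) + d$x1 * 2   # predictors confounded with age
    d$gender <- sample(c("female", "male"), nrow(d), replace = TRUE)
    rs <- residual_scores(d)
    for (cn in paste0("x", 1:4)) {
      expect_equal(mean(rs[[cn]]), 0, tolerance = 1e-12)
      expect_equal(sd(rs[[cn]]), 1, tolerance = 1e-12)
      expect_equal(stats::cor(rs[[cn]], d$age), 0, tolerance = 1e-10)
    }
    expect_error(residual_scores(dplyr::mutate(d, x1 = 1)), "constant")
  })
})

test_that("MANOVA screen is null for duplicated relabeled groups", {
  withr::with_seed(203, {
    X <- matrix(rnorm(15 * 3), 15, 3)
    d <- as.data.frame(rbind(X, X))
    d$phase <- rep(c("mania", "mixed"), each = 15)
    sc <- manova_screen(d)
    expect_equal(sc$wilks, 1, tolerance = 1e-10)
    expect_lt(sc$statistic, 1e-3)
  })
})

test_that("two-group MANOVA F equals the Hotelling T-squared F exactly", {
  withr::with_seed(204, {
    X1 <- matrix(rnorm(12 * 3, 0), 12, 3)
    X2 <- matrix(rnorm(16 * 3, 0.8), 16, 3)
    d <- as.data.frame(rbind(X1, X2))
    d$phase <- rep(c("bipolar_depression", "mania"), c(12, 16))
    sc <- manova_screen(d)
    expect_equal(sc$statistic, hotelling_F(X1, X2), tolerance = 1e-10)
  })
})

test_that("MANOVA screen agrees with the built-in MANOVA and flags separation", {
  withr::with_seed(205, {
    d <- make_groups(sep = 0.5)
    sc <- manova_screen(d)
    ref <- summary(stats::manova(as.matrix(d[paste0("x", 1:4)]) ~ d$phase),
                   test = "Wilks")$stats
    expect_equal(sc$wilks, unname(ref[1, "Wilks"]), tolerance = 1e-8)
    expect_equal(sc$statistic, unname(ref[1, "approx F"]), tolerance = 1e-8)
    expect_equal(sc$p_value, unname(ref[1, "Pr(>F)"]), tolerance = 1e-8)

    strong <- make_groups(sep = 3)
    expect_lt(manova_screen(strong)$p_value, 0.001)
  })
})

test_that("eigenvalue identities hold on every fit", {
  withr::with_seed(206, {
    for (i in 1:10) {
      d <- make_groups(sep = runif(1, 0.5, 3))
      f <- fit_dfa(d)
      lam <- f$eigenvalues
      expect_equal(f$canonical_correlation^2, lam / (1 + lam), tolerance = 1e-12)
      for (k in seq_along(lam)) {
        expect_equal(f$wilks[k] * prod(1 + lam[k:length(lam)]), 1,
                     tolerance = 1e-10)
      }
      expect_equal(sum(f$pct_variance), 100, tolerance = 1e-10)
      # group-size-weighted centroid mean is zero on each function
      w <- f$counts / f$n
      expect_equal(drop(w %*% f$centroids), rep(0, ncol(f$centroids)),
                   tolerance = 1e-9, ignore_attr = TRUE)
      # discriminant scores have pooled within-group variance 1
      Zc <- f$scores - f$centroids[f$groups, , drop = FALSE]
      expect_equal(colSums(Zc^2) / (f$n - f$g), rep(1, ncol(Zc)),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  })
})

test_that("identical group distributions give all-zero eigenvalues", {
  withr::with_seed(207, {
    X <- matrix(rnorm(10 * 3), 10, 3)
    d <- as.data.frame(rbind(X, X, X))
    d$phase <- rep(c("bipolar_depression", "mania", "mixed"), each = 10)
    f <- fit_dfa(d)
    expect_equal(f$eigenvalues, rep(0, 2), tolerance = 1e-10, ignore_attr = TRUE)
  })
})

test_that("the two-group discriminant direction matches Fisher's closed form", {
  withr::with_seed(208, {
    d <- make_groups(n_per = c(14, 16, 4), p = 2, sep = 1.5)
    d <- d[d$phase != "mixed", ]
    f <- fit_dfa(d)
    X <- as.matrix(d[c("x1", "x2")])
    grp <- factor(d$phase)
    mns <- rowsum(X, grp) / as.numeric(table(grp))
    Xc <- X - mns[grp, ]
    Wm <- crossprod(Xc)
    dirn <- solve(Wm, mns[1, ] - mns[2, ])
    a <- f$coefficients[, 1]
    expect_equal(abs(stats::cor(a, dirn)), 1, tolerance = 1e-8)
  })
})

test_that("Bartlett chi-square uses the textbook multiplier", {
  withr::with_seed(209, {
    d <- make_groups()
    f <- fit_dfa(d)
    mult <- f$n - 1 - (f$p + f$g) / 2
    expect_equal(f$chi2, -mult * log(f$wilks), tolerance = 1e-12)
    expect_equal(f$df, (f$p - seq_along(f$eigenvalues) + 1) *
                   (f$g - seq_along(f$eigenvalues)))
  })
})

test_that("group centroids classify to their own group under equal priors", {
  withr::with_seed(210, {
    d <- make_groups(sep = 2)
    f <- fit_dfa(d, priors = "equal")
    cen <- as.data.frame(f$group_means)
    names(cen) <- f$predictor_cols
    pred <- predict(f, cen)$.pred
    expect_equal(as.character(pred), f$levels)
  })
})

test_that("classification agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  withr::with_seed(211, {
    for (i in 1:50) {
      d <- make_groups(n_per = sample(5:15, 3, replace = TRUE),
                       p = sample(2:5, 1), sep = runif(1, 0, 2.5))
      f <- fit_dfa(d)
      ours <- as.character(predict(f)$.pred)
      ld <- MASS::lda(phase ~ ., data = d[c(f$predictor_cols, "phase")])
      theirs <- as.character(predict(ld)$class)
      expect_equal(ours, theirs)
      # eigenvalue spectrum agrees too (svd in MASS is sqrt of lambda scaled)
      lam_theirs <- ld$svd^2 / (nrow(d) - 3) * 1
      expect_equal(f$eigenvalues / f$eigenvalues[1],
                   lam_theirs / lam_theirs[1], tolerance = 1e-6)
    }
  })
})

test_that("score ties break to the earlier group in the fixed label order", {
  withr::with_seed(212, {
    X <- matrix(rnorm(12 * 2), 12, 2)
    d <- as.data.frame(rbind(X, X))   # identical distributions, equal priors
    d$phase <- rep(c("mania", "mixed"), each = 12)
    f <- fit_dfa(d, priors = "equal")
    # identical group means make every classification score equal
    pred <- predict(f)$.pred
    expect_true(all(pred == "mania"))
  })
})

test_that("ill-posed fits raise informative errors", {
  withr::with_seed(213, {
    d <- make_groups(n_per = c(3, 3, 3), p = 10)
    expect_error(fit_dfa(d), "singular")
    d2 <- make_groups()
    expect_error(fit_dfa(d2, priors = c(a = 0.5, b = 0.5)), "priors")
    expect_error(predict(fit_dfa(d2), d2[, 1:2]), "missing predictor")
  })
})

test_that("tidy and glance expose the discriminant summary", {
  withr::with_seed(214, {
    d <- make_groups()
    f <- fit_dfa(d)
    td <- tidy(f)
    expect_equal(nrow(td), 2)
    expect_named(td, c("fn", "eigenvalue", "pct_variance",
                       "canonical_correlation", "wilks", "chi2", "df",
                       "p_value"))
    gl <- glance(f)
    expect_equal(gl$n, nrow(d))
    expect_equal(gl$wilks, f$wilks[1])
  })
})
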