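#' Standardized residual scores of the activity predictors
#'
#' Prepares the predictor matrix for the discriminant analysis: each activity
#' parameter is regressed (OLS with intercept) on the covariates, and the
#' residuals are divided by their sample SD, yielding columns with mean 0 and
#' SD 1 that are orthogonal to the covariates. With an empty covariate set
#' this reduces to plain z-scores.
#'
#' @param data A feature table (see [build_feature_table()]).
#' @param covariates Character vector of covariate column names (default
#'   `c("age", "gender")`); may be empty.
#' @param predictor_cols Columns to standardize; defaults to every numeric
#'   column not named in `covariates` and not `subject_id`/`phase`.
#' @return A tibble with `subject_id`, `phase` (when present in `data`) and
#'   the standardized predictor columns.
#' @export
residual_scores <- function(data, covariates = c("age", "gender"),
                            predictor_cols = NULL) {
  if (is.null(predictor_cols)) {
    predictor_cols <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(covariates, "subject_id", "phase")
    )
  }
  if (length(predictor_cols) == 0) abort("no predictor columns found.")
  n <- nrow(data)
  if (n < length(covariates) + 3) abort("too few rows to residualize predictors.")

  keep <- intersect(c("subject_id", "phase"), names(data))
  out <- data[keep]
  if (length(covariates) > 0) {
    miss <- setdiff(covariates, names(data))
    if (length(miss) > 0) {
      abort(paste0("missing covariate column(s): ", paste(miss, collapse = ", ")))
    }
    mm <- stats::model.matrix(
      stats::reformulate(covariates),
      data = data
    )
  } else {
    mm <- matrix(1, n, 1)
  }
  for (pc in predictor_cols) {
    y <- data[[pc]]
    if (sd(y) == 0) abort(paste0("predictor column ", pc, " is constant."))
    res <- stats::lm.fit(mm, y)$residuals
    out[[pc]] <- res / sd(res)
  }
  tibble::as_tibble(out)
}

#' MANOVA screen for overall group differences
#'
#' One-way multivariate analysis of variance across the phase groups:
#' Wilks' Lambda from the within/total scatter determinant ratio, with Rao's
#' F approximation. Used as a preliminary screen before the discriminant
#' analysis.
#'
#' @param data Data frame containing the predictors and the group column.
#' @param group_col Name of the grouping column (default `"phase"`).
#' @param predictor_cols Predictor columns; default all numeric columns
#'   except `group_col`, `subject_id`, `age`.
#' @return A one-row tibble: `wilks`, `statistic` (approximate F), `df1`,
#'   `df2`, `p_value`, `n`, `n_groups`, `n_predictors`.
#' @export
manova_screen <- function(data, group_col = "phase", predictor_cols = NULL) {
  xg <- dfa_matrix(data, group_col, predictor_cols)
  X <- xg$X; grp <- xg$groups
  N <- nrow(X); p <- ncol(X); g <- nlevels(grp)
  if (g < 2 || any(table(grp) < 2)) {
    abort("manova_screen needs at least two groups with two rows each.")
  }
  sc <- scatter_matrices(X, grp)
  Tm <- sc$W + sc$B
  lam <- det(sc$W) / det(Tm)
  if (!is.finite(lam) || lam <= 0) {
    abort(paste0("within-group scatter is singular (N = ", N, ", p = ", p,
                 "); reduce the predictor set."))
  }
  # Rao's F approximation
  t_den <- p^2 + (g - 1)^2 - 5
  tt <- if (t_den > 0) sqrt((p^2 * (g - 1)^2 - 4) / t_den) else 1
  df1 <- p * (g - 1)
  df2 <- (N - 1 - (p + g) / 2) * tt - (df1 - 2) / 2
  lw <- lam^(1 / tt)
  Fstat <- (1 - lw) / lw * df2 / df1
  tibble::tibble(
    wilks = lam, statistic = Fstat, df1 = df1, df2 = df2,
    p_value = pf(Fstat, df1, df2, lower.tail = FALSE),
    n = N, n_groups = g, n_predictors = p
  )
}

#' Fit a canonical discriminant function analysis
#'
#' Solves the generalized eigenproblem of the between-group against the
#' within-group scatter, yielding canonical discriminant functions that
#' maximally separate the phase groups. Reports eigenvalues, percentage of
#' explained variance, canonical correlations, Wilks' Lambda per function
#' with Bartlett's chi-square test, raw and standardized coefficients (scores
#' scaled to pooled within-group variance 1), the structure matrix of pooled
#' within-group predictor-score correlations, group centroids, and Fisher
#' linear classification functions built from the pooled within-group
#' covariance and the priors.
#'
#' @param data Data frame of predictors plus a group column (typically the
#'   output of [residual_scores()]).
#' @param group_col Name of the grouping column (default `"phase"`).
#' @param predictor_cols Predictor columns; default all numeric columns
#'   except `group_col`, `subject_id`, `age`.
#' @param priors `"proportional"` (to group sizes, default) or `"equal"`, or
#'   a named numeric vector of prior probabilities summing to 1.
#' @return An object of class `"dfa"`; see [tidy.dfa()], [glance.dfa()],
#'   [predict.dfa()], [structure_matrix()], [autoplot.dfa()].
#' @export
fit_dfa <- function(data, group_col = "phase", predictor_cols = NULL,
                    priors = c("proportional", "equal")) {
  xg <- dfa_matrix(data, group_col, predictor_cols)
  X <- xg$X; grp <- xg$groups
  N <- nrow(X); p <- ncol(X); g <- nlevels(grp)
  if (N <= p) {
    abort(paste0("N = ", N, " cases cannot support p = ", p,
                 " predictors; the within-group scatter would be singular. ",
                 "Reduce the predictor set or pool groups."))
  }
  counts <- table(grp)
  if (is.character(priors)) {
    priors <- match.arg(priors)
    pri <- if (priors == "proportional") as.numeric(counts) / N
           else rep(1 / g, g)
  } else {
    pri <- as.numeric(priors[levels(grp)])
    if (anyNA(pri) || abs(sum(pri) - 1) > 1e-8) {
      abort("numeric priors must be named by group and sum to 1.")
    }
  }
  names(pri) <- levels(grp)

  sc <- scatter_matrices(X, grp)
  W <- sc$W; B <- sc$B
  Sw <- W / (N - g)
  R <- tryCatch(chol(W), error = function(e) {
    abort("within-group scatter is singular; cannot fit the DFA.")
  })
  Ri <- backsolve(R, diag(p))
  M <- crossprod(Ri, B %*% Ri)           # symmetric; same spectrum as W^-1 B
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  s <- min(g - 1, p)
  lambda <- pmax(eg$values[seq_len(s)], 0)
  A <- Ri %*% eg$vectors[, seq_len(s), drop = FALSE]
  A <- A * sqrt(N - g)                    # pooled within-group score variance 1
  # deterministic sign: largest-|coefficient| entry of each function positive
  for (j in seq_len(s)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  rownames(A) <- colnames(X)
  colnames(A) <- paste0("function_", seq_len(s))

  grand <- colMeans(X)
  scores <- sweep(X, 2, grand) %*% A
  centroids <- rowsum(scores, grp) / as.numeric(counts)

  # pooled within-group correlations of predictors with discriminant scores
  Xc <- X - rowsum(X, grp)[grp, ] / as.numeric(counts)[grp]
  Zc <- scores - centroids[grp, , drop = FALSE]
  sw_sd <- sqrt(diag(Sw))
  struct <- crossprod(Xc, Zc) / (N - g) / sw_sd   # score pooled SD is 1
  dimnames(struct) <- dimnames(A)

  # Fisher linear classification functions from pooled covariance + priors
  means <- rowsum(X, grp) / as.numeric(counts)
  Swi <- chol2inv(chol(Sw))
  cf_coef <- Swi %*% t(means)
  cf_const <- -0.5 * colSums(t(means) * cf_coef) + log(pri)
  dimnames(cf_coef) <- list(colnames(X), levels(grp))

  wilks <- rev(cumprod(rev(1 / (1 + lambda))))
  chi_mult <- N - 1 - (p + g) / 2
  chi2 <- -chi_mult * log(wilks)
  dfk <- (p - seq_len(s) + 1) * (g - seq_len(s))

  structure(list(
    levels = levels(grp), counts = as.integer(counts), priors = pri,
    n = N, p = p, g = g,
    predictor_cols = colnames(X), group_col = group_col,
    grand_mean = grand, group_means = means, pooled_cov = Sw,
    eigenvalues = lambda,
    pct_variance = 100 * lambda / sum(lambda),
    canonical_correlation = sqrt(lambda / (1 + lambda)),
    wilks = wilks, chi2 = chi2, df = dfk,
    p_value = pchisq(chi2, dfk, lower.tail = FALSE),
    coefficients = A,
    std_coefficients = A * sw_sd,
    structure_matrix = struct,
    centroids = centroids,
    scores = scores, groups = grp, training_X = X,
    classification = list(coef = cf_coef, const = cf_const)
  ), class = "dfa")
}

#' Identity layer linking eigenvalues to the derived discriminant statistics
#'
#' Given canonical eigenvalues, computes the quantities that are pure
#' functions of them: percentage of explained variance, canonical
#' correlations \eqn{\sqrt{\lambda/(1+\lambda)}} and the Wilks' Lambda ladder
#' \eqn{\Lambda_k = \prod_{i \ge k} 1/(1+\lambda_i)}.
#'
#' @param lambda Numeric vector of eigenvalues, descending.
#' @return A tibble with columns `fn`, `eigenvalue`, `pct_variance`,
#'   `canonical_correlation`, `wilks`.
#' @export
discriminant_identities <- function(lambda) {
  if (any(lambda < 0)) abort("eigenvalues must be non-negative.")
  tibble::tibble(
    fn = seq_along(lambda),
    eigenvalue = lambda,
    pct_variance = 100 * lambda / sum(lambda),
    canonical_correlation = sqrt(lambda / (1 + lambda)),
    wilks = rev(cumprod(rev(1 / (1 + lambda))))
  )
}

#' @export
print.dfa <- function(x, ...) {
  cat("Canonical discriminant function analysis\n")
  cat("  ", x$n, "cases,", x$p, "predictors,", x$g, "groups (",
      paste(x$levels, collapse = ", "), ")\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a fitted discriminant analysis
#'
#' @param x A `"dfa"` object.
#' @param ... Unused.
#' @return One row per canonical function: `fn`, `eigenvalue`,
#'   `pct_variance`, `canonical_correlation`, `wilks`, `chi2`, `df`,
#'   `p_value`.
#' @export
tidy.dfa <- function(x, ...) {
  tibble::tibble(
    fn = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    pct_variance = x$pct_variance,
    canonical_correlation = x$canonical_correlation,
    wilks = x$wilks,
    chi2 = x$chi2,
    df = x$df,
    p_value = x$p_value
  )
}

#' Model-level summary of a fitted discriminant analysis
#'
#' @param x A `"dfa"` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_predictors`, `n_groups`,
#'   `n_functions`, `wilks`, `chi2`, `df`, `p_value` (the first-function
#'   ladder test).
#' @export
glance.dfa <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_predictors = x$p, n_groups = x$g,
    n_functions = length(x$eigenvalues),
    wilks = x$wilks[1], chi2 = x$chi2[1], df = x$df[1],
    p_value = x$p_value[1]
  )
}

#' Classify cases with a fitted discriminant analysis
#'
#' Assigns each row to the group with the highest Fisher classification
#' score (equivalently, the smallest prior-adjusted Mahalanobis distance
#' under the pooled within-group covariance). Ties break deterministically
#' to the group earlier in the fixed label order.
#'
#' @param object A `"dfa"` object.
#' @param newdata Data frame containing the model's predictor columns;
#'   defaults to the training data.
#' @param ... Unused.
#' @return A tibble with `.pred` (factor), the per-group classification
#'   scores, and the canonical discriminant scores `function_*`.
#' @export
predict.dfa <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    Xm <- object$training_X
  } else {
    miss <- setdiff(object$predictor_cols, names(newdata))
    if (length(miss) > 0) {
      abort(paste0("newdata is missing predictor column(s): ",
                   paste(miss, collapse = ", ")))
    }
    Xm <- as.matrix(newdata[object$predictor_cols])
  }
  cs <- Xm %*% object$classification$coef
  cs <- sweep(cs, 2, object$classification$const, "+")
  pred <- factor(object$levels[max.col(cs, ties.method = "first")],
                 levels = object$levels)
  scr <- sweep(Xm, 2, object$grand_mean) %*% object$coefficients
  out <- tibble::tibble(.pred = pred)
  for (j in colnames(cs)) out[[paste0("score_", j)]] <- cs[, j]
  for (j in colnames(scr)) out[[j]] <- scr[, j]
  out
}

# Shared predictor-matrix assembly for the DFA family of fitters.
dfa_matrix <- function(data, group_col, predictor_cols) {
  if (!group_col %in% names(data)) {
    abort(paste0("grouping column `", group_col, "` not found."))
  }
  if (is.null(predictor_cols)) {
    predictor_cols <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(group_col, "subject_id", "age")
    )
  }
  miss <- setdiff(predictor_cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("missing predictor column(s): ", paste(miss, collapse = ", ")))
  }
  X <- as.matrix(data[predictor_cols])
  if (anyNA(X)) abort("predictors contain missing values; exclude those rows first.")
  grp <- data[[group_col]]
  lev <- if (is.factor(grp)) levels(droplevels(grp)) else {
    u <- unique(as.character(grp))
    known <- intersect(PHASE_LEVELS, u)
    c(known, sort(setdiff(u, known)))      # fixed phase order, extras sorted
  }
  list(X = X, groups = factor(as.character(grp), levels = lev))
}

# Within-group (W) and between-group (B) scatter about the grand mean.
scatter_matrices <- function(X, grp) {
  counts <- as.numeric(table(grp))
  means <- rowsum(X, grp) / counts
  Xc <- X - means[grp, , drop = FALSE]
  W <- crossprod(Xc)
  grand <- colMeans(X)
  Mc <- sweep(means, 2, grand) * sqrt(counts)
  B <- crossprod(Mc)
  list(W = W, B = B)
}
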