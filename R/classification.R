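#' Classification table with accuracy and chi-square test
#'
#' Cross-tabulates original against predicted group, with per-group and
#' overall accuracy and a Pearson chi-square test of the g x g contingency
#' table (expected counts from the row/column margins, df = (g-1)^2).
#'
#' @param truth Factor or character vector of original group labels, or a
#'   g x g counts matrix (rows = original, columns = predicted) when
#'   `estimate` is missing.
#' @param estimate Predicted labels, same length as `truth`.
#' @param levels Label order; defaults to the fixed phase order for phase
#'   labels, otherwise the sorted union of observed labels.
#' @param mode `"apparent"` (training-data reclassification) or
#'   `"leave_one_out"`.
#' @return An object of class `"classification_table"`: list with `counts`,
#'   `per_group_accuracy` (%), `overall_accuracy` (%), `chi2`, `df`,
#'   `p_value`, `n`, `mode`.
#' @export
classification_table <- function(truth, estimate = NULL, levels = NULL,
                                 mode = c("apparent", "leave_one_out")) {
  mode <- match.arg(mode)
  if (is.matrix(truth) && is.null(estimate)) {
    counts <- truth
    if (nrow(counts) != ncol(counts)) abort("counts matrix must be square.")
    if (is.null(rownames(counts))) {
      rownames(counts) <- colnames(counts) <-
        if (nrow(counts) == 3) PHASE_LEVELS else paste0("g", seq_len(nrow(counts)))
    }
  } else {
    if (length(truth) != length(estimate)) {
      abort("truth and estimate must have equal length.")
    }
    if (is.null(levels)) {
      u <- unique(c(as.character(truth), as.character(estimate)))
      known <- intersect(PHASE_LEVELS, u)
      levels <- c(known, sort(setdiff(u, known)))
    }
    bad <- setdiff(unique(as.character(estimate)), levels)
    if (length(bad) > 0) {
      abort(paste0("predicted label(s) not among the group levels: ",
                   paste(bad, collapse = ", ")))
    }
    truth <- factor(as.character(truth), levels = levels)
    estimate <- factor(as.character(estimate), levels = levels)
    counts <- unclass(table(truth, estimate))
  }
  g <- nrow(counts)
  n <- sum(counts)
  row_n <- rowSums(counts)
  per_group <- ifelse(row_n > 0, 100 * diag(counts) / row_n, NA_real_)
  overall <- 100 * sum(diag(counts)) / n
  expected <- outer(row_n, colSums(counts)) / n
  use <- expected > 0
  chi2 <- sum((counts[use] - expected[use])^2 / expected[use])
  df <- (g - 1)^2
  structure(list(
    counts = counts,
    per_group_accuracy = setNames(per_group, rownames(counts)),
    overall_accuracy = overall,
    chi2 = chi2, df = df,
    p_value = pchisq(chi2, df, lower.tail = FALSE),
    n = n, mode = mode
  ), class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  cat("Classification table (", x$mode, ")\n", sep = "")
  print(x$counts)
  cat(sprintf("overall accuracy %.1f%%  (chi2 = %.2f, df = %d, p = %.3g)\n",
              x$overall_accuracy, x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Tidy a classification table
#'
#' @param x A `"classification_table"`.
#' @param ... Unused.
#' @return Long tibble: `original`, `predicted`, `count`, `proportion` (of
#'   the original group).
#' @export
tidy.classification_table <- function(x, ...) {
  d <- as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)
  names(d) <- c("original", "predicted", "count")
  d <- tibble::as_tibble(d)
  row_n <- rowSums(x$counts)[d$original]
  d$proportion <- ifelse(row_n > 0, d$count / row_n, NA_real_)
  d
}

#' One-row summary of a classification table
#'
#' @param x A `"classification_table"`.
#' @param ... Unused.
#' @return Tibble with `n`, `overall_accuracy`, `chi2`, `df`, `p_value`,
#'   `mode`.
#' @export
glance.classification_table <- function(x, ...) {
  tibble::tibble(
    n = x$n, overall_accuracy = x$overall_accuracy,
    chi2 = x$chi2, df = x$df, p_value = x$p_value, mode = x$mode
  )
}

#' Leave-one-out cross-validated classification
#'
#' Deletes each case in turn, refits the discriminant functions on the
#' remaining N - 1 cases, classifies the held-out case, and aggregates the
#' results. Guards against the optimism of apparent (training-data)
#' reclassification. Folds whose within-group scatter is singular leave the
#' case unclassified; such cases are counted in the `"unclassifiable"`
#' attribute and excluded from the table.
#'
#' @inheritParams fit_dfa
#' @return A `"classification_table"` with `mode = "leave_one_out"`.
#' @export
loocv_dfa <- function(data, group_col = "phase", predictor_cols = NULL,
                      priors = c("proportional", "equal")) {
  grp <- data[[group_col]]
  if (is.null(grp)) abort(paste0("grouping column `", group_col, "` not found."))
  tb <- table(grp)
  if (any(tb < 3)) {
    warn("groups with fewer than 3 members make leave-one-out folds degenerate.")
  }
  n <- nrow(data)
  preds <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      fit_dfa(data[-i, , drop = FALSE], group_col, predictor_cols, priors),
      error = function(e) NULL
    )
    if (!is.null(fit_i)) {
      preds[i] <- as.character(predict(fit_i, data[i, , drop = FALSE])$.pred[1])
    }
  }
  ok <- !is.na(preds)
  if (!all(ok)) {
    warn(paste0(sum(!ok), " case(s) unclassifiable in leave-one-out folds."))
  }
  out <- classification_table(as.character(grp)[ok], preds[ok],
                              mode = "leave_one_out")
  attr(out, "unclassifiable") <- sum(!ok)
  out
}

#' Stratified case bootstrap of the discriminant analysis
#'
#' Resamples cases with replacement within each group, refits the
#' discriminant analysis on each replicate, and collects eigenvalues,
#' canonical correlations and apparent accuracy, with percentile 95%
#' confidence intervals. Replicates with a singular within-group scatter are
#' dropped and counted.
#'
#' @inheritParams fit_dfa
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the same seed reproduces the replicates exactly.
#' @return An object of class `"dfa_boot"`: list with `replicates` (tibble,
#'   one row per successful replicate), `ci` (percentile 2.5/97.5% bounds per
#'   statistic), `n_boot`, `n_failed`, `seed`.
#' @export
bootstrap_dfa <- function(data, group_col = "phase", predictor_cols = NULL,
                          priors = c("proportional", "equal"),
                          n_boot = 1000L, seed = 1L) {
  grp <- data[[group_col]]
  if (is.null(grp)) abort(paste0("grouping column `", group_col, "` not found."))
  idx_by_group <- split(seq_len(nrow(data)), as.character(grp))
  reps <- with_seed_(seed, {
    purrr::map(seq_len(n_boot), function(b) {
      take <- unlist(lapply(idx_by_group, function(ix) {
        sample(ix, length(ix), replace = TRUE)
      }), use.names = FALSE)
      fit_b <- tryCatch(
        fit_dfa(data[take, , drop = FALSE], group_col, predictor_cols, priors),
        error = function(e) NULL
      )
      if (is.null(fit_b)) return(NULL)
      acc <- classification_table(
        as.character(fit_b$groups), as.character(predict(fit_b)$.pred)
      )$overall_accuracy
      row <- tibble::tibble(replicate = b, accuracy = acc)
      for (j in seq_along(fit_b$eigenvalues)) {
        row[[paste0("eigenvalue_", j)]] <- fit_b$eigenvalues[j]
        row[[paste0("canonical_correlation_", j)]] <- fit_b$canonical_correlation[j]
      }
      row
    })
  })
  failed <- sum(vapply(reps, is.null, logical(1)))
  reps <- dplyr::bind_rows(reps)
  if (failed > 0.2 * n_boot) {
    warn(paste0(failed, " of ", n_boot, " bootstrap replicates were singular."))
  }
  stat_cols <- setdiff(names(reps), "replicate")
  ci <- purrr::map_dfr(stat_cols, function(cn) {
    q <- stats::quantile(reps[[cn]], c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    tibble::tibble(statistic = cn, ci_low = q[1], ci_high = q[2],
                   estimate = mean(reps[[cn]], na.rm = TRUE))
  })
  structure(list(replicates = reps, ci = ci, n_boot = n_boot,
                 n_failed = failed, seed = seed),
            class = "dfa_boot")
}

#' @export
print.dfa_boot <- function(x, ...) {
  cat("Stratified case bootstrap,", x$n_boot, "replicates (",
      x$n_failed, "singular )\n")
  print(x$ci, ...)
  invisible(x)
}

#' Tidy bootstrap percentile intervals
#'
#' @param x A `"dfa_boot"` object.
#' @param ... Unused.
#' @return The `ci` tibble: `statistic`, `estimate`, `ci_low`, `ci_high`.
#' @export
tidy.dfa_boot <- function(x, ...) {
  dplyr::select(x$ci, "statistic", "estimate", "ci_low", "ci_high")
}

#' Structure matrix report
#'
#' Pooled within-group correlations between each predictor and each
#' discriminant function. The full matrix is always retained in the fitted
#' model; with a masking threshold, loadings of absolute value below the
#' threshold are displayed as `NA` (the study convention treats loadings
#' below .3 as uninterpretable at this sample size).
#'
#' @param model A fitted `"dfa"`.
#' @param threshold Masking threshold on `|loading|`; `NULL` (or 0) returns
#'   the full matrix.
#' @return A tibble: `predictor`, then one column per function. Loadings are
#'   sorted by the function of their largest absolute loading, descending.
#' @export
structure_matrix <- function(model, threshold = NULL) {
  if (!inherits(model, "dfa")) abort("structure_matrix() expects a fitted dfa.")
  sm <- model$structure_matrix
  out <- sm
  if (!is.null(threshold) && threshold > 0) {
    out[abs(out) < threshold] <- NA_real_
  }
  tb <- tibble::as_tibble(out, rownames = "predictor")
  dom <- apply(abs(sm), 1, which.max)
  ord <- order(dom, -apply(abs(sm), 1, max))
  tb[ord, , drop = FALSE]
}
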