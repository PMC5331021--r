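#' Default end-to-end run configuration
#'
#' @param out_dir Output directory for run artifacts.
#' @param n_subjects,seed Cohort size and master seed for the simulation
#'   stage (ignored when `input_dir` points at an existing cohort).
#' @param input_dir Optional directory with `activity.csv` and
#'   `subjects.csv`; when `NULL` a synthetic cohort is generated.
#' @param day_rule Day-selection rule for window slicing.
#' @param seg_len Active-period length in minutes; must be a power of two so
#'   the Fourier band analysis applies directly.
#' @param start_tolerance Initial consecutive-zero tolerance of the
#'   active-period search.
#' @param covariates Covariates residualized out of the predictors.
#' @param priors Classification priors, `"proportional"` or `"equal"`.
#' @param n_boot Bootstrap replicates.
#' @param structure_threshold Masking threshold for the structure-matrix
#'   report.
#' @param alpha Significance level used in the run report.
#' @return A named list of settings for [run_pipeline()].
#' @export
pipeline_config <- function(out_dir = tempfile("actiphase_run_"),
                            n_subjects = 34L, seed = 17L, input_dir = NULL,
                            day_rule = "prefer_maximal_coverage",
                            seg_len = 64L, start_tolerance = 2L,
                            covariates = c("age", "gender"),
                            priors = "proportional", n_boot = 1000L,
                            structure_threshold = 0.3, alpha = 0.05) {
  cfg <- list(
    out_dir = out_dir, n_subjects = n_subjects, seed = seed,
    input_dir = input_dir, day_rule = day_rule, seg_len = as.integer(seg_len),
    start_tolerance = as.integer(start_tolerance), covariates = covariates,
    priors = priors, n_boot = as.integer(n_boot),
    structure_threshold = structure_threshold, alpha = alpha
  )
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  n <- cfg$seg_len
  if (n < 4 || bitwAnd(n, n - 1L) != 0L) {
    abort("seg_len must be a power of two (the Fourier analysis requires it).")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("alpha must lie in (0, 1).")
  if (cfg$start_tolerance < 1) abort("start_tolerance must be at least 1.")
  if (cfg$n_boot < 1) abort("n_boot must be at least 1.")
  invisible(cfg)
}

#' Run the full actigraphy classification pipeline
#'
#' Executes simulate (or load) -> slice -> extract active periods ->
#' compute activity parameters -> residualize -> MANOVA screen -> canonical
#' DFA -> apparent and leave-one-out classification -> bootstrap, persisting
#' every intermediate artifact as CSV/JSON in `config$out_dir` together with
#' a machine-readable run manifest. Any stage failure halts the run; partial
#' outputs are kept alongside a `FAILED` marker naming the stage.
#'
#' @param config A configuration list from [pipeline_config()].
#' @return Invisibly, a list with the in-memory results: `cohort`,
#'   `segments`, `features`, `scores`, `manova`, `fit`, `apparent`, `loocv`,
#'   `boot`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, code) {
    ts <- Sys.time()
    res <- tryCatch(force(code), error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    res
  }

  cohort <- stage("simulate", {
    if (is.null(config$input_dir)) {
      co <- simulate_cohort(config$n_subjects, seed = config$seed)
      write_cohort_csv(co, config$out_dir)
      co
    } else {
      read_cohort_csv(config$input_dir)
    }
  })

  segments <- stage("extract", {
    seg <- extract_segments(cohort$activity, day_rule = config$day_rule,
                            seg_len = config$seg_len,
                            start_tolerance = config$start_tolerance)
    write_segments_csv(seg, file.path(config$out_dir, "segments.csv"))
    seg
  })

  features <- stage("features", {
    ft <- build_feature_table(segments, cohort$subjects)
    readr::write_csv(ft, file.path(config$out_dir, "features.csv"),
                     progress = FALSE)
    excl <- exclusion_report(ft)
    readr::write_csv(excl, file.path(config$out_dir, "exclusions.csv"),
                     progress = FALSE)
    ft
  })

  scores <- stage("residualize", {
    residual_scores(features, covariates = config$covariates)
  })

  screen <- stage("manova", manova_screen(scores))

  fit <- stage("dfa", {
    f <- fit_dfa(scores, priors = config$priors)
    model_json <- list(
      eigenvalues = f$eigenvalues,
      pct_variance = f$pct_variance,
      canonical_correlation = f$canonical_correlation,
      wilks = f$wilks, chi2 = f$chi2, df = f$df, p_value = f$p_value,
      priors = as.list(f$priors),
      centroids = as.data.frame(f$centroids),
      std_coefficients = as.data.frame(f$std_coefficients)
    )
    jsonlite::write_json(model_json, file.path(config$out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    readr::write_csv(structure_matrix(f),
                     file.path(config$out_dir, "structure_matrix.csv"),
                     progress = FALSE)
    readr::write_csv(structure_matrix(f, config$structure_threshold),
                     file.path(config$out_dir, "structure_matrix_masked.csv"),
                     progress = FALSE)
    f
  })

  apparent <- stage("classify", {
    ct <- classification_table(as.character(fit$groups),
                               as.character(predict(fit)$.pred))
    readr::write_csv(tidy(ct),
                     file.path(config$out_dir, "classification_apparent.csv"),
                     progress = FALSE)
    ct
  })

  loocv <- stage("loocv", {
    ct <- loocv_dfa(scores, priors = config$priors)
    readr::write_csv(tidy(ct),
                     file.path(config$out_dir, "classification_loocv.csv"),
                     progress = FALSE)
    ct
  })

  boot <- stage("bootstrap", {
    bs <- bootstrap_dfa(scores, priors = config$priors,
                        n_boot = config$n_boot, seed = config$seed)
    readr::write_csv(tidy(bs), file.path(config$out_dir, "bootstrap.csv"),
                     progress = FALSE)
    bs
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("actiphase")),
    r_version = R.version.string,
    config = config[setdiff(names(config), "out_dir")],
    seed = config$seed,
    n_subjects = nrow(cohort$subjects),
    segment_failures = as.data.frame(attr(segments, "failures")),
    feature_exclusions = as.data.frame(exclusion_report(features)),
    manova = as.list(screen),
    apparent_accuracy = apparent$overall_accuracy,
    loocv_accuracy = loocv$overall_accuracy,
    stage_seconds = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  invisible(list(cohort = cohort, segments = segments, features = features,
                 scores = scores, manova = screen, fit = fit,
                 apparent = apparent, loocv = loocv, boot = boot,
                 manifest = manifest))
}
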