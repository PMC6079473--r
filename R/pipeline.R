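#' Run the full anthropometric-risk / metabolic-syndrome analysis pipeline
#'
#' Executes every stage in order on one cohort: anthropometric indices,
#' age/sex reference standardization, penalized-spline hazard-curve
#' estimation on the training subsample, ARI evaluation for all subjects,
#' ATP III metabolic-syndrome scoring, the ten-model Cox comparison on the
#' evaluation subsample, and the component correlation matrix.
#'
#' The hazard curves are always fitted on the disjoint training subsample
#' (`training == 1`) and applied to the evaluation subsample
#' (`training == 0`), emulating the design in which curves come from
#' subjects without fasting laboratory data while the MS models are fitted
#' on the fasted (morning) subsample.
#'
#' @param cohort A cohort tibble (e.g. from [read_cohort()] or
#'   [generate_cohort()]); must carry a 0/1 training-flag column.
#' @param models Roster names to fit (default all ten; see
#'   [model_roster()]).
#' @param weights_col Sampling-weight column for the model comparison, or
#'   `NULL` for unweighted.
#' @param training_col Name of the 0/1 training-subsample flag.
#' @param age_bin_width,min_cell_n Reference-table stratification (see
#'   [build_reference()]).
#' @param spline_df Degrees of freedom of the penalized splines.
#' @param weighted_curves Survey-weight the hazard-curve fits (default
#'   `FALSE`).
#' @param outdir If non-`NULL`, write the report bundle there:
#'   `cohort.csv`, `reference.csv`, `curve_<index>.csv` (+ JSON sidecars),
#'   `model_comparison.csv`, `hazard_ratios.csv`, `correlations.csv` and a
#'   `run_log.json` with seed, configuration hash and software versions.
#' @param seed Recorded in the run log (the pipeline itself is
#'   deterministic given its input cohort).
#' @return An `ari_pipeline` list: `cohort` (all derived columns),
#'   `reference`, `curves`, `fits`, `comparison` (AIC/R^2/concordance
#'   table), `hazard_ratios`, `correlations`, `meta`.
#' @export
run_ari_pipeline <- function(cohort, models = names(model_roster()),
                             weights_col = "sample_weight",
                             training_col = "training",
                             age_bin_width = 5, min_cell_n = 25,
                             spline_df = 4, weighted_curves = FALSE,
                             outdir = NULL, seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage \"", name, "\" failed: ", conditionMessage(e)))
    })
  }
  if (!training_col %in% names(cohort)) {
    abort(paste0(
      "no training-subsample flag: add a 0/1 column \"", training_col,
      "\" (1 = curve-fitting subsample, 0 = evaluation subsample), ",
      "or point training_col at it"
    ))
  }
  cohort <- as_tibble(cohort)
  training <- cohort[[training_col]] == 1

  cohort <- stage("indices", add_anthro_indices(cohort))
  reference <- stage("reference", build_reference(
    cohort, age_bin_width = age_bin_width, min_cell_n = min_cell_n
  ))
  cohort <- stage("zscore", add_zscores(cohort, reference))
  curves <- stage("curves", fit_hazard_curves(
    cohort[training, ], df = spline_df, weighted = weighted_curves
  ))
  cohort <- stage("ari", add_ari(cohort, curves))
  cohort <- stage("ms", score_ms(cohort))

  eval_cohort <- cohort[!training, ]
  eval_cohort <- eval_cohort[complete.cases(
    eval_cohort[c("ari", "ms_score", "followup_years", "died")]
  ), ]
  fits <- stage("compare", fit_model_roster(
    eval_cohort, models = models, weights_col = weights_col
  ))
  comparison <- aic_compare(fits)
  hazard_ratios <- tidy(fits)
  correlations <- stage("correlate", correlation_table(eval_cohort))

  meta <- list(
    seed = seed,
    schema_version = COHORT_SCHEMA_VERSION,
    config_hash = rlang::hash(list(models, weights_col, training_col,
                                   age_bin_width, min_cell_n, spline_df,
                                   weighted_curves)),
    package_version = as.character(packageVersion("anthrorisk")),
    r_version = R.version.string,
    n_training = sum(training),
    n_evaluation = nrow(eval_cohort)
  )

  out <- structure(
    list(cohort = cohort, reference = reference, curves = curves,
         fits = fits, comparison = comparison, hazard_ratios = hazard_ratios,
         correlations = correlations, meta = meta),
    class = "ari_pipeline"
  )
  if (!is.null(outdir)) write_pipeline_bundle(out, outdir)
  out
}

#' @export
print.ari_pipeline <- function(x, ...) {
  cat(sprintf("<ari_pipeline> %d subjects (%d training, %d evaluation), %d models\n",
              nrow(x$cohort), x$meta$n_training, x$meta$n_evaluation,
              length(x$fits)))
  print(x$comparison)
  invisible(x)
}

#' Write the pipeline report bundle to a directory
#'
#' @param pipeline An `ari_pipeline` result.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_bundle <- function(pipeline, outdir) {
  stopifnot(inherits(pipeline, "ari_pipeline"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_cohort(pipeline$cohort, p("cohort.csv"))
  write_reference(pipeline$reference, p("reference.csv"))
  for (ix in names(pipeline$curves)) {
    write_hazard_curve(pipeline$curves[[ix]], p(paste0("curve_", ix, ".csv")))
  }
  readr::write_csv(pipeline$comparison, p("model_comparison.csv"))
  readr::write_csv(pipeline$hazard_ratios, p("hazard_ratios.csv"))
  write_correlation_csv(pipeline$correlations, p("correlations.csv"))
  jsonlite::write_json(pipeline$meta, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(outdir)
}
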