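#' The roster of mortality-prediction models
#'
#' Named list of predictor sets for the compared Cox models. Every model
#' additionally includes sex and black race as covariates, and age enters
#' implicitly as the timescale of the Cox model. `MSx` denotes the MS score
#' or components excluding Waist, the variant used alongside ARI (whose BMI
#' and ABSI inputs already carry the waist information).
#'
#' @return Named list mapping model name to a character vector of predictor
#'   columns (beyond sex and race).
#' @export
model_roster <- function() {
  comps <- c("ms_waist", "ms_bp", "ms_tg", "ms_hdl", "ms_glu")
  list(
    "Base" = character(0),
    "ARI" = "ari",
    "MS" = "ms",
    "MS score" = "ms_score",
    "ARI + MS" = c("ari", "ms"),
    "ARI + MS score" = c("ari", "ms_score"),
    "ARI + MSx score" = c("ari", "msx_score"),
    "MS components" = comps,
    "ARI + MS components" = c("ari", comps),
    "ARI + MSx components" = c("ari", setdiff(comps, "ms_waist"))
  )
}

cohort_surv_frame <- function(data, weights_col) {
  needed <- c("age", "followup_years", "died", "sex", "race_black")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  w <- if (is.null(weights_col)) rep(1, nrow(data)) else {
    if (!weights_col %in% names(data)) {
      abort(sprintf("weights column %s not found", weights_col))
    }
    data[[weights_col]]
  }
  # normalize weights to sum to n so the weighted partial-likelihood AIC is
  # on the same scale as an unweighted fit
  w <- w * nrow(data) / sum(w)
  fd <- as_tibble(data)
  fd$.entry <- fd$age
  fd$.exit <- fd$age + fd$followup_years
  fd$.w <- w
  fd
}

#' Fit one survey-weighted Cox mortality model
#'
#' Cox proportional-hazards fit with attained age as the timescale (entry at
#' baseline age, exit at age of death or censoring), Efron tie handling,
#' case weights normalized to sum to the sample size, and robust (sandwich)
#' variance for the confidence intervals. Sex and black race are always
#' included as covariates.
#'
#' @param data Evaluation cohort: columns `age`, `followup_years`, `died`,
#'   `sex`, `race_black`, plus every predictor in `predictors`.
#' @param predictors Character vector of additional predictor columns
#'   (possibly empty, giving the Base model).
#' @param name Model label.
#' @param weights_col Column holding sampling weights, or `NULL` for
#'   unweighted.
#' @param min_events Minimum number of deaths required (default 50).
#' @return An `ari_cox_fit`: the `coxph` fit plus log-likelihood, AIC,
#'   explained variation R^2 and concordance C. Use [generics::tidy()] for
#'   hazard ratios and [generics::glance()] for the performance row.
#' @seealso [fit_model_roster()], [aic_compare()]
#' @export
fit_cox <- function(data, predictors = character(0), name = "model",
                    weights_col = "sample_weight", min_events = 50) {
  if (anyDuplicated(predictors)) {
    dup <- unique(predictors[duplicated(predictors)])
    abort(paste0("collinear predictors: duplicated term(s) ", paste(dup, collapse = ", ")),
          class = "anthrorisk_collinear")
  }
  fd <- cohort_surv_frame(data, weights_col)
  missing_pred <- setdiff(predictors, names(fd))
  if (length(missing_pred) > 0) {
    abort(paste0("predictor column(s) absent: ", paste(missing_pred, collapse = ", ")))
  }
  if (sum(fd$died) < min_events) {
    abort(sprintf("too few events to fit: %d < %d", sum(fd$died), min_events),
          class = "anthrorisk_too_few_events")
  }
  terms_rhs <- c("sex", "race_black", predictors)
  fml <- stats::as.formula(
    paste("Surv(.entry, .exit, died) ~", paste(terms_rhs, collapse = " + "))
  )
  fit <- tryCatch(
    coxph(fml, data = fd, weights = fd$.w, cluster = seq_len(nrow(fd)),
          ties = "efron"),
    error = function(e) abort(paste0("Cox fit failed for model \"", name, "\": ",
                                     conditionMessage(e)),
                              class = "anthrorisk_fit_error")
  )
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("collinear predictors in model \"", name, "\": ",
                 paste(bad, collapse = ", "), " aliased"),
          class = "anthrorisk_collinear")
  }
  ll <- fit$loglik[2]
  df <- length(coef(fit))
  cfit <- concordance(fit)
  structure(
    list(
      name = name,
      predictors = predictors,
      fit = fit,
      n = nrow(fd),
      n_events = sum(fd$died),
      sum_w = sum(fd$.w),
      loglik = ll,
      df = df,
      aic = -2 * ll + 2 * df,
      r2 = royston_r2(fd, fit),
      concordance = as.numeric(cfit$concordance)
    ),
    class = "ari_cox_fit"
  )
}

# Royston & Sauerbrei explained variation on the log-hazard scale:
# rank the linear predictor, map ranks to expected normal order statistics
# (Blom), scale by kappa = sqrt(8/pi), refit Cox on that regressor; the
# coefficient is the prognostic separation D and
# R^2_D = (D^2/kappa^2) / (pi^2/6 + D^2/kappa^2).
royston_r2 <- function(fd, fit) {
  lp <- as.numeric(predict(fit, type = "lp"))
  if (length(unique(lp)) < 2 || sd(lp) < 1e-12) return(0)
  n <- length(lp)
  kappa <- sqrt(8 / pi)
  rankit <- qnorm((rank(lp, ties.method = "average") - 0.375) / (n + 0.25))
  fd$.rankit_scaled <- rankit / kappa
  aux <- coxph(Surv(.entry, .exit, died) ~ .rankit_scaled, data = fd,
               weights = fd$.w, ties = "efron")
  D <- as.numeric(coef(aux))
  if (!is.finite(D)) return(0)
  (D^2 / kappa^2) / (pi^2 / 6 + D^2 / kappa^2)
}

#' @export
print.ari_cox_fit <- function(x, ...) {
  cat(sprintf("<ari_cox_fit \"%s\"> n=%d, deaths=%d, AIC=%.1f, R2=%.4f, C=%.3f\n",
              x$name, x$n, x$n_events, x$aic, x$r2, x$concordance))
  invisible(x)
}

#' Fit the whole model roster on one cohort
#'
#' @param data Evaluation cohort (see [fit_cox()]) carrying `ari` and the MS
#'   scoring columns as needed by the selected models.
#' @param models Character vector of roster names (default: all ten).
#' @param weights_col,min_events Passed to [fit_cox()].
#' @return An `ari_model_set`: named list of `ari_cox_fit` objects.
#' @export
fit_model_roster <- function(data, models = names(model_roster()),
                             weights_col = "sample_weight", min_events = 50) {
  roster <- model_roster()
  unknown <- setdiff(models, names(roster))
  if (length(unknown) > 0) {
    abort(paste0("unknown model name(s): ", paste(unknown, collapse = ", "),
                 "; see model_roster()"))
  }
  fits <- lapply(models, function(m) {
    fit_cox(data, roster[[m]], name = m, weights_col = weights_col,
            min_events = min_events)
  })
  structure(setNames(fits, models), class = "ari_model_set")
}

#' Compare fitted models by AIC differences
#'
#' Assigns each model its AIC difference `delta_i` from the minimum across
#' the set. `delta_i = 0` marks the best-performing model; models with
#' `delta_i > 6` are flagged as predicting significantly worse for the
#' sampled population, and models within 6 of the best are statistically
#' tied with it.
#'
#' @param fits An `ari_model_set` or list of `ari_cox_fit` objects fitted on
#'   the identical cohort and weighting.
#' @return A tibble, one row per model, ordered by `delta_i` (name breaks
#'   ties): `model`, `loglik`, `df`, `aic`, `delta_i`, `r2`, `concordance`,
#'   `significantly_worse`, `tied_with_best`.
#' @export
aic_compare <- function(fits) {
  if (inherits(fits, "ari_cox_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "ari_cox_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  ev <- vapply(fits, `[[`, numeric(1), "n_events")
  sw <- vapply(fits, `[[`, numeric(1), "sum_w")
  if (length(unique(ns)) > 1 || length(unique(ev)) > 1 ||
      diff(range(sw)) > 1e-8 * max(sw)) {
    abort("models were fitted on different cohorts or weightings; AIC differences are not comparable")
  }
  out <- tibble(
    model = vapply(fits, `[[`, character(1), "name"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    df = vapply(fits, `[[`, numeric(1), "df"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    concordance = vapply(fits, `[[`, numeric(1), "concordance")
  ) |>
    mutate(
      delta_i = aic - min(aic),
      significantly_worse = delta_i > 6,
      tied_with_best = delta_i <= 6
    ) |>
    arrange(delta_i, model)
  out
}

#' Harrell-type concordance of an arbitrary risk score
#'
#' Fraction of comparable subject pairs (under the age timescale, i.e.
#' overlapping at-risk age intervals) in which the member with the higher
#' risk score dies sooner; ties in score or age count 1/2, so a constant or
#' random score scores 0.5.
#'
#' @param data Cohort with `age`, `followup_years`, `died`.
#' @param risk Numeric risk score (higher = predicted to die sooner), or the
#'   name of a column of `data`.
#' @param weights_col Optional weights column name.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(data, risk, weights_col = NULL) {
  fd <- cohort_surv_frame(
    mutate(as_tibble(data),
           sex = if ("sex" %in% names(data)) sex else "male",
           race_black = if ("race_black" %in% names(data)) race_black else 0L),
    weights_col
  )
  r <- if (is.character(risk) && length(risk) == 1) fd[[risk]] else risk
  stopifnot(length(r) == nrow(fd))
  fd$.risk <- r
  cf <- concordance(Surv(.entry, .exit, died) ~ .risk, data = fd,
                    weights = fd$.w, reverse = TRUE)
  npairs <- sum(cf$count[c("concordant", "discordant", "tied.x")])
  if (npairs == 0) abort("no comparable pairs for concordance")
  as.numeric(cf$concordance)
}

#' Correlation matrix of risk components
#'
#' Pearson correlations on complete cases among per-subject quantities; for
#' 0/1 columns this yields point-biserial/phi coefficients automatically.
#' Zero-variance columns are kept but their correlations reported as `NA`
#' with a warning.
#'
#' @param data Cohort carrying the requested columns.
#' @param vars Columns to correlate; defaults to the index log hazards, ARI,
#'   the five MS components, MS score and MS.
#' @return A symmetric correlation matrix (class `cor_table`); see
#'   [tidy.cor_table()] and [write_correlation_csv()].
#' @export
correlation_table <- function(data, vars = c("hH", "hBMI", "hABSI", "hHI", "ari",
                                             "ms_waist", "ms_bp", "ms_tg", "ms_hdl",
                                             "ms_glu", "ms_score", "ms")) {
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("correlation table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(as_tibble(data)[vars])
  storage.mode(m) <- "double"
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) abort("fewer than 3 complete cases for correlations")
  sds <- apply(m, 2, sd)
  degenerate <- sds == 0
  if (any(degenerate)) {
    warn(paste0("zero-variance column(s), correlations undefined: ",
                paste(vars[degenerate], collapse = ", ")))
  }
  out <- suppressWarnings(cor(m))
  diag(out) <- 1
  out[degenerate, ] <- NA_real_
  out[, degenerate] <- NA_real_
  diag(out)[degenerate] <- NA_real_
  class(out) <- c("cor_table", class(out))
  attr(out, "n") <- nrow(m)
  out
}

#' Write a correlation table to CSV
#'
#' Fixed schema: first column `variable`, then one column per variable.
#'
#' @param tab A `cor_table` from [correlation_table()].
#' @param path File path.
#' @export
write_correlation_csv <- function(tab, path) {
  df <- as_tibble(unclass(tab)[seq_len(nrow(tab)), , drop = FALSE])
  df <- bind_cols(tibble(variable = rownames(tab)), df)
  readr::write_csv(df, path)
  invisible(path)
}
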