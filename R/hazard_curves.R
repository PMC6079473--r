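HAZARD_GRID <- seq(-4, 4, by = 0.01)

#' Fit a per-index log mortality-hazard curve
#'
#' Estimates the natural logarithm of the mortality hazard as a smooth
#' function of one anthropometric-index Z score, by penalized-spline Cox
#' proportional-hazards regression with attained age as the timescale
#' (delayed entry at baseline age, exit at age of death or censoring).
#'
#' The fitted curve is tabulated on a dense grid over z in [-4, 4] and
#' centered so that the (optionally weighted) mean of `exp(curve(z))` over
#' the training sample equals 1: a curve value of 0 then denotes the
#' population-average hazard, which is what makes the summed ARI
#' interpretable as a log hazard relative to the population mean.
#'
#' @param data Training records with columns `age` (baseline age, years),
#'   `followup_years`, `died` (0/1), and the Z-score column `z_col`.
#' @param z_col Name of the Z-score column (e.g. `"zBMI"`).
#' @param index Label for the index the curve describes; defaults to
#'   `z_col` without its `z` prefix.
#' @param df Target degrees of freedom of the penalized spline (default 4);
#'   `df = 0` lets the fitter choose by its corrected-AIC criterion.
#' @param weighted Use `sample_weight` as case weights (default `FALSE`;
#'   the training subsample is treated as an internal reference).
#' @param min_events Minimum number of deaths required (default 50).
#'
#' @return An object of class `hazard_curve`: the centered log-hazard grid
#'   plus training summary (`n`, `n_events`), centering offset, and spline
#'   degrees of freedom.
#' @seealso [evaluate_hazard()], [add_ari()], [write_hazard_curve()]
#' @export
fit_hazard_curve <- function(data, z_col, index = sub("^z", "", z_col),
                             df = 4, weighted = FALSE, min_events = 50) {
  needed <- c("age", "followup_years", "died", z_col)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("training data lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  z <- data[[z_col]]
  if (any(!is.finite(z))) abort(sprintf("non-finite Z scores in %s", z_col))
  n_events <- sum(data$died)
  if (n_events < min_events) {
    abort(sprintf("too few events to fit a hazard curve: %d < %d", n_events, min_events),
          class = "anthrorisk_too_few_events")
  }
  w <- if (weighted) data$sample_weight else NULL
  fd <- tibble(
    entry = data$age, exit = data$age + data$followup_years,
    died = data$died, z = z
  )
  fit <- tryCatch(
    coxph(Surv(entry, exit, died) ~ pspline(z, df = df), data = fd,
          weights = w, ties = "efron"),
    error = function(e) abort(paste0("hazard-curve fit failed: ", conditionMessage(e)),
                              class = "anthrorisk_fit_error")
  )
  grid <- HAZARD_GRID
  raw <- as.numeric(predict(
    fit,
    newdata = tibble(z = grid, entry = 50, exit = 51, died = 0),
    type = "terms"
  ))
  # center so the training-sample weighted mean relative hazard is exactly 1
  # under the grid evaluator itself
  interp <- splinefun(grid, raw, method = "natural")
  z_tr <- pmin(pmax(z, min(grid)), max(grid))
  ww <- if (is.null(w)) rep(1, length(z_tr)) else w
  offset <- log(weighted.mean(exp(interp(z_tr)), ww))
  structure(
    list(
      index = index,
      grid_z = grid,
      log_hazard = raw - offset,
      offset = offset,
      n = nrow(fd),
      n_events = n_events,
      df = df,
      weighted = weighted
    ),
    class = "hazard_curve"
  )
}

#' Fit all four index hazard curves on a training sample
#'
#' Convenience wrapper running [fit_hazard_curve()] for the Z scores of
#' height, BMI, ABSI and hip index.
#'
#' @inheritParams fit_hazard_curve
#' @param indices Which indices to fit (default all four).
#' @return Named list of `hazard_curve` objects (`H`, `BMI`, `ABSI`, `HI`).
#' @export
fit_hazard_curves <- function(data, indices = c("H", "BMI", "ABSI", "HI"),
                              df = 4, weighted = FALSE, min_events = 50) {
  out <- lapply(indices, function(ix) {
    fit_hazard_curve(data, paste0("z", ix), index = ix, df = df,
                     weighted = weighted, min_events = min_events)
  })
  setNames(out, indices)
}

#' Evaluate a hazard curve at Z scores
#'
#' Returns the centered log hazard ratio for the given Z scores. Values
#' outside the curve's tabulated range ([-4, 4]) are clamped to the
#' boundary with a warning rather than extrapolated.
#'
#' @param curve A `hazard_curve`.
#' @param z Numeric vector of Z scores.
#' @return Numeric vector of log hazard ratios.
#' @export
evaluate_hazard <- function(curve, z) {
  stopifnot(inherits(curve, "hazard_curve"))
  lo <- min(curve$grid_z); hi <- max(curve$grid_z)
  if (any(z < lo | z > hi, na.rm = TRUE)) {
    warn(sprintf("Z scores outside [%g, %g] clamped to the curve boundary for index %s",
                 lo, hi, curve$index))
    z <- pmin(pmax(z, lo), hi)
  }
  splinefun(curve$grid_z, curve$log_hazard, method = "natural")(z)
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat(sprintf(
    "<hazard_curve %s> pspline Cox log-hazard vs Z (df %s), %d subjects, %d deaths\n",
    x$index, format(x$df), x$n, x$n_events
  ))
  cat(sprintf("  range over z in [-4, 4]: [%.3f, %.3f]; centering offset %.4f\n",
              min(x$log_hazard), max(x$log_hazard), x$offset))
  invisible(x)
}

#' Add ARI components and the anthropometric risk index
#'
#' Evaluates the four centered hazard curves at each subject's Z scores,
#' giving per-index log hazard ratios `hH`, `hBMI`, `hABSI`, `hHI`; their
#' sum is the anthropometric risk index `ari`, and `exp(ari)`
#' (`relative_hazard`) is the estimated mortality hazard as a fraction of
#' the population-average hazard. `ari = 0` denotes population-average risk.
#'
#' @param data Cohort with Z-score columns `zH`, `zBMI`, `zABSI`, `zHI`
#'   (see [add_zscores()]).
#' @param curves Named list with elements `H`, `BMI`, `ABSI`, `HI`, each a
#'   [fit_hazard_curve()] result.
#' @return `data` with columns `hH`, `hBMI`, `hABSI`, `hHI`, `ari`,
#'   `relative_hazard` appended.
#' @export
add_ari <- function(data, curves) {
  need <- c("H", "BMI", "ABSI", "HI")
  missing_curves <- setdiff(need, names(curves))
  if (length(missing_curves) > 0) {
    abort(paste0("missing hazard curve(s) for: ", paste(missing_curves, collapse = ", ")))
  }
  out <- as_tibble(data)
  for (ix in need) {
    out[[paste0("h", ix)]] <- evaluate_hazard(curves[[ix]], out[[paste0("z", ix)]])
  }
  out$ari <- out$hH + out$hBMI + out$hABSI + out$hHI
  out$relative_hazard <- exp(out$ari)
  out
}

#' Serialize a hazard curve to a CSV grid with a JSON sidecar
#'
#' The CSV holds the dense grid (`z` from -4 to 4 in steps of 0.01 and the
#' centered `log_hazard`), the convention used by online ARI calculators; a
#' `<path>.json` sidecar stores metadata (index, centering offset, training
#' n and events, spline df).
#'
#' @param curve A `hazard_curve`.
#' @param path CSV file path.
#' @return [read_hazard_curve()] returns a `hazard_curve`;
#'   [write_hazard_curve()] returns `path` invisibly.
#' @export
write_hazard_curve <- function(curve, path) {
  stopifnot(inherits(curve, "hazard_curve"))
  readr::write_csv(tibble(z = curve$grid_z, log_hazard = curve$log_hazard), path)
  meta <- curve[c("index", "offset", "n", "n_events", "df", "weighted")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hazard_curve
#' @export
read_hazard_curve <- function(path) {
  grid <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(
      index = meta$index, grid_z = grid$z, log_hazard = grid$log_hazard,
      offset = meta$offset, n = meta$n, n_events = meta$n_events,
      df = meta$df, weighted = isTRUE(meta$weighted)
    ),
    class = "hazard_curve"
  )
}
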