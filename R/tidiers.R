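#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted mortality model
#'
#' One row per predictor with the hazard ratio and its robust Wald 95%
#' confidence interval.
#'
#' @param x An `ari_cox_fit` from [fit_cox()].
#' @param conf_level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Tibble: `model`, `term`, `estimate` (log HR), `std.error`
#'   (robust), `hazard_ratio`, `conf.low`, `conf.high` (HR scale),
#'   `p.value`.
#' @export
tidy.ari_cox_fit <- function(x, conf_level = 0.95, ...) {
  beta <- coef(x$fit)
  se <- sqrt(diag(x$fit$var))
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    model = x$name,
    term = names(beta),
    estimate = unname(beta),
    std.error = se,
    hazard_ratio = exp(unname(beta)),
    conf.low = exp(unname(beta) - q * se),
    conf.high = exp(unname(beta) + q * se),
    p.value = 2 * pnorm(-abs(unname(beta) / se))
  )
}

#' @rdname tidy.ari_cox_fit
#' @export
glance.ari_cox_fit <- function(x, ...) {
  tibble(
    model = x$name, n = x$n, n_events = x$n_events,
    loglik = x$loglik, df = x$df, aic = x$aic,
    r2 = x$r2, concordance = x$concordance
  )
}

#' Tidy/glance a fitted model set
#'
#' @param x An `ari_model_set` from [fit_model_roster()].
#' @param ... Passed to the per-fit method.
#' @return [tidy()]: stacked per-predictor hazard ratios. [glance()]: the
#'   [aic_compare()] table.
#' @export
tidy.ari_model_set <- function(x, ...) {
  list_rbind(lapply(unclass(x), tidy, ...))
}

#' @rdname tidy.ari_model_set
#' @export
glance.ari_model_set <- function(x, ...) {
  aic_compare(x)
}

#' Tidy a correlation table to long form
#'
#' @param x A `cor_table` from [correlation_table()].
#' @param upper_only Keep only the upper triangle (default `TRUE`).
#' @param ... Unused.
#' @return Tibble with `row_var`, `col_var`, `r`.
#' @export
tidy.cor_table <- function(x, upper_only = TRUE, ...) {
  m <- unclass(x)
  df <- expand.grid(row_var = rownames(m), col_var = colnames(m),
                    stringsAsFactors = FALSE)
  df$r <- as.vector(m)
  out <- as_tibble(df)
  if (upper_only) {
    ri <- match(out$row_var, rownames(m))
    ci <- match(out$col_var, colnames(m))
    out <- out[ri < ci, ]
  }
  out
}
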