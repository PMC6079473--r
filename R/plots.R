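#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_point
#'   geom_errorbarh geom_histogram labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a fitted log-hazard curve
#'
#' @param object A `hazard_curve`.
#' @param ... Unused.
#' @return A ggplot: centered log hazard ratio against the index Z score.
#' @export
autoplot.hazard_curve <- function(object, ...) {
  df <- tibble(z = object$grid_z, log_hazard = object$log_hazard)
  ggplot(df, aes(z, log_hazard)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_line(linewidth = 0.8) +
    labs(
      x = sprintf("%s Z score (age/sex standardized)", object$index),
      y = "log hazard ratio",
      title = sprintf("Mortality log-hazard curve: %s", object$index),
      subtitle = sprintf("penalized-spline Cox fit, %d subjects, %d deaths",
                         object$n, object$n_events)
    ) +
    theme_minimal()
}

#' Plot the AIC model comparison
#'
#' Dot plot of AIC differences for a fitted model set; the dashed line marks
#' the significance threshold (models beyond it predict significantly worse
#' than the best model).
#'
#' @param object An `ari_model_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ari_model_set <- function(object, ...) {
  cmp <- aic_compare(object)
  cmp$model <- factor(cmp$model, levels = rev(cmp$model))
  ggplot(cmp, aes(delta_i, model)) +
    ggplot2::geom_vline(xintercept = 6, linetype = "dashed", colour = "grey50") +
    geom_point(size = 2) +
    labs(x = expression(Delta[i] ~ "(AIC difference from best model)"),
         y = NULL, title = "Mortality model comparison") +
    theme_minimal()
}

#' Histogram of the anthropometric risk index
#'
#' @param data Cohort with an `ari` column (see [add_ari()]).
#' @param bins Number of histogram bins.
#' @return A ggplot.
#' @export
plot_ari_distribution <- function(data, bins = 60) {
  ggplot(as_tibble(data), aes(ari)) +
    geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    geom_hline(yintercept = 0) +
    labs(x = "ARI (log hazard relative to population average)",
         y = "subjects",
         title = "Distribution of the anthropometric risk index") +
    theme_minimal()
}

#' Forest plot of hazard ratios for one or more fitted models
#'
#' @param fits An `ari_cox_fit` or `ari_model_set`.
#' @return A ggplot with hazard ratios and 95% CIs on a log scale.
#' @export
plot_hazard_ratios <- function(fits) {
  td <- if (inherits(fits, "ari_model_set")) tidy(fits) else tidy(fits)
  ggplot(td, aes(hazard_ratio, term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = conf.low, xmax = conf.high), height = 0.2) +
    geom_point(size = 1.8) +
    ggplot2::scale_x_log10() +
    facet_wrap(~model, scales = "free_y") +
    labs(x = "hazard ratio (95% CI, log scale)", y = NULL) +
    theme_minimal()
}
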