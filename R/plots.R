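# ggplot2 displays of fitted quantities.

#' Plot resistance estimates
#'
#' Posterior means and 95% credible intervals of prevalence or infection
#' intensity per phenotype.
#'
#' @param object A `resistance_fit`.
#' @param type `"prevalence"` or `"intensity"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot resistance_fit
#' @export
autoplot.resistance_fit <- function(object, type = c("prevalence", "intensity"),
                                    ...) {
  type <- match.arg(type)
  est <- if (type == "prevalence") {
    prevalence_estimates(object)
  } else {
    intensity_estimates(object)
  }
  est$phenotype <- factor(est$phenotype, levels = phenotype_levels())
  ggplot2::ggplot(est, ggplot2::aes(x = .data$phenotype, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(
      x = "Phenotype",
      y = if (type == "prevalence") "Prevalence (P(mites > 0))"
          else "Infection intensity (mites | infected)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot fecundity reaction norms
#'
#' Fitted fecundity against mite load per morph with 95% credible bands
#' (fitted-mean bands).
#'
#' @param object A `tolerance_fit`.
#' @param mite_grid Grid of mite loads (default 0..56).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot tolerance_fit
#' @export
autoplot.tolerance_fit <- function(object, mite_grid = 0:56, ...) {
  pred <- predict_fecundity(object, mite_grid = mite_grid)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$mites, y = .data$mean,
                                     colour = .data$morph, fill = .data$morph)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Water-mite load", y = "Fitted 72-h fecundity (eggs)",
                  colour = "Morph", fill = "Morph") +
    ggplot2::theme_minimal()
}

#' Plot virulence posteriors
#'
#' Kernel density of the resampled virulence draws per morph.
#'
#' @param object A `virulence_draws` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot virulence_draws
#' @export
autoplot.virulence_draws <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$virulence,
                                       fill = .data$morph,
                                       colour = .data$morph)) +
    ggplot2::geom_density(alpha = 0.3) +
    ggplot2::labs(x = "Virulence (proportional fecundity reduction)",
                  y = "Posterior density", fill = "Morph", colour = "Morph") +
    ggplot2::theme_minimal()
}
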