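#' Plot a niche surface
#'
#' Raster of predicted occurrence probability over the (RTH, redox) plane,
#' with unavailable (hull-clipped) cells blanked; lighter shading marks more
#' suitable conditions.
#'
#' @param object A [niche_surface()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.niche_surface <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       .pred = ifelse(.data$available, .data$.pred, NA_real_))
  ggplot2::ggplot(dat, ggplot2::aes(.data$rth, .data$redox,
                                    fill = .data$.pred)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "P(occurrence)") +
    ggplot2::labs(x = "Relative tidal height",
                  y = "Redox potential (mV vs SHE)",
                  title = attr(object, "species")) +
    ggplot2::theme_minimal()
}

#' Plot observed versus model-expected tidal position
#'
#' Filled points show the mean RTH of occupied quadrats per marsh age class
#' (grey band: interquartile range); open points the model-expected mean if
#' the species occupied the most suitable quadrats, with 95% interval bars.
#'
#' @param object A [tidal_position_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tidal_position <- function(object, ...) {
  dat <- dplyr::filter(object, .data$defined)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$age_class)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$observed_q25,
                                         ymax = .data$observed_q75),
                            linewidth = 4, colour = "grey80") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_mean_rth), size = 3) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$expected_ci_lo,
                                        ymax = .data$expected_ci_hi),
                           width = 0.15) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected_mean_rth),
                        shape = 21, fill = "white", size = 3) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "Marsh age class", y = "Relative tidal height") +
    ggplot2::theme_minimal()
}

#' Plot transfer predictions or age effects across marsh age classes
#'
#' Point-interval display of per-class occurrence probability summaries:
#' medians with 95% intervals for transfer predictions, posterior modes with
#' 95% credible intervals for age effects.
#'
#' @param data Tibble from [predict_transfer()] (rows bound across classes)
#'   or [age_effect_at_optimum()].
#' @param value Column holding the point summary (`"median"` or `"mode"`).
#' @return A ggplot.
#' @export
plot_occurrence_by_age <- function(data, value = c("median", "mode")) {
  value <- match.arg(value)
  ggplot2::ggplot(data, ggplot2::aes(x = factor(.data$age_class,
                                                levels = marsh_age_classes),
                                     y = .data[[value]])) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.15) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "Marsh age class", y = "Occurrence probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
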