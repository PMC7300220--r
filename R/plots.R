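#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_hline facet_wrap labs theme_bw
NULL

#' @export
ggplot2::autoplot

#' Plot a prediction-corrected VPC
#'
#' Observed prediction-corrected percentiles (points/lines) over the
#' simulated 2.5th-97.5th percentile band per time bin.
#'
#' @param object A `pk_vpc` from [vpc_pk()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pk_vpc <- function(object, ...) {
  b <- object$bins
  ggplot(b, aes(x = .data$time_mid)) +
    geom_ribbon(aes(ymin = .data$sim_p2.5, ymax = .data$sim_p97.5),
                fill = "steelblue", alpha = 0.25) +
    geom_line(aes(y = .data$sim_p50), colour = "steelblue") +
    geom_line(aes(y = .data$obs_p50)) +
    geom_point(aes(y = .data$obs_p50)) +
    geom_line(aes(y = .data$obs_p2.5), linetype = 2) +
    geom_line(aes(y = .data$obs_p97.5), linetype = 2) +
    labs(x = "Time (h)", y = "Prediction-corrected concentration (ng/ml)",
         title = "Prediction-corrected visual predictive check") +
    theme_bw()
}

#' Plot probability of target attainment across the dose grid
#'
#' One line per weight group, faceted by regimen, with the PTA on the
#' vertical axis.
#'
#' @param object A `pta_grid` tibble from [pta_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pta_grid <- function(object, ...) {
  ggplot(object, aes(x = .data$daily_dose, y = .data$pta,
                     colour = factor(.data$weight))) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(~.data$regimen) +
    labs(x = "Daily dose (mg/kg/day)", y = "P(trough in target window)",
         colour = "Weight (kg)",
         title = "Probability of target attainment") +
    theme_bw()
}

#' Per-kilogram clearance against body weight
#'
#' Visualises why heavier children need a smaller per-kg dose: typical
#' CL/F per kg declines with weight under allometric scaling.
#'
#' @param model A [pop_model()].
#' @param weights Body weights, kg.
#' @return A ggplot.
#' @export
plot_clearance_per_kg <- function(model, weights = seq(5, 60, by = 1)) {
  ggplot(clearance_per_kg(model, weights),
         aes(x = .data$weight, y = .data$cl_per_kg)) +
    geom_line() +
    labs(x = "Body weight (kg)", y = "Typical CL/F per kg (L/h/kg)",
         title = "Weight-normalised apparent clearance") +
    theme_bw()
}

#' Goodness-of-fit panels from residual diagnostics
#'
#' Observations vs predictions and weighted residuals vs time.
#'
#' @param diagnostics Tibble from [residual_diagnostics()].
#' @return A ggplot (faceted panels).
#' @export
plot_gof <- function(diagnostics) {
  long <- dplyr::bind_rows(
    dplyr::transmute(diagnostics, x = .data$pred, y = .data$dv,
                     panel = "Observed vs population prediction"),
    dplyr::transmute(diagnostics, x = .data$ipred, y = .data$dv,
                     panel = "Observed vs individual prediction"),
    dplyr::transmute(diagnostics, x = .data$ipred, y = abs(.data$iwres),
                     panel = "|IWRES| vs individual prediction"),
    dplyr::transmute(diagnostics, x = .data$time, y = .data$wres,
                     panel = "WRES vs time"))
  ggplot(long, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = 0, linetype = 3) +
    facet_wrap(~.data$panel, scales = "free") +
    labs(x = NULL, y = NULL) +
    theme_bw()
}
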