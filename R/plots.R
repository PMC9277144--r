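#' Plot a kinetic fit: observed rates, model curve and 95% band
#'
#' Observed segment-mean volumetric sulfate reduction rates against the
#' flow-to-volume ratio, one shape per cumulative segment, with the fitted
#' plug-flow rate curve and its two-sided 95% confidence band (dashed).
#'
#' @param object An `srk_fit` from [fit_kinetics()].
#' @param band_points Grid resolution for the curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srk_fit <- function(object, band_points = 100, ...) {
  pts <- object$data
  fv <- seq(min(pts$flow_per_volume), max(pts$flow_per_volume),
            length.out = band_points)
  curve <- if (!is.na(object$dof) && object$dof >= 1) {
    confidence_band(object, c0 = max(pts$c0), fv_grid = fv)
  } else {
    tibble::tibble(flow_per_volume = fv,
                   fit = mean_rate(max(pts$c0), object$k, object$n, fv),
                   lwr = NA_real_, upr = NA_real_)
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$flow_per_volume)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$fit)) +
    ggplot2::labs(
      x = expression(F / V ~ (h^{-1})),
      y = expression(VSRR ~ (mg ~ L^{-1} ~ h^{-1})),
      title = sprintf("Plug-flow rate-law fit: k = %.4g %s, n = %.3g",
                      object$k, object$k_units, object$n),
      shape = "segment"
    ) +
    ggplot2::theme_minimal()
  if (!all(is.na(curve$lwr))) {
    p <- p +
      ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$lwr),
                         linetype = "dashed") +
      ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$upr),
                         linetype = "dashed")
  }
  if ("label" %in% names(pts)) {
    p + ggplot2::geom_point(ggplot2::aes(y = .data$y, shape = .data$label),
                            size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(y = .data$y), size = 2)
  }
}

#' Plot observed vs predicted zone-outlet acetate
#'
#' One panel per zone: observed and ledger-predicted acetate leaving the
#' zone across the dilution-rate ladder.
#'
#' @param profile A tibble from [predict_acetate_profile()].
#' @return A ggplot object.
#' @export
plot_acetate_profile <- function(profile) {
  long <- tidyr::pivot_longer(
    dplyr::select(profile, "dilution_rate", "zone",
                  observed = "observed_mg_l", predicted = "predicted_mg_l"),
    cols = c("observed", "predicted"),
    names_to = "series", values_to = "acetate_mg_l"
  )
  long$zone <- factor(long$zone, levels = .ZONES)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dilution_rate,
                                     y = .data$acetate_mg_l,
                                     colour = .data$series,
                                     shape = .data$series)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$zone)) +
    ggplot2::labs(x = expression(dilution ~ rate ~ (h^{-1})),
                  y = "acetate leaving zone (mg/L)", colour = NULL,
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot zone-boundary sulfate profiles
#'
#' Residual sulfate at each zone boundary across the dilution ladder,
#' from an observation table (means) or a simulated profile.
#'
#' @param observations An observation tibble (see [load_observations()]).
#' @return A ggplot object.
#' @export
plot_sulfate_profile <- function(observations) {
  s <- dplyr::filter(observations, .data$analyte == "sulfate")
  s$zone_boundary <- factor(s$zone_boundary, levels = c("feed", .ZONES))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$dilution_rate,
                                  y = .data$mean_conc,
                                  colour = .data$zone_boundary)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded), size = 2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = expression(dilution ~ rate ~ (h^{-1})),
                  y = "residual sulfate (mg/L)",
                  colour = "boundary", shape = "excluded") +
    ggplot2::theme_minimal()
}
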