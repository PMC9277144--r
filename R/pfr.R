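#' Outlet concentration of an ideal plug-flow reactor
#'
#' Integrates the irreversible rate law \eqn{r = -k C^n} along an ideal
#' plug-flow reactor for a residence time `tau`, giving the closed-form
#' outlet concentration:
#' \deqn{C_A = C_0 e^{-k\tau} \quad (n = 1)}
#' \deqn{C_A = \left[C_0^{1-n} + (n-1) k \tau\right]^{1/(1-n)} \quad (n \ne 1)}
#' For `n < 1` the bracketed quantity can reach zero within the reactor;
#' the concentration is then clamped at 0 (complete conversion).
#'
#' Vectorised over `c0` and `residence_time`.
#'
#' @param c0 Inlet concentration (mg/L), >= 0.
#' @param k Rate constant, mg^(1-n) L^(n-1) h^-1 (h^-1 when `n = 1`); >= 0.
#' @param n Reaction order, > 0.
#' @param residence_time Hydraulic residence time tau = V/F (h), >= 0.
#' @return Outlet concentration(s), mg/L; non-increasing in `tau` and `k`.
#' @examples
#' pfr_outlet_concentration(1000, k = 0.06955, n = 1, residence_time = 24)
#' pfr_outlet_concentration(1000, k = 1.5e-7, n = 2.9, residence_time = 24)
#' @export
pfr_outlet_concentration <- function(c0, k, n, residence_time) {
  if (any(c0 < 0) || k < 0 || any(residence_time < 0)) {
    abort("c0, k and residence_time must all be >= 0",
          class = "sulfkin_domain_error")
  }
  if (n <= 0) abort("reaction order n must be > 0", class = "sulfkin_domain_error")
  if (n == 1) {
    return(c0 * exp(-k * residence_time))
  }
  # c0 = 0 stays 0 under any positive order
  out <- numeric(length(c0 + residence_time))
  c0 <- rep_len(c0, length(out))
  tau <- rep_len(residence_time, length(out))
  pos <- c0 > 0
  base <- c0[pos]^(1 - n) + (n - 1) * k * tau[pos]
  ca <- ifelse(base <= 0, 0, base^(1 / (1 - n)))
  out[pos] <- ca
  out
}

#' Modelled segment-mean volumetric rate at a given F/V
#'
#' The mean volumetric reaction rate over a plug-flow segment operated at a
#' flow-to-volume ratio `F/V`:
#' \eqn{r = (F/V) (C_0 - C_A(\tau = V/F))}. This is the model curve fitted to
#' the observed zone-mean rates; it tends to 0 as `k -> 0` and to
#' `(F/V) C_0` (complete conversion) as `k -> Inf`.
#'
#' @inheritParams pfr_outlet_concentration
#' @param flow_per_volume F/V for the segment (1/h), > 0. Vectorised.
#' @return Mean rate(s), mg L^-1 h^-1.
#' @examples
#' mean_rate(1000, k = 0.06955, n = 1, flow_per_volume = 1 / 24)
#' @export
mean_rate <- function(c0, k, n, flow_per_volume) {
  if (any(flow_per_volume <= 0)) {
    abort("flow_per_volume must be > 0", class = "sulfkin_domain_error")
  }
  flow_per_volume *
    (c0 - pfr_outlet_concentration(c0, k, n, 1 / flow_per_volume))
}

#' Build cumulative-volume rate points from observations
#'
#' Converts zone-outlet sulfate observations into the (F/V, C0, CA, rate)
#' tuples the kinetic fit consumes. For each non-excluded steady state the
#' reactor is read as three nested plug-flow segments measured from the
#' inlet: the inlet zone (0.33 L), the composite inlet+middle segment
#' (0.66 L) and the whole reactor (1.0 L). Each segment contributes one
#' point with `C0` the feed sulfate, `CA` the sulfate leaving the segment,
#' `flow_per_volume = D * V_working / V_segment`, and observed mean rate
#' `y = flow_per_volume * (C0 - CA)`.
#'
#' @param observations An observation tibble (see [load_observations()]).
#' @param config An [reactor_config()].
#' @param datasets Which cumulative segments to emit: any of `"inlet"`,
#'   `"composite"`, `"whole"` (default all three, the joint dataset).
#' @return A tibble with columns `dilution_rate`, `dataset`, `label`,
#'   `segment_volume`, `flow_per_volume`, `c0`, `ca`, `y`.
#' @export
build_rate_points <- function(observations, config = reactor_config(),
                              datasets = c("inlet", "composite", "whole")) {
  datasets <- match.arg(datasets, several.ok = TRUE)
  wide <- .analyte_wide(observations, "sulfate")
  if (nrow(wide) == 0) {
    abort("no non-excluded sulfate observations", class = "sulfkin_data_error")
  }
  if (!"feed" %in% names(wide) || anyNA(wide$feed)) {
    missing_d <- if (!"feed" %in% names(wide)) wide$dilution_rate else
      wide$dilution_rate[is.na(wide$feed)]
    abort(
      paste0("missing feed sulfate row for dilution rate(s): ",
             paste(format(missing_d), collapse = ", ")),
      class = "sulfkin_data_error"
    )
  }
  zmap <- tibble::tibble(
    dataset = c("inlet", "composite", "whole"),
    zone_boundary = .ZONES,
    segment_volume = config$zones$cumulative_volume,
    label = sprintf("%s %.2f L",
                    c("inlet", "inlet+middle", "whole"),
                    config$zones$cumulative_volume)
  )
  zmap <- dplyr::filter(zmap, .data$dataset %in% datasets)

  long <- tidyr::pivot_longer(
    wide, cols = dplyr::any_of(.ZONES),
    names_to = "zone_boundary", values_to = "ca"
  )
  pts <- dplyr::inner_join(long, zmap, by = "zone_boundary")
  pts <- dplyr::filter(pts, !is.na(.data$ca))
  pts <- dplyr::mutate(
    pts,
    c0 = .data$feed,
    flow_per_volume = .data$dilution_rate * config$working_volume /
      .data$segment_volume,
    y = .data$flow_per_volume * (.data$c0 - .data$ca)
  )
  dplyr::arrange(
    dplyr::select(pts, "dilution_rate", "dataset", "label", "segment_volume",
                  "flow_per_volume", "c0", "ca", "y"),
    .data$dilution_rate, .data$segment_volume
  )
}
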