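#' Sulfate conversion
#'
#' Fraction of the sulfate entering a reactor (or zone) that is removed
#' across it: `X = (C_in - C_out) / C_in`. A negative conversion (outlet
#' above inlet, possible with measurement noise) is returned as-is with a
#' warning, never clamped.
#'
#' @param c_in Inlet concentration (mg/L), > 0.
#' @param c_out Outlet concentration (mg/L), >= 0.
#' @return Conversion fraction(s), dimensionless.
#' @examples
#' conversion(1000, 36)  # 0.964
#' @export
conversion <- function(c_in, c_out) {
  if (any(c_in <= 0)) {
    abort("conversion() is undefined for c_in <= 0",
          class = "sulfkin_domain_error")
  }
  if (any(c_out < 0)) {
    abort("c_out must be >= 0", class = "sulfkin_domain_error")
  }
  x <- (c_in - c_out) / c_in
  if (any(x < 0)) {
    warn("negative conversion: outlet concentration exceeds inlet (not clamped)")
  }
  x
}

#' Volumetric sulfate reduction and loading rates
#'
#' `vsrr()` is the zone-mean volumetric sulfate reduction rate
#' `F (C_in - C_out) / V` and `vslr()` the volumetric sulfate loading rate
#' `F C_in / V`, both in mg per litre of reactor (or zone) per hour. Rates
#' are positive for net consumption. The identity
#' `vsrr = vslr * conversion` holds exactly.
#'
#' @param c_in Inlet sulfate (mg/L).
#' @param c_out Outlet sulfate (mg/L).
#' @param flow Applied flow rate F (L/h).
#' @param volume Reactor or zone volume V (L), > 0.
#' @return Rate(s) in mg L^-1 h^-1.
#' @examples
#' vsrr(1000, 36, 1 / 24, 1.0)  # ~40.2 at a one-day HRT
#' vslr(1000, 0.042, 1.0)       # 42
#' @export
vsrr <- function(c_in, c_out, flow, volume) {
  if (any(volume <= 0)) abort("volume must be > 0", class = "sulfkin_domain_error")
  if (any(flow <= 0)) abort("flow must be > 0", class = "sulfkin_domain_error")
  flow * (c_in - c_out) / volume
}

#' @rdname vsrr
#' @export
vslr <- function(c_in, flow, volume) {
  if (any(volume <= 0)) abort("volume must be > 0", class = "sulfkin_domain_error")
  if (any(flow < 0)) abort("flow must be >= 0", class = "sulfkin_domain_error")
  flow * c_in / volume
}

#' Biofilm cell density in a reactor subzone
#'
#' Converts a total biofilm cell count recovered from a sampling subzone to
#' a density per mL of liquid subzone volume, i.e. the subzone volume minus
#' the volume displaced by the polyurethane foam packing. Planktonic counts
#' are already densities and are rejected here.
#'
#' @param counts Tibble with columns `phase` (one of `biofilm_attached`,
#'   `biofilm_associated`, `planktonic`), `subzone` (index 1-6 or zone
#'   name) and `total_cells`.
#' @param config An [reactor_config()]; supplies `subzone_volume` and
#'   `foam_displacement_fraction`.
#' @return The input tibble with a `density_cells_ml` column appended.
#' @examples
#' cfg <- reactor_config()
#' biofilm_density(
#'   tibble::tibble(phase = "biofilm_attached", subzone = 1, total_cells = 3.2064e12),
#'   cfg
#' )
#' @export
biofilm_density <- function(counts, config = reactor_config()) {
  stopifnot(all(c("phase", "total_cells") %in% names(counts)))
  if (any(!counts$phase %in% c("biofilm_attached", "biofilm_associated"))) {
    abort(
      "biofilm_density() applies to biofilm phases only; planktonic counts are already per-mL densities",
      class = "sulfkin_phase_error"
    )
  }
  if (any(counts$total_cells < 0)) {
    abort("total_cells must be >= 0", class = "sulfkin_domain_error")
  }
  ref_ml <- config$subzone_volume * (1 - config$foam_displacement_fraction) * 1000
  dplyr::mutate(counts, density_cells_ml = .data$total_cells / ref_ml)
}

#' Ratio of associated to attached biofilm cells
#'
#' @param associated Density of weakly attached (matrix-associated) cells.
#' @param attached Density of firmly attached cells, > 0.
#' @return `associated / attached`, dimensionless.
#' @export
phase_ratio <- function(associated, attached) {
  if (any(attached <= 0)) {
    abort("phase_ratio() is undefined for attached <= 0",
          class = "sulfkin_domain_error")
  }
  associated / attached
}
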