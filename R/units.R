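#' Anion molar masses used for unit conversion
#'
#' Molar masses (g/mol) of the free anions measured in sulfate-reducing
#' reactor liquors: sulfate, lactate, propionate, acetate, citrate and
#' sulfide (as bisulfide, HS-). These define the package's mg/L <-> mM
#' conversions; concentrations are carried internally in mg/L.
#'
#' @return A tibble with columns `analyte` and `molar_mass` (g/mol).
#' @examples
#' molar_masses()
#' @export
molar_masses <- function() {
  tibble::tibble(analyte = .ANALYTES, molar_mass = unname(.MOLAR_MASS))
}

.check_analyte <- function(analyte) {
  bad <- setdiff(unique(analyte), .ANALYTES)
  if (length(bad) > 0) {
    abort(
      paste0(
        "Unknown analyte(s): ", paste(bad, collapse = ", "),
        ". Allowed: ", paste(.ANALYTES, collapse = ", ")
      ),
      class = "sulfkin_unknown_analyte"
    )
  }
  invisible(analyte)
}

#' Convert concentrations between mg/L and mM
#'
#' Vectorised conversions between mass and molar concentration using the
#' anion molar masses in [molar_masses()]. `analyte` is recycled against
#' the concentration vector.
#'
#' @param x Numeric vector of concentrations.
#' @param analyte Character vector of analyte names (see [molar_masses()]).
#' @return Numeric vector of converted concentrations.
#' @examples
#' to_mM(1000, "sulfate")    # 10.41 mM
#' to_mg_l(13.3, "lactate")  # 1184.6 mg/L
#' @export
to_mM <- function(x, analyte) {
  .check_analyte(analyte)
  unname(x / .MOLAR_MASS[analyte])
}

#' @rdname to_mM
#' @export
to_mg_l <- function(x, analyte) {
  .check_analyte(analyte)
  unname(x * .MOLAR_MASS[analyte])
}
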