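.OBS_HEADER <- c(
  "dilution_rate_h", "zone_boundary", "analyte", "mean_conc", "sd_conc",
  "n", "steady", "excluded", "unit", "note"
)
.BOUNDARIES <- c("feed", .ZONES)

#' Load a steady-state observation table
#'
#' Reads the delimited observation table (comma by default, tab accepted)
#' holding one row per (dilution rate, zone boundary, analyte): the mean and
#' standard deviation of the replicate concentration measurements taken at
#' that zone outlet during a defined steady state, plus flags marking
#' non-steady states that are carried in the table but excluded from
#' modelling. Concentrations reported in mM are converted to mg/L at this
#' boundary using [molar_masses()]; everything downstream works in mg/L.
#'
#' The file must have the exact header
#' `dilution_rate_h, zone_boundary, analyte, mean_conc, sd_conc, n, steady,
#' excluded, unit, note` with `unit` one of `mg/L`, `mM`. Rows violating the
#' record invariants (negative concentrations or SDs, n < 1, non-positive
#' dilution rate, unknown analyte or zone) are rejected with row-numbered
#' diagnostics.
#'
#' @param path Path to the delimited text file.
#' @param config An [reactor_config()] object (used for schema context only).
#' @return A tibble of class `srk_observations` with columns
#'   `dilution_rate` (1/h), `zone_boundary`, `analyte`, `mean_conc` (mg/L),
#'   `sd_conc` (mg/L), `n_samples`, `steady`, `excluded`, `note`.
#' @seealso [write_observations()], [simulate_observations()]
#' @export
load_observations <- function(path, config = reactor_config()) {
  if (!file.exists(path)) {
    abort(paste0("Observation file not found: ", path), class = "sulfkin_io_error")
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      dilution_rate_h = readr::col_double(),
      zone_boundary = readr::col_character(),
      analyte = readr::col_character(),
      mean_conc = readr::col_double(),
      sd_conc = readr::col_double(),
      n = readr::col_integer(),
      steady = readr::col_logical(),
      excluded = readr::col_logical(),
      unit = readr::col_character(),
      note = readr::col_character()
    )
  )
  missing_cols <- setdiff(.OBS_HEADER, names(tab))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Observation table is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "sulfkin_parse_error"
    )
  }
  tab <- tab[.OBS_HEADER]
  if (nrow(tab) == 0) {
    return(.as_observations(tibble::tibble(
      dilution_rate = double(), zone_boundary = character(),
      analyte = character(), mean_conc = double(), sd_conc = double(),
      n_samples = integer(), steady = logical(), excluded = logical(),
      note = character()
    )))
  }

  problems <- character()
  row_bad <- function(i, msg) {
    problems <<- c(problems, sprintf("row %d: %s", i, msg))
  }
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (!r$analyte %in% .ANALYTES) {
      row_bad(i, paste0("unknown analyte '", r$analyte, "' (allowed: ",
                        paste(.ANALYTES, collapse = ", "), ")"))
    }
    if (!r$zone_boundary %in% .BOUNDARIES) {
      row_bad(i, paste0("unknown zone_boundary '", r$zone_boundary,
                        "' (allowed: ", paste(.BOUNDARIES, collapse = ", "), ")"))
    }
    if (!r$unit %in% c("mg/L", "mM")) {
      row_bad(i, paste0("unit must be 'mg/L' or 'mM', got '", r$unit, "'"))
    }
    if (is.na(r$mean_conc) || r$mean_conc < 0) row_bad(i, "mean_conc must be >= 0")
    if (is.na(r$sd_conc) || r$sd_conc < 0) row_bad(i, "sd_conc must be >= 0")
    if (is.na(r$n) || r$n < 1) row_bad(i, "n must be >= 1")
    if (is.na(r$dilution_rate_h) || r$dilution_rate_h <= 0) {
      row_bad(i, "dilution_rate_h must be > 0")
    }
  }
  if (length(problems) > 0) {
    abort(
      c("Invalid observation rows:", setNames(problems, rep("x", length(problems)))),
      class = "sulfkin_parse_error"
    )
  }

  is_mM <- tab$unit == "mM"
  tab$mean_conc[is_mM] <- to_mg_l(tab$mean_conc[is_mM], tab$analyte[is_mM])
  tab$sd_conc[is_mM] <- to_mg_l(tab$sd_conc[is_mM], tab$analyte[is_mM])

  .as_observations(tibble::tibble(
    dilution_rate = tab$dilution_rate_h,
    zone_boundary = tab$zone_boundary,
    analyte = tab$analyte,
    mean_conc = tab$mean_conc,
    sd_conc = tab$sd_conc,
    n_samples = as.integer(tab$n),
    steady = tab$steady,
    excluded = tab$excluded,
    note = dplyr::coalesce(tab$note, "")
  ))
}

.as_observations <- function(x) {
  class(x) <- unique(c("srk_observations", class(x)))
  x
}

#' Write a steady-state observation table
#'
#' Writes the table in the same schema [load_observations()] reads, in
#' mg/L, so that a load -> write -> load round trip preserves numeric
#' content.
#'
#' @param observations An observation tibble (see [load_observations()]).
#' @param path Output file path.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path, delim = ",") {
  out <- tibble::tibble(
    dilution_rate_h = observations$dilution_rate,
    zone_boundary = observations$zone_boundary,
    analyte = observations$analyte,
    mean_conc = observations$mean_conc,
    sd_conc = observations$sd_conc,
    n = observations$n_samples,
    steady = observations$steady,
    excluded = observations$excluded,
    unit = "mg/L",
    note = if ("note" %in% names(observations)) observations$note else ""
  )
  # fixed 10-significant-digit formatting keeps write -> load -> write
  # byte-stable while preserving numeric content well past assay precision
  out$mean_conc <- sprintf("%.10g", out$mean_conc)
  out$sd_conc <- sprintf("%.10g", out$sd_conc)
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

# Zone-outlet means of one analyte in wide form: one row per dilution rate,
# one column per boundary (feed, inlet, middle, effluent). Internal helper
# shared by rate-point construction and the donor balance.
.analyte_wide <- function(observations, which_analyte, keep_excluded = FALSE) {
  obs <- dplyr::filter(observations, .data$analyte == which_analyte)
  if (!keep_excluded) {
    obs <- dplyr::filter(obs, !.data$excluded)
  }
  tidyr::pivot_wider(
    dplyr::select(obs, "dilution_rate", "zone_boundary", "mean_conc"),
    names_from = "zone_boundary", values_from = "mean_conc"
  )
}
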