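#' Attribute one zone's sulfate removal to electron donors
#'
#' Builds the stoichiometric ledger for a single reactor zone from its
#' inlet and outlet compositions (mM). Attribution follows the fixed
#' precedence of the analysis:
#'
#' 1. A net propionate increase across the zone is read as lactate
#'    fermentation (1.5 lactate per propionate, crediting 0.5 acetate);
#'    a net decrease as propionate oxidation (0.75 sulfate and 1 acetate
#'    credit per propionate).
#' 2. Lactate consumed beyond the fermented share is oxidised
#'    incompletely to acetate (0.5 sulfate per lactate, 1 acetate credit),
#'    capped at the remaining observed sulfate removal.
#' 3. Any residual sulfate removal is charged to acetate oxidation
#'    (1 sulfate per acetate), drawing on inlet acetate plus all credits;
#'    the inlet zone additionally receives the fixed yeast-extract acetate
#'    credit.
#'
#' Residual sulfate removal that exhausts the available acetate is
#' reported as `unexplained_sulfate` with a deficit flag; negative
#' intermediate quantities are flagged and floored at zero rather than
#' raised, so noisy data flow through.
#'
#' @param zone_in,zone_out Named numeric vectors, analyte -> mM, for the
#'   composition entering and leaving the zone. `sulfate` required;
#'   `lactate`, `propionate`, `acetate`, `citrate` default to 0.
#' @param config An [reactor_config()] (yeast-extract credit, citrate
#'   handling).
#' @param zone Zone name (`"inlet"`, `"middle"`, `"effluent"`).
#' @param dilution_rate Reactor dilution rate (1/h), carried into the
#'   ledger row.
#' @return A one-row tibble (class `srk_balance`) with the ledger:
#'   in/out concentrations, `lactate_fermented`, `lactate_to_srm`,
#'   `sulfate_via_lactate` / `_propionate` / `_acetate` (mM),
#'   `acetate_produced`, `acetate_consumed`, `ye_acetate_credit`,
#'   `predicted_acetate_out` (mM), `predicted_acetate_out_mg_l`,
#'   `unexplained_sulfate` and a `deficit_flags` list-column.
#' @examples
#' cfg <- reactor_config(primary_donor = "lactate",
#'                       yeast_extract_acetate_credit = 0)
#' attribute_zone_sulfate(
#'   zone_in = c(sulfate = 10.41, lactate = 13.3, propionate = 0, acetate = 0),
#'   zone_out = c(sulfate = 10.41 - 4.925, lactate = 0, propionate = 2.3,
#'                acetate = 11),
#'   config = cfg, zone = "middle"
#' )
#' @export
attribute_zone_sulfate <- function(zone_in, zone_out,
                                   config = reactor_config(),
                                   zone = "inlet",
                                   dilution_rate = NA_real_) {
  if (!zone %in% .ZONES) {
    abort(paste0("unknown zone '", zone, "'"), class = "sulfkin_domain_error")
  }
  get0v <- function(v, a) if (a %in% names(v)) unname(v[[a]]) else 0
  need <- function(v, lab) {
    if (!"sulfate" %in% names(v)) {
      abort(paste0(lab, " must include sulfate"), class = "sulfkin_data_error")
    }
    if (any(v < 0)) abort(paste0(lab, " concentrations must be >= 0"),
                          class = "sulfkin_domain_error")
  }
  need(zone_in, "zone_in"); need(zone_out, "zone_out")

  flags <- character()
  in_s <- get0v(zone_in, "sulfate");   out_s <- get0v(zone_out, "sulfate")
  in_l <- get0v(zone_in, "lactate");   out_l <- get0v(zone_out, "lactate")
  in_p <- get0v(zone_in, "propionate"); out_p <- get0v(zone_out, "propionate")
  in_a <- get0v(zone_in, "acetate")
  in_c <- get0v(zone_in, "citrate");   out_c <- get0v(zone_out, "citrate")

  removal <- in_s - out_s
  if (removal < 0) {
    flags <- c(flags, "negative sulfate removal (outlet above inlet)")
    removal <- 0
  }
  remaining <- removal

  # (1) net propionate change
  d_prop <- out_p - in_p
  ferm_lactate <- 0; ferm_acetate <- 0; prop_oxidised <- 0; s_prop <- 0
  if (d_prop >= 0) {
    ferm_lactate <- 1.5 * d_prop
    ferm_acetate <- 0.5 * d_prop
  } else {
    prop_consumed <- -d_prop
    s_prop <- min(0.75 * prop_consumed, remaining)
    if (s_prop < 0.75 * prop_consumed - 1e-12) {
      flags <- c(flags, "propionate oxidation capped at observed sulfate removal")
    }
    prop_oxidised <- s_prop / 0.75
    remaining <- remaining - s_prop
  }

  # (2) lactate beyond the fermented share
  lactate_consumed <- in_l - out_l
  if (lactate_consumed < 0) {
    flags <- c(flags, "negative lactate consumption floored at zero")
    lactate_consumed <- 0
  }
  lactate_to_srm <- lactate_consumed - ferm_lactate
  if (lactate_to_srm < 0) {
    flags <- c(flags, "fermented lactate exceeds consumed lactate")
    lactate_to_srm <- 0
  }
  lactate_oxidised <- min(lactate_to_srm, remaining / 0.5)
  if (lactate_oxidised < lactate_to_srm - 1e-12) {
    flags <- c(flags, "lactate available to SRM exceeds observed sulfate removal")
  }
  s_lac <- 0.5 * lactate_oxidised
  remaining <- remaining - s_lac

  # (3) residual removal drawn from the acetate pool
  ye_credit <- if (zone == "inlet") {
    to_mM(config$yeast_extract_acetate_credit, "acetate")
  } else 0
  citrate_consumed <- max(in_c - out_c, 0)
  citrate_credit <- if (isTRUE(config$citrate_acetate_credit)) {
    citrate_consumed
  } else 0
  acetate_available <- in_a + ferm_acetate + prop_oxidised +
    lactate_oxidised + ye_credit + citrate_credit
  s_ace <- min(remaining, acetate_available)
  remaining <- remaining - s_ace
  if (remaining > 1e-9) {
    flags <- c(flags, sprintf(
      "electron-donor deficit: %.4g mM sulfate removal unexplained", remaining))
  }
  unexplained <- max(remaining, 0)

  predicted_acetate <- acetate_available - s_ace

  res <- tibble::tibble(
    zone = zone,
    dilution_rate = dilution_rate,
    sulfate_in = in_s, sulfate_out = out_s,
    sulfate_removed = in_s - out_s,
    lactate_in = in_l, lactate_out = out_l,
    propionate_in = in_p, propionate_out = out_p,
    acetate_in = in_a,
    citrate_consumed = citrate_consumed,
    lactate_fermented = ferm_lactate,
    lactate_to_srm = lactate_to_srm,
    sulfate_via_lactate = s_lac,
    sulfate_via_propionate = s_prop,
    sulfate_via_acetate = s_ace,
    acetate_produced = ferm_acetate + prop_oxidised + lactate_oxidised,
    acetate_consumed = s_ace,
    ye_acetate_credit = ye_credit,
    citrate_acetate_credit = citrate_credit,
    predicted_acetate_out = predicted_acetate,
    predicted_acetate_out_mg_l = to_mg_l(predicted_acetate, "acetate"),
    unexplained_sulfate = unexplained,
    deficit_flags = list(flags)
  )
  class(res) <- unique(c("srk_balance", class(res)))
  res
}

#' Zone-chained donor attribution over an observation table
#'
#' Runs [attribute_zone_sulfate()] across the three zones of every
#' non-excluded steady state in an observation table, chaining each zone's
#' inlet composition from the previous boundary. With
#' `chaining = "observed"` (default) each zone's inlet is the measured
#' composition at the upstream boundary; with `"predicted"` the acetate
#' entering a zone is the previous zone's predicted acetate while the
#' other analytes remain observed.
#'
#' @param observations An observation tibble (see [load_observations()]).
#' @param config An [reactor_config()].
#' @param chaining `"observed"` or `"predicted"` upstream acetate.
#' @return An `srk_balance` tibble, one row per (dilution rate, zone),
#'   ordered inlet to effluent, with an `observed_acetate_out` column and
#'   the chaining mode in attribute `chaining`.
#' @export
attribute_observations <- function(observations, config = reactor_config(),
                                   chaining = c("observed", "predicted")) {
  chaining <- match.arg(chaining)
  analytes <- c("sulfate", "lactate", "propionate", "acetate", "citrate")
  wides <- lapply(analytes, function(a) .analyte_wide(observations, a))
  names(wides) <- analytes
  rates <- sort(unique(wides$sulfate$dilution_rate))

  comp_at <- function(d, boundary) {
    out <- vapply(analytes, function(a) {
      w <- wides[[a]]
      if (!boundary %in% names(w)) return(NA_real_)
      v <- w[[boundary]][w$dilution_rate == d]
      if (length(v) == 0) NA_real_ else to_mM(v, a)
    }, numeric(1))
    out[is.na(out)] <- 0
    out
  }

  rows <- purrr::map(rates, function(d) {
    bounds <- c("feed", .ZONES)
    zone_rows <- vector("list", length(.ZONES))
    upstream <- comp_at(d, "feed")
    for (i in seq_along(.ZONES)) {
      zn <- .ZONES[i]
      zout <- comp_at(d, zn)
      bal <- attribute_zone_sulfate(upstream, zout, config, zone = zn,
                                    dilution_rate = d)
      bal$observed_acetate_out <- zout[["acetate"]]
      zone_rows[[i]] <- bal
      upstream <- zout
      if (chaining == "predicted") {
        upstream[["acetate"]] <- bal$predicted_acetate_out
      }
    }
    dplyr::bind_rows(zone_rows)
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "chaining") <- chaining
  class(res) <- unique(c("srk_balance", class(res)))
  res
}

#' Predicted zone-outlet acetate profile
#'
#' Extracts the per-zone predicted acetate concentrations from a chained
#' ledger, alongside the observed values, in both mM and mg/L.
#'
#' @param balances An `srk_balance` tibble from [attribute_observations()]
#'   (or rows from [attribute_zone_sulfate()] ordered inlet to effluent).
#' @return A tibble with columns `dilution_rate`, `zone`, `predicted_mM`,
#'   `predicted_mg_l`, `observed_mM`, `observed_mg_l` and the chaining mode
#'   in attribute `chaining`.
#' @export
predict_acetate_profile <- function(balances) {
  ord <- match(balances$zone, .ZONES)
  if (anyNA(ord)) {
    abort("unknown zone names in balances", class = "sulfkin_domain_error")
  }
  by_d <- split(ord, balances$dilution_rate)
  if (any(vapply(by_d, function(o) any(diff(o) <= 0), logical(1)))) {
    abort("zones must be ordered inlet -> effluent within each dilution rate",
          class = "sulfkin_domain_error")
  }
  obs <- if ("observed_acetate_out" %in% names(balances)) {
    balances$observed_acetate_out
  } else NA_real_
  res <- tibble::tibble(
    dilution_rate = balances$dilution_rate,
    zone = balances$zone,
    predicted_mM = balances$predicted_acetate_out,
    predicted_mg_l = to_mg_l(balances$predicted_acetate_out, "acetate"),
    observed_mM = obs,
    observed_mg_l = to_mg_l(obs, "acetate")
  )
  attr(res, "chaining") <- attr(balances, "chaining") %||% "observed"
  res
}

#' Observed-vs-predicted percent difference, averaged per zone
#'
#' The agreement metric for the acetate predictions: per point,
#' `100 * |observed - predicted| / observed`; per zone, the arithmetic
#' mean across dilution rates. Points with zero observed concentration are
#' excluded from the mean and flagged.
#'
#' @param profile A tibble from [predict_acetate_profile()], or any tibble
#'   with columns `zone`, `observed_mg_l`, `predicted_mg_l` (mM columns
#'   work identically; the metric is scale-invariant).
#' @return A list with `per_point` (the input plus `pct_diff`) and
#'   `per_zone` (tibble: `zone`, `mean_pct_diff`, `n_used`, `n_excluded`).
#' @export
percent_difference_profile <- function(profile) {
  stopifnot(all(c("zone", "observed_mg_l", "predicted_mg_l") %in% names(profile)))
  per_point <- dplyr::mutate(
    profile,
    pct_diff = dplyr::if_else(
      .data$observed_mg_l > 0,
      100 * abs(.data$observed_mg_l - .data$predicted_mg_l) / .data$observed_mg_l,
      NA_real_
    )
  )
  per_zone <- dplyr::summarise(
    dplyr::group_by(per_point, .data$zone),
    mean_pct_diff = mean(.data$pct_diff, na.rm = TRUE),
    n_used = sum(!is.na(.data$pct_diff)),
    n_excluded = sum(is.na(.data$pct_diff)),
    .groups = "drop"
  )
  per_zone <- per_zone[order(match(per_zone$zone, .ZONES)), ]
  if (any(per_zone$n_excluded > 0)) {
    warn("points with zero observed concentration were excluded from the zone means")
  }
  list(per_point = per_point, per_zone = per_zone)
}
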