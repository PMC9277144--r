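# Signed molar stoichiometry (negative = consumed) of the sulfate-reducing
# and lactate-fermenting reactions used by the donor ledger, with standard
# transformed Gibbs energies (kJ per reaction as written).
.REACTIONS <- list(
  ACETATE_OX = list(
    equation = "Acetate- + SO4^2- -> 2 HCO3- + HS-",
    delta_g = -47.6,
    stoichiometry = c(acetate = -1, sulfate = -1, bicarbonate = 2, sulfide = 1)
  ),
  PROPIONATE_OX = list(
    equation = "Propionate- + 0.75 SO4^2- -> Acetate- + HCO3- + 0.75 HS- + 0.25 H+",
    delta_g = -37.7,
    stoichiometry = c(propionate = -1, sulfate = -0.75, acetate = 1,
                      bicarbonate = 1, sulfide = 0.75, proton = 0.25)
  ),
  LACTATE_INCOMPLETE = list(
    equation = "Lactate- + 0.5 SO4^2- -> Acetate- + HCO3- + 0.5 HS-",
    delta_g = -80.2,
    stoichiometry = c(lactate = -1, sulfate = -0.5, acetate = 1,
                      bicarbonate = 1, sulfide = 0.5)
  ),
  LACTATE_COMPLETE = list(
    equation = "2 Lactate- + 3 SO4^2- -> 6 HCO3- + 3 HS- + H+",
    delta_g = -225.3,
    stoichiometry = c(lactate = -2, sulfate = -3, bicarbonate = 6,
                      sulfide = 3, proton = 1)
  ),
  LACTATE_FERMENT = list(
    equation = "3 Lactate- -> Acetate- + 2 Propionate- + HCO3- + H+",
    delta_g = -70.0,
    stoichiometry = c(lactate = -3, acetate = 1, propionate = 2,
                      bicarbonate = 1, proton = 1)
  )
)

#' Sulfidogenic and fermentative reaction stoichiometries
#'
#' The five reactions underpinning the electron-donor mass balance:
#' complete acetate oxidation, incomplete propionate oxidation to acetate,
#' incomplete and complete lactate oxidation, and lactate fermentation to
#' acetate + propionate (the methylmalonyl-CoA route). Coefficients are
#' signed moles per reaction as written (negative = consumed); `delta_g`
#' is the standard transformed Gibbs energy in kJ/reaction.
#'
#' @param id Optional reaction id; if given, returns that single reaction
#'   as a list with elements `equation`, `delta_g`, `stoichiometry`.
#' @return With no `id`, a tibble with columns `id`, `equation`, `delta_g`
#'   and a `stoichiometry` list-column of named coefficient vectors.
#' @examples
#' srk_reactions()
#' srk_reactions("LACTATE_INCOMPLETE")$stoichiometry
#' @export
srk_reactions <- function(id = NULL) {
  if (!is.null(id)) {
    if (!id %in% names(.REACTIONS)) {
      abort(paste0("unknown reaction id '", id, "'; allowed: ",
                   paste(names(.REACTIONS), collapse = ", ")),
            class = "sulfkin_domain_error")
    }
    return(.REACTIONS[[id]])
  }
  tibble::tibble(
    id = names(.REACTIONS),
    equation = purrr::map_chr(.REACTIONS, "equation"),
    delta_g = unname(purrr::map_dbl(.REACTIONS, "delta_g")),
    stoichiometry = unname(purrr::map(.REACTIONS, "stoichiometry"))
  )
}

# moles of sulfate consumed per mole of donor for a sulfidogenic reaction
.sulfate_per_donor <- function(id, donor) {
  s <- .REACTIONS[[id]]$stoichiometry
  if (!"sulfate" %in% names(s)) {
    abort(paste0(id, " is not sulfidogenic (no sulfate term)"),
          class = "sulfkin_domain_error")
  }
  if (!donor %in% names(s) || s[[donor]] >= 0) {
    abort(paste0(id, " does not consume ", donor), class = "sulfkin_domain_error")
  }
  s[["sulfate"]] / s[[donor]]  # ratio of two negatives: positive
}

#' Theoretical sulfate-reduction capacity of a donor supply
#'
#' The maximum percentage of a sulfate supply that a given electron-donor
#' supply could reduce through one sulfidogenic reaction, capped at 100%:
#' e.g. 13.3 mM lactate against 10.41 mM sulfate via incomplete lactate
#' oxidation (0.5 sulfate per lactate) allows ~64% reduction.
#'
#' @param donor Donor analyte name (must be consumed by `reaction_id`).
#' @param donor_mM Donor supply, mM.
#' @param sulfate_mM Sulfate supply, mM, > 0.
#' @param reaction_id One of the sulfidogenic ids in [srk_reactions()].
#' @return Capacity in percent (0-100).
#' @examples
#' theoretical_sulfate_capacity("lactate", 13.3, to_mM(1000, "sulfate"),
#'                              "LACTATE_INCOMPLETE")
#' @export
theoretical_sulfate_capacity <- function(donor, donor_mM, sulfate_mM,
                                         reaction_id) {
  if (sulfate_mM <= 0) {
    abort("sulfate_mM must be > 0", class = "sulfkin_domain_error")
  }
  if (donor_mM < 0) abort("donor_mM must be >= 0", class = "sulfkin_domain_error")
  coeff <- .sulfate_per_donor(reaction_id, donor)
  100 * min(1, donor_mM * coeff / sulfate_mM)
}

#' Partition supplied lactate between fermentation and sulfidogenesis
#'
#' All net propionate appearing across a zone is attributed to lactate
#' fermentation (3 lactate -> 1 acetate + 2 propionate), so the lactate
#' fermented is 1.5x the net propionate produced and the fermentation also
#' credits 0.5x that propionate as acetate. The remainder of the consumed
#' lactate is available to sulfate reducers.
#'
#' @param net_propionate_produced Net propionate appearing across the zone,
#'   mM, >= 0.
#' @param lactate_supplied Lactate supplied to the zone, mM, > 0.
#' @return A one-row tibble: `lactate_fermented` (mM),
#'   `fermented_fraction_pct` (% of supply), `acetate_from_fermentation`
#'   (mM) and `inconsistent` (`TRUE` when the implied fermented lactate
#'   exceeds the supply; flagged, not raised).
#' @examples
#' lactate_fermentation_split(2.3, 13.3)  # ~26% fermented
#' @export
lactate_fermentation_split <- function(net_propionate_produced,
                                       lactate_supplied) {
  if (any(lactate_supplied <= 0)) {
    abort("lactate_supplied must be > 0", class = "sulfkin_domain_error")
  }
  if (any(net_propionate_produced < 0)) {
    abort("net_propionate_produced must be >= 0", class = "sulfkin_domain_error")
  }
  fermented <- 1.5 * net_propionate_produced
  tibble::tibble(
    lactate_fermented = fermented,
    fermented_fraction_pct = 100 * fermented / lactate_supplied,
    acetate_from_fermentation = 0.5 * net_propionate_produced,
    inconsistent = fermented > lactate_supplied
  )
}
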