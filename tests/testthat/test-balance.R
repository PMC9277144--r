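cfg0 <- reactor_config(primary_donor = "lactate",
                       yeast_extract_acetate_credit = 0)

test_that("an inert non-inlet zone yields an empty ledger", {
  comp <- c(sulfate = 8, lactate = 1, propionate = 0.5, acetate = 6)
  bal <- attribute_zone_sulfate(comp, comp, cfg0, zone = "middle")
  expect_equal(bal$sulfate_via_lactate + bal$sulfate_via_propionate +
                 bal$sulfate_via_acetate, 0)
  expect_equal(bal$predicted_acetate_out, 6)
  expect_equal(bal$unexplained_sulfate, 0)
  expect_length(bal$deficit_flags[[1]], 0)
})

test_that("a lactate-only zone splits fermentation and incomplete oxidation", {
  zin <- c(sulfate = 10.41, lactate = 13.3, propionate = 0, acetate = 0)
  zout <- c(sulfate = 10.41 - 4.925, lactate = 0, propionate = 2.3, acetate = 0)
  bal <- attribute_zone_sulfate(zin, zout, cfg0, zone = "middle")
  expect_equal(bal$lactate_fermented, 3.45)
  expect_equal(bal$lactate_to_srm, 9.85)
  expect_equal(bal$sulfate_via_lactate, 4.925, tolerance = 1e-12)
  expect_equal(bal$sulfate_via_acetate, 0, tolerance = 1e-9)
  # 9.85 from lactate oxidation + 1.15 from fermentation
  expect_equal(bal$acetate_produced, 11, tolerance = 1e-9)
  expect_equal(bal$predicted_acetate_out, 11, tolerance = 1e-9)
})

test_that("a propionate-consuming middle zone charges residual to acetate", {
  zin <- c(sulfate = 5, lactate = 0, propionate = 2.3, acetate = 8)
  zout <- c(sulfate = 2.5, lactate = 0, propionate = 0, acetate = 8)
  bal <- attribute_zone_sulfate(zin, zout, cfg0, zone = "middle")
  expect_equal(bal$sulfate_via_propionate, 1.725)
  expect_equal(bal$sulfate_via_acetate, 0.775, tolerance = 1e-12)
  # net acetate change: +2.3 produced, -0.775 consumed
  expect_equal(bal$predicted_acetate_out - bal$acetate_in, 2.3 - 0.775,
               tolerance = 1e-12)
})

test_that("the inlet-zone yeast-extract-only case predicts exactly 268 mg/L", {
  cfg <- reactor_config(primary_donor = "lactate")  # 268 mg/L credit
  comp <- c(sulfate = 10.41, lactate = 0, propionate = 0, acetate = 0)
  bal <- attribute_zone_sulfate(comp, comp, cfg, zone = "inlet")
  expect_equal(bal$predicted_acetate_out_mg_l, 268)
  # no credit outside the inlet zone
  balm <- attribute_zone_sulfate(comp, comp, cfg, zone = "middle")
  expect_equal(balm$predicted_acetate_out_mg_l, 0)
})

test_that("incomplete oxidation + acetate reoxidation equals complete oxidation", {
  # symbolic ledger identity on the tracked species, per mole lactate
  inc <- srk_reactions("LACTATE_INCOMPLETE")$stoichiometry
  ace <- srk_reactions("ACETATE_OX")$stoichiometry
  com <- srk_reactions("LACTATE_COMPLETE")$stoichiometry
  species <- c("lactate", "sulfate", "acetate", "propionate", "bicarbonate",
               "sulfide")
  get0 <- function(v, s) if (s %in% names(v)) v[[s]] else 0
  for (s in species) {
    expect_equal(get0(inc, s) + get0(ace, s), get0(com, s) / 2,
                 info = s, tolerance = 1e-12)
  }
  # numeric ledgers: forcing full reoxidation of lactate-derived acetate
  # gives the same net result as invoking complete oxidation directly
  set.seed(42)
  for (i in 1:20) {
    L <- runif(1, 0.5, 8); a0 <- runif(1, 0, 5); s0 <- runif(1, 13, 30)
    zin <- c(sulfate = s0, lactate = L, propionate = 0, acetate = a0)
    zout <- c(sulfate = s0 - 1.5 * L, lactate = 0, propionate = 0, acetate = a0)
    bal <- attribute_zone_sulfate(zin, zout, cfg0, zone = "middle")
    expect_equal(bal$sulfate_via_lactate + bal$sulfate_via_acetate, 1.5 * L,
                 tolerance = 1e-9)
    expect_equal(bal$predicted_acetate_out, a0, tolerance = 1e-9)
    expect_equal(bal$unexplained_sulfate, 0, tolerance = 1e-9)
  }
})

test_that("attribution books donors against sulfate with exact coefficients", {
  set.seed(7)
  for (i in 1:25) {
    L <- runif(1, 0, 6); P <- runif(1, 0, 2); A <- runif(1, 1, 8)
    lac_ox <- runif(1, 0, L); prop_ox <- runif(1, 0, P); ace_ox <- runif(1, 0, A)
    removal <- 0.5 * lac_ox + 0.75 * prop_ox + ace_ox
    zin <- c(sulfate = removal + 1, lactate = L, propionate = P, acetate = A)
    zout <- c(sulfate = 1, lactate = L - lac_ox, propionate = P - prop_ox,
              acetate = A)
    bal <- attribute_zone_sulfate(zin, zout, cfg0, zone = "middle")
    expect_equal(bal$sulfate_via_lactate + bal$sulfate_via_propionate +
                   bal$sulfate_via_acetate, removal, tolerance = 1e-9)
    expect_equal(bal$sulfate_via_propionate, 0.75 * prop_ox, tolerance = 1e-9)
    expect_equal(bal$unexplained_sulfate, 0, tolerance = 1e-9)
    # acetate is conserved through the ledger
    expect_equal(bal$predicted_acetate_out,
                 A + 0.5 * 0 + lac_ox + prop_ox - ace_ox, tolerance = 1e-9)
  }
})

test_that("noisy inconsistencies are flagged, never fatal", {
  # outlet sulfate above inlet
  zin <- c(sulfate = 5, lactate = 1, propionate = 0, acetate = 1)
  zout <- c(sulfate = 5.2, lactate = 1, propionate = 0, acetate = 1)
  bal <- attribute_zone_sulfate(zin, zout, cfg0, zone = "effluent")
  expect_match(paste(bal$deficit_flags[[1]], collapse = " "),
               "negative sulfate removal")
  # donor deficit
  zin2 <- c(sulfate = 10, lactate = 0, propionate = 0, acetate = 0.5)
  zout2 <- c(sulfate = 2, lactate = 0, propionate = 0, acetate = 0)
  bal2 <- attribute_zone_sulfate(zin2, zout2, cfg0, zone = "effluent")
  expect_equal(bal2$unexplained_sulfate, 8 - 0.5, tolerance = 1e-9)
  expect_match(paste(bal2$deficit_flags[[1]], collapse = " "), "deficit")
})

test_that("zone-chained attribution and acetate prediction run end to end", {
  spec <- scenario_lactate_reactor(noise_cv = 0, replicates = 1)
  obs <- simulate_observations(spec, seed = 1)
  bal <- attribute_observations(obs, spec$config)
  expect_equal(attr(bal, "chaining"), "observed")
  prof <- predict_acetate_profile(bal)
  expect_equal(nrow(prof), 7 * 3)   # 9 rates minus 2 excluded, 3 zones
  pd <- percent_difference_profile(prof)
  expect_true(all(pd$per_zone$mean_pct_diff < 1e-9))
  # predicted-chaining mode is recorded
  balp <- attribute_observations(obs, spec$config, chaining = "predicted")
  expect_equal(attr(predict_acetate_profile(balp), "chaining"), "predicted")
})

test_that("percent differences match hand arithmetic and flag zero observations", {
  prof <- tibble::tibble(
    zone = c("inlet", "middle", "middle"),
    observed_mg_l = c(400, 100, 200),
    predicted_mg_l = c(372.4, 90, 220)
  )
  pd <- percent_difference_profile(prof)
  expect_equal(pd$per_zone$mean_pct_diff[pd$per_zone$zone == "inlet"], 6.9,
               tolerance = 1e-6)
  expect_equal(pd$per_zone$mean_pct_diff[pd$per_zone$zone == "middle"], 10,
               tolerance = 1e-12)
  prof0 <- dplyr::mutate(prof, observed_mg_l = c(0, 100, 200))
  expect_warning(pd0 <- percent_difference_profile(prof0), regexp = "zero")
  expect_equal(pd0$per_zone$n_excluded[pd0$per_zone$zone == "inlet"], 1L)
})

test_that("mis-ordered zones are rejected", {
  bal <- dplyr::bind_rows(
    attribute_zone_sulfate(c(sulfate = 5), c(sulfate = 5), cfg0, "middle", 0.01),
    attribute_zone_sulfate(c(sulfate = 5), c(sulfate = 5), cfg0, "inlet", 0.01)
  )
  expect_error(predict_acetate_profile(bal), class = "sulfkin_domain_error")
})
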