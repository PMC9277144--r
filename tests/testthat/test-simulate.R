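test_that("sulfate profiles follow the kinetic truth and are monotone", {
  spec <- noiseless_lactate()
  prof <- simulate_sulfate_profile(spec)
  expect_equal(nrow(prof), 9 * 4)   # ladder x (feed + 3 zones)
  whole <- dplyr::filter(prof, zone_boundary == "effluent",
                         dilution_rate == 0.042)
  expect_equal(whole$sulfate_mg_l,
               pfr_outlet_concentration(1000, 0.06955, 1, 1 / 0.042),
               tolerance = 1e-9)
  for (d in spec$dilution_ladder) {
    p <- dplyr::filter(prof, dilution_rate == d)
    expect_true(all(diff(p$sulfate_mg_l[order(p$cumulative_volume)]) <= 0))
  }
  # doubling k strictly lowers every post-feed concentration
  spec2 <- simulation_spec(kinetic = list(k = 2 * 0.06955, n = 1),
                           config = spec$config)
  prof2 <- simulate_sulfate_profile(spec2)
  post <- prof$zone_boundary != "feed"
  expect_true(all(prof2$sulfate_mg_l[post] < prof$sulfate_mg_l[post]))
  # zero rate constant: flat profiles at the feed concentration
  spec0 <- simulation_spec(kinetic = list(k = 0, n = 1), config = spec$config)
  expect_true(all(simulate_sulfate_profile(spec0)$sulfate_mg_l == 1000))
})

test_that("donor profiles close the stoichiometric ledger at every zone", {
  spec <- noiseless_lactate()
  truth <- simulate_donor_profiles(spec)
  # zero-reduction scenario: donors unchanged except fermentation + YE credit
  spec0 <- simulation_spec(
    kinetic = list(k = 0, n = 1), config = spec$config,
    fermentation_schedule = spec$fermentation_schedule
  )
  t0 <- simulate_donor_profiles(spec0)
  eff <- dplyr::filter(t0, zone_boundary == "effluent", dilution_rate == 0.010)
  lac_feed <- to_mM(spec$config$feed[["lactate"]], "lactate")
  expect_equal(eff$conc_mM[eff$analyte == "lactate"], lac_feed - 1.5 * 2.3,
               tolerance = 1e-9)
  expect_equal(eff$conc_mM[eff$analyte == "propionate"], 2.3, tolerance = 1e-9)
  expect_equal(eff$conc_mM[eff$analyte == "acetate"],
               0.5 * 2.3 + to_mM(268, "acetate"), tolerance = 1e-9)
  # all concentrations non-negative in the feasible default
  expect_true(all(truth$conc_mM >= 0))
})

test_that("attribution recovers a cleanly separated scenario's ledger exactly", {
  # moderate demand: lactate alone covers the inlet, propionate the middle
  spec <- simulation_spec(
    kinetic = list(k = 0.02, n = 1),
    config = reactor_config(primary_donor = "lactate"),
    fermentation_schedule = 2.3
  )
  obs <- simulate_observations(
    simulation_spec(kinetic = spec$kinetic, config = spec$config,
                    fermentation_schedule = 2.3, noise_cv = 0, replicates = 1),
    seed = 1
  )
  bal <- attribute_observations(obs, spec$config)
  inlet <- dplyr::filter(bal, zone == "inlet", dilution_rate == 0.042)
  expect_equal(inlet$lactate_fermented, 3.45, tolerance = 1e-9)
  expect_equal(inlet$sulfate_via_propionate, 0, tolerance = 1e-9)
  expect_equal(inlet$sulfate_via_lactate, inlet$sulfate_removed, tolerance = 1e-9)
  expect_equal(inlet$unexplained_sulfate, 0, tolerance = 1e-9)
})

test_that("an infeasible scenario fails naming the starved zone", {
  cfg <- reactor_config(primary_donor = "acetate",
                        feed = c(acetate = 100),
                        yeast_extract_acetate_credit = 0)
  spec <- simulation_spec(kinetic = list(k = 1.5e-7, n = 2.9), config = cfg)
  err <- expect_error(simulate_donor_profiles(spec),
                      class = "sulfkin_infeasible")
  expect_match(conditionMessage(err), "zone")
})

test_that("observation tables are seed-deterministic and truth-faithful at cv = 0", {
  spec <- scenario_lactate_reactor(noise_cv = 0.05, replicates = 5)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  emit_observation_table(spec, p1, seed = 99, truth_path = NULL)
  emit_observation_table(spec, p2, seed = 99, truth_path = NULL)
  expect_identical(readLines(p1), readLines(p2))
  emit_observation_table(spec, p2, seed = 100, truth_path = NULL)
  expect_false(identical(readLines(p1), readLines(p2)))

  obs0 <- simulate_observations(noiseless_lactate(), seed = 1)
  truth <- simulate_donor_profiles(noiseless_lactate())
  key <- paste(obs0$dilution_rate, obs0$zone_boundary, obs0$analyte)
  tkey <- paste(truth$dilution_rate, truth$zone_boundary, truth$analyte)
  expect_equal(obs0$mean_conc, truth$conc_mg_l[match(key, tkey)],
               tolerance = 1e-12)
  expect_true(all(obs0$sd_conc == 0))
  # exclusion flags follow the scenario
  expect_setequal(unique(obs0$dilution_rate[obs0$excluded]), c(0.014, 0.016))
})

test_that("replicate noise has the nominal spread and never goes negative", {
  spec <- scenario_lactate_reactor(noise_cv = 0.05, replicates = 5)
  cvs <- c()
  for (seed in 1:60) {
    obs <- simulate_observations(spec, seed = seed)
    nz <- obs$mean_conc > 1   # cells with non-trivial truth
    expect_true(all(obs$mean_conc >= 0) && all(obs$sd_conc >= 0))
    cvs <- c(cvs, obs$sd_conc[nz] / obs$mean_conc[nz])
  }
  expect_gte(mean(cvs >= 0 & cvs <= 0.15), 0.95)
  expect_equal(median(cvs), 0.05, tolerance = 0.3)
})

test_that("full circle: emit -> load -> fit recovers the truth through files", {
  spec <- noiseless_lactate()
  path <- withr::local_tempfile(fileext = ".csv")
  emit_observation_table(spec, path, seed = 1,
                         truth_path = paste0(path, ".yml"))
  obs <- load_observations(path, spec$config)
  fit <- fit_kinetics(build_rate_points(obs, spec$config), order_fixed = 1)
  truth <- yaml::read_yaml(paste0(path, ".yml"))
  expect_equal(fit$k, truth$kinetic$k, tolerance = 1e-3)
  free <- fit_kinetics(build_rate_points(obs, spec$config))
  expect_lt(abs(free$n - truth$kinetic$n), 0.05)
})
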