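#' Specify a synthetic steady-state reactor scenario
#'
#' Bundles everything needed to generate synthetic observation tables with
#' the statistical and stoichiometric structure the analysis assumes: the
#' kinetic truth driving the sulfate profile, the dilution-rate ladder of
#' the HRT study, the reactor configuration (zones, feed), a per-dilution-
#' rate lactate-fermentation schedule, the measurement-noise model and the
#' replicate count.
#'
#' @param kinetic List with elements `k` and `n`: the true rate law
#'   \eqn{r = -k C^n} along the reactor.
#' @param config An [reactor_config()].
#' @param dilution_ladder Dilution rates (1/h), strictly increasing;
#'   defaults to the nine-step ladder 0.010-0.042 of the HRT study.
#' @param fermentation_schedule Tibble with columns `dilution_rate`,
#'   `net_propionate_mM`: net propionate produced by lactate fermentation
#'   in the inlet zone at each dilution rate. A scalar is recycled over
#'   the ladder. The schedule is an explicit input, not an emergent model:
#'   community dynamics are out of scope.
#' @param excluded_rates Dilution rates flagged `excluded` (non-steady
#'   transients after a rate step); carried in the table, filtered
#'   downstream.
#' @param noise_cv Relative SD of replicate measurements; scalar or named
#'   per-analyte vector. Gaussian, truncated at zero.
#' @param replicates Replicate samples per steady state (>= 1).
#' @param scenario Label recorded in outputs.
#' @return An object of class `srk_scenario`.
#' @seealso [scenario_lactate_reactor()], [scenario_acetate_reactor()]
#' @export
simulation_spec <- function(kinetic,
                            config = reactor_config(),
                            dilution_ladder = c(0.010, 0.014, 0.016, 0.018,
                                                0.021, 0.024, 0.028, 0.032,
                                                0.042),
                            fermentation_schedule = 0,
                            excluded_rates = numeric(),
                            noise_cv = 0.05,
                            replicates = 5,
                            scenario = "custom") {
  stopifnot(is.list(kinetic), all(c("k", "n") %in% names(kinetic)))
  if (kinetic$k < 0 || kinetic$n <= 0) {
    abort("kinetic truth requires k >= 0 and n > 0", class = "sulfkin_domain_error")
  }
  if (any(diff(dilution_ladder) <= 0)) {
    abort("dilution_ladder must be strictly increasing", class = "sulfkin_domain_error")
  }
  if (replicates < 1) abort("replicates must be >= 1", class = "sulfkin_domain_error")
  if (any(noise_cv < 0)) abort("noise_cv must be >= 0", class = "sulfkin_domain_error")
  if (is.numeric(fermentation_schedule) && !is.data.frame(fermentation_schedule)) {
    fermentation_schedule <- tibble::tibble(
      dilution_rate = dilution_ladder,
      net_propionate_mM = rep_len(fermentation_schedule, length(dilution_ladder))
    )
  }
  stopifnot(all(c("dilution_rate", "net_propionate_mM") %in%
                  names(fermentation_schedule)))
  structure(
    list(
      kinetic = kinetic, config = config, dilution_ladder = dilution_ladder,
      fermentation_schedule = fermentation_schedule,
      excluded_rates = excluded_rates, noise_cv = noise_cv,
      replicates = as.integer(replicates), scenario = scenario
    ),
    class = "srk_scenario"
  )
}

#' Named default scenarios for the two reactors
#'
#' `scenario_lactate_reactor()` carries the first-order truth
#' (`k = 0.06955` 1/h, `n = 1`) with 13.3 mM lactate feed, a fermentation
#' schedule of 2.3 mM net propionate (elevated to 4.6 and 3.9 mM at the
#' 0.014 and 0.016 1/h transients, which are flagged excluded).
#' `scenario_acetate_reactor()` carries the high-order truth (`n = 2.9`,
#' `k = 1.5e-7`) with 15.3 mM acetate feed, no fermentation, and the
#' 0.014 1/h transient excluded.
#'
#' @param noise_cv,replicates Passed to [simulation_spec()].
#' @return An `srk_scenario`.
#' @export
scenario_lactate_reactor <- function(noise_cv = 0.05, replicates = 5) {
  ladder <- c(0.010, 0.014, 0.016, 0.018, 0.021, 0.024, 0.028, 0.032, 0.042)
  sched <- tibble::tibble(
    dilution_rate = ladder,
    net_propionate_mM = dplyr::case_when(
      ladder == 0.014 ~ 4.6,
      ladder == 0.016 ~ 3.9,
      TRUE ~ 2.3
    )
  )
  simulation_spec(
    kinetic = list(k = 0.06955, n = 1),
    config = reactor_config(primary_donor = "lactate"),
    fermentation_schedule = sched,
    excluded_rates = c(0.014, 0.016),
    noise_cv = noise_cv, replicates = replicates,
    scenario = "lactate-reactor"
  )
}

#' @rdname scenario_lactate_reactor
#' @export
scenario_acetate_reactor <- function(noise_cv = 0.05, replicates = 5) {
  simulation_spec(
    kinetic = list(k = 1.5e-7, n = 2.9),
    config = reactor_config(primary_donor = "acetate"),
    fermentation_schedule = 0,
    excluded_rates = 0.014,
    noise_cv = noise_cv, replicates = replicates,
    scenario = "acetate-reactor"
  )
}

#' Noiseless sulfate profile along the reactor
#'
#' Evaluates the kinetic truth at every zone boundary of every dilution
#' rate: sulfate at cumulative volume `V` is
#' `pfr_outlet_concentration(C_feed, k, n, tau = V / (D * V_working))`.
#' Profiles are monotone non-increasing along the reactor.
#'
#' @param spec An [simulation_spec()].
#' @return A tibble with columns `dilution_rate`, `zone_boundary` (`feed`
#'   plus the zones), `cumulative_volume`, `sulfate_mg_l`, `sulfate_mM`.
#' @export
simulate_sulfate_profile <- function(spec) {
  stopifnot(inherits(spec, "srk_scenario"))
  cfg <- spec$config
  feed_s <- cfg$feed[["sulfate"]]
  grid <- tidyr::expand_grid(
    dilution_rate = spec$dilution_ladder,
    tibble::tibble(
      zone_boundary = c("feed", cfg$zones$name),
      cumulative_volume = c(0, cfg$zones$cumulative_volume)
    )
  )
  dplyr::mutate(
    grid,
    residence_time = .data$cumulative_volume /
      (.data$dilution_rate * cfg$working_volume),
    sulfate_mg_l = pfr_outlet_concentration(
      feed_s, spec$kinetic$k, spec$kinetic$n, .data$residence_time),
    sulfate_mM = to_mM(.data$sulfate_mg_l, "sulfate"),
    residence_time = NULL
  )
}

# Forward ledger for one dilution rate: walks the zones applying the same
# attribution rules in reverse (fermentation fixes propionate; lactate,
# then propionate, then acetate supply the sulfate demand; YE credit in
# the inlet). Returns state (mM) at each boundary or aborts as infeasible.
.simulate_donors_one <- function(spec, d, sulfate_mM_by_boundary) {
  cfg <- spec$config
  state <- c(
    lactate = to_mM(cfg$feed[["lactate"]], "lactate"),
    propionate = to_mM(cfg$feed[["propionate"]], "propionate"),
    acetate = to_mM(cfg$feed[["acetate"]], "acetate"),
    citrate = to_mM(cfg$feed[["citrate"]], "citrate"),
    sulfide = to_mM(cfg$feed[["sulfide"]], "sulfide")
  )
  sched <- spec$fermentation_schedule
  p_yield <- sched$net_propionate_mM[sched$dilution_rate == d]
  if (length(p_yield) == 0) p_yield <- 0
  out <- list(feed = state)
  for (zn in cfg$zones$name) {
    demand <- sulfate_mM_by_boundary[[.prev_boundary(zn, cfg)]] -
      sulfate_mM_by_boundary[[zn]]
    if (zn == "inlet") {
      if (state[["lactate"]] + 1e-12 < 1.5 * p_yield) {
        abort(sprintf(
          "infeasible scenario at D = %g 1/h, zone inlet: fermentation schedule needs %.3g mM lactate, %.3g available",
          d, 1.5 * p_yield, state[["lactate"]]), class = "sulfkin_infeasible")
      }
      state[["lactate"]] <- state[["lactate"]] - 1.5 * p_yield
      state[["propionate"]] <- state[["propionate"]] + p_yield
      state[["acetate"]] <- state[["acetate"]] + 0.5 * p_yield
      if (isTRUE(cfg$citrate_acetate_credit)) {
        state[["acetate"]] <- state[["acetate"]] + state[["citrate"]]
      }
      state[["citrate"]] <- 0
      state[["acetate"]] <- state[["acetate"]] +
        to_mM(cfg$yeast_extract_acetate_credit, "acetate")
    }
    lac_ox <- min(state[["lactate"]], demand / 0.5)
    state[["lactate"]] <- state[["lactate"]] - lac_ox
    state[["acetate"]] <- state[["acetate"]] + lac_ox
    demand <- demand - 0.5 * lac_ox
    prop_ox <- min(state[["propionate"]], demand / 0.75)
    state[["propionate"]] <- state[["propionate"]] - prop_ox
    state[["acetate"]] <- state[["acetate"]] + prop_ox
    demand <- demand - 0.75 * prop_ox
    ace_ox <- min(state[["acetate"]], demand)
    state[["acetate"]] <- state[["acetate"]] - ace_ox
    demand <- demand - ace_ox
    if (demand > 1e-9) {
      abort(sprintf(
        "infeasible scenario at D = %g 1/h, zone %s: %.3g mM sulfate demand exceeds electron-donor capacity",
        d, zn, demand), class = "sulfkin_infeasible")
    }
    state[["sulfide"]] <- state[["sulfide"]] +
      (sulfate_mM_by_boundary[[.prev_boundary(zn, cfg)]] -
         sulfate_mM_by_boundary[[zn]])
    out[[zn]] <- state
  }
  out
}

.prev_boundary <- function(zone, cfg) {
  i <- match(zone, cfg$zones$name)
  if (i == 1) "feed" else cfg$zones$name[i - 1]
}

#' Noiseless donor profiles consistent with the ledger
#'
#' Given the sulfate profile of a scenario, allocates lactate, propionate
#' and acetate at every zone boundary by running the attribution rules
#' forward: the fermentation schedule fixes propionate production in the
#' inlet zone, then lactate, propionate and acetate (in that order) supply
#' each zone's sulfate demand; the yeast-extract acetate credit enters in
#' the inlet zone and sulfide accumulates 1:1 with sulfate reduced. A
#' scenario whose sulfate demand exceeds total donor capacity fails with
#' an infeasibility error naming the zone.
#'
#' @param spec An [simulation_spec()].
#' @param sulfate_profile Output of [simulate_sulfate_profile()] (computed
#'   if omitted).
#' @return A long tibble: `dilution_rate`, `zone_boundary`, `analyte`,
#'   `conc_mM`, `conc_mg_l`, covering all six analytes at all boundaries.
#' @export
simulate_donor_profiles <- function(spec, sulfate_profile = NULL) {
  stopifnot(inherits(spec, "srk_scenario"))
  if (is.null(sulfate_profile)) sulfate_profile <- simulate_sulfate_profile(spec)
  rows <- purrr::map(spec$dilution_ladder, function(d) {
    prof_d <- dplyr::filter(sulfate_profile, .data$dilution_rate == d)
    s_by_boundary <- setNames(prof_d$sulfate_mM, prof_d$zone_boundary)
    states <- .simulate_donors_one(spec, d, as.list(s_by_boundary))
    purrr::imap(states, function(st, boundary) {
      tibble::tibble(
        dilution_rate = d,
        zone_boundary = boundary,
        analyte = c("sulfate", names(st)),
        conc_mM = c(s_by_boundary[[boundary]], unname(st))
      )
    }) |> dplyr::bind_rows()
  })
  res <- dplyr::bind_rows(rows)
  dplyr::mutate(res, conc_mg_l = to_mg_l(.data$conc_mM, .data$analyte))
}

#' Draw a synthetic steady-state observation table
#'
#' Applies the noise model to the noiseless truth: for every (dilution
#' rate, boundary, analyte) cell, `replicates` Gaussian draws with
#' relative SD `noise_cv` are truncated at zero and summarised to a mean
#' and SD, mirroring how steady-state tables arise from repeated
#' sampling. Rows at `excluded_rates` are flagged `steady = FALSE,
#' excluded = TRUE`.
#'
#' @param spec An [simulation_spec()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return An `srk_observations` tibble (the schema of
#'   [load_observations()]).
#' @export
simulate_observations <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "srk_scenario"))
  truth <- simulate_donor_profiles(spec)
  cv <- spec$noise_cv
  cv_for <- function(a) if (length(cv) > 1) unname(cv[a]) else cv
  set.seed(as.integer(seed))
  truth <- dplyr::arrange(truth, .data$dilution_rate,
                          match(.data$zone_boundary, c("feed", .ZONES)),
                          .data$analyte)
  reps <- spec$replicates
  drawn <- purrr::map2(truth$conc_mg_l, truth$analyte, function(mu, a) {
    x <- pmax(rnorm(reps, mean = mu, sd = cv_for(a) * mu), 0)
    c(mean(x), if (reps > 1) sd(x) else 0)
  })
  res <- tibble::tibble(
    dilution_rate = truth$dilution_rate,
    zone_boundary = truth$zone_boundary,
    analyte = truth$analyte,
    mean_conc = purrr::map_dbl(drawn, 1),
    sd_conc = purrr::map_dbl(drawn, 2),
    n_samples = reps,
    steady = !truth$dilution_rate %in% spec$excluded_rates,
    excluded = truth$dilution_rate %in% spec$excluded_rates,
    note = dplyr::if_else(
      truth$dilution_rate %in% spec$excluded_rates,
      "transient after dilution-rate step", "")
  )
  .as_observations(res)
}

#' Write a synthetic observation table and its truth sidecar
#'
#' Emits the delimited observation table ([write_observations()] schema)
#' plus a YAML sidecar recording the generating truth (scenario name,
#' kinetic parameters, ladder, feed, noise, seed) for recovery tests.
#' Identical seeds produce byte-identical files.
#'
#' @param spec An [simulation_spec()].
#' @param path Output path for the observation table.
#' @param seed Integer seed.
#' @param truth_path Optional path for the YAML truth sidecar (default
#'   `paste0(path, ".truth.yml")`).
#' @return `path`, invisibly.
#' @export
emit_observation_table <- function(spec, path, seed = 1,
                                   truth_path = paste0(path, ".truth.yml")) {
  obs <- simulate_observations(spec, seed = seed)
  write_observations(obs, path)
  truth <- list(
    scenario = spec$scenario,
    kinetic = list(k = spec$kinetic$k, n = spec$kinetic$n),
    dilution_ladder = as.numeric(spec$dilution_ladder),
    excluded_rates = as.numeric(spec$excluded_rates),
    noise_cv = as.numeric(spec$noise_cv),
    replicates = spec$replicates,
    seed = as.integer(seed),
    feed_mg_l = as.list(spec$config$feed)
  )
  if (!is.null(truth_path)) yaml::write_yaml(truth, truth_path)
  invisible(path)
}
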