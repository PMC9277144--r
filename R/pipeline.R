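#' Write a run manifest
#'
#' Records what produced the contents of an output directory: the command
#' label, the input/output files with MD5 hashes, the seed, the package
#' version and a timestamp. Each output directory holds exactly one
#' manifest (`manifest.json`, overwritten on rerun).
#'
#' @param out_dir Output directory.
#' @param command Command label (e.g. `"simulate"`).
#' @param files Paths to hash into the manifest.
#' @param seed Seed used, if any.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, command, files = character(), seed = NULL) {
  files <- files[file.exists(files)]
  manifest <- list(
    command = command,
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files))),
    seed = seed,
    package = "sulfkin",
    version = as.character(packageVersion("sulfkin")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Simulate a scenario to disk
#'
#' Generates the observation table and truth sidecar for a scenario and
#' records a manifest. The front door for producing synthetic datasets
#' from the shell or a script.
#'
#' @param spec An [simulation_spec()] (or the name of a built-in scenario,
#'   `"lactate-reactor"` or `"acetate-reactor"`).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with the observation and truth paths.
#' @export
run_simulation <- function(spec, out_dir, seed = 1) {
  if (is.character(spec)) {
    spec <- switch(spec,
      "lactate-reactor" = scenario_lactate_reactor(),
      "acetate-reactor" = scenario_acetate_reactor(),
      abort(paste0("unknown scenario '", spec, "'"), class = "sulfkin_usage_error")
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obs_path <- file.path(out_dir, "observations.csv")
  truth_path <- file.path(out_dir, "truth.yml")
  emit_observation_table(spec, obs_path, seed = seed, truth_path = truth_path)
  write_manifest(out_dir, "simulate", c(obs_path, truth_path), seed = seed)
  invisible(list(observations = obs_path, truth = truth_path))
}

#' Fit plug-flow kinetics to an observation table
#'
#' Builds rate points, fits the rate law, and (optionally) writes the fit
#' summary (JSON) and the banded model curve (CSV) plus a manifest.
#' Machine-readable outputs carry full precision; rounding happens only in
#' the human-readable report.
#'
#' @param observations An observation tibble or a path to one.
#' @param config An [reactor_config()].
#' @param order_fixed Fix the reaction order (e.g. 1), or `NULL` to fit it.
#' @param dataset `"joint"` (default: all three cumulative segments) or
#'   one of `"inlet"`, `"composite"`, `"whole"`.
#' @param out_dir Optional output directory.
#' @param band_points Number of F/V grid points for the confidence band.
#' @return A list with elements `fit` (`srk_fit`), `summary` (named list),
#'   `band` (tibble) and `points` (tibble).
#' @export
run_fit <- function(observations, config = reactor_config(),
                    order_fixed = NULL, dataset = "joint", out_dir = NULL,
                    band_points = 50) {
  if (is.character(observations)) {
    observations <- load_observations(observations, config)
  }
  datasets <- if (identical(dataset, "joint")) {
    c("inlet", "composite", "whole")
  } else dataset
  n_excluded <- length(unique(
    observations$dilution_rate[observations$excluded &
                                 observations$analyte == "sulfate"]))
  points <- build_rate_points(observations, config, datasets = datasets)
  fit <- fit_kinetics(points, order_fixed = order_fixed)
  summary <- list(
    k = fit$k, n = fit$n, k_units = fit$k_units,
    order_fixed = fit$order_fixed, sse = fit$sse, r2 = fit$r2, se = fit$se,
    dof = fit$dof, t_crit = fit$t_crit, n_points = fit$n_points,
    n_excluded_steady_states = n_excluded, dataset = dataset
  )
  band <- if (!is.na(fit$dof) && fit$dof >= 1) {
    fv <- seq(min(points$flow_per_volume), max(points$flow_per_volume),
              length.out = band_points)
    confidence_band(fit, c0 = max(points$c0), fv_grid = fv)
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fit_path <- file.path(out_dir, "fit.json")
    jsonlite::write_json(summary, fit_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    curve_path <- file.path(out_dir, "curve.csv")
    if (!is.null(band)) readr::write_csv(band, curve_path)
    write_manifest(out_dir, "fit", c(fit_path, curve_path))
  }
  list(fit = fit, summary = summary, band = band, points = points)
}

#' Run the donor mass balance over an observation table
#'
#' Chains the zone-wise attribution across all steady states, derives the
#' predicted-vs-observed acetate profile and its zone-averaged percent
#' differences, and optionally writes the ledger table, the acetate
#' report and a manifest.
#'
#' @inheritParams run_fit
#' @param chaining `"observed"` or `"predicted"` upstream acetate
#'   (see [attribute_observations()]).
#' @return A list with `balance` (ledger tibble), `profile` (acetate
#'   profile tibble) and `pct_diff` (list of `per_point`, `per_zone`).
#' @export
run_balance <- function(observations, config = reactor_config(),
                        chaining = "observed", out_dir = NULL) {
  if (is.character(observations)) {
    observations <- load_observations(observations, config)
  }
  balance <- attribute_observations(observations, config, chaining = chaining)
  profile <- predict_acetate_profile(balance)
  pct <- percent_difference_profile(profile)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    bal_path <- file.path(out_dir, "balance.csv")
    flat <- dplyr::mutate(
      balance,
      deficit_flags = purrr::map_chr(.data$deficit_flags, paste, collapse = "; "))
    readr::write_csv(flat, bal_path)
    ace_path <- file.path(out_dir, "acetate_report.csv")
    readr::write_csv(pct$per_point, ace_path)
    zone_path <- file.path(out_dir, "acetate_zone_summary.json")
    jsonlite::write_json(pct$per_zone, zone_path, digits = NA)
    write_manifest(out_dir, "balance", c(bal_path, ace_path, zone_path))
  }
  list(balance = balance, profile = profile, pct_diff = pct)
}

#' Consolidated human-readable report
#'
#' Renders the kinetic fit and the donor balance into one plain-text
#' report. Missing sections are marked absent rather than failing;
#' regenerating the report from the same inputs is idempotent. Display
#' values are rounded here and only here.
#'
#' @param fit Result of [run_fit()], or `NULL`.
#' @param balance Result of [run_balance()], or `NULL`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
run_report <- function(fit = NULL, balance = NULL, path) {
  lines <- c("sulfate-reducing UAPBR analysis report",
             strrep("=", 40), "")
  lines <- c(lines, "## Plug-flow kinetic fit", "")
  if (is.null(fit)) {
    lines <- c(lines, "(section absent: no fit supplied)", "")
  } else {
    s <- fit$summary
    lines <- c(lines,
      sprintf("  rate law: r = -k C^n, %s",
              if (s$order_fixed) sprintf("order fixed at n = %.4g", s$n)
              else sprintf("fitted order n = %.4g", s$n)),
      sprintf("  k = %.5g %s", s$k, s$k_units),
      sprintf("  SSE = %.6g, R2 = %s, SE = %s, dof = %d",
              s$sse,
              ifelse(is.na(s$r2), "NA", sprintf("%.4f", s$r2)),
              ifelse(is.na(s$se), "NA", sprintf("%.4g", s$se)), s$dof),
      sprintf("  points: %d (excluded steady states: %d)",
              s$n_points, s$n_excluded_steady_states),
      "")
  }
  lines <- c(lines, "## Electron-donor mass balance", "")
  if (is.null(balance)) {
    lines <- c(lines, "(section absent: no balance supplied)", "")
  } else {
    pz <- balance$pct_diff$per_zone
    lines <- c(lines, "  observed vs predicted acetate, mean % difference by zone:")
    lines <- c(lines, sprintf("    %-9s %6.1f %% (n = %d)",
                              pz$zone, pz$mean_pct_diff, pz$n_used))
    deficits <- dplyr::filter(balance$balance, .data$unexplained_sulfate > 1e-9)
    if (nrow(deficits) > 0) {
      lines <- c(lines, "", "  electron-donor deficits:")
      lines <- c(lines, sprintf("    D = %.3g 1/h, %s: %.3g mM unexplained",
                                deficits$dilution_rate, deficits$zone,
                                deficits$unexplained_sulfate))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
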