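# Noiseless single-replicate scenarios used across the suite
noiseless_lactate <- function() scenario_lactate_reactor(noise_cv = 0, replicates = 1)
noiseless_acetate <- function() scenario_acetate_reactor(noise_cv = 0, replicates = 1)

# One observation row in the internal (post-load) schema
obs_row <- function(d, boundary, analyte, conc, excluded = FALSE, sd = 0, n = 5) {
  tibble::tibble(
    dilution_rate = d, zone_boundary = boundary, analyte = analyte,
    mean_conc = conc, sd_conc = sd, n_samples = as.integer(n),
    steady = !excluded, excluded = excluded, note = ""
  )
}

# Sulfate observations (feed + three zone outlets) for one steady state
sulfate_state <- function(d, feed, inlet, middle, effluent, excluded = FALSE) {
  dplyr::bind_rows(
    obs_row(d, "feed", "sulfate", feed, excluded),
    obs_row(d, "inlet", "sulfate", inlet, excluded),
    obs_row(d, "middle", "sulfate", middle, excluded),
    obs_row(d, "effluent", "sulfate", effluent, excluded)
  )
}

# Independent brute-force oracle: minimum SSE over a 40 x 40 grid of
# log10(k) x n, on the same bounds the fitter searches.
grid_search_sse <- function(pts, lk_bounds = c(-12, 3), n_bounds = c(0.2, 6),
                            m = 40) {
  lks <- seq(lk_bounds[1], lk_bounds[2], length.out = m)
  ns <- seq(n_bounds[1], n_bounds[2], length.out = m)
  best <- Inf
  for (lk in lks) {
    for (nn in ns) {
      sse <- sum((pts$y - mean_rate(pts$c0, 10^lk, nn, pts$flow_per_volume))^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# Adaptive numeric integration of dC/dtau = -k C^n (independent of the
# closed-form implementation under test)
numeric_pfr_outlet <- function(c0, k, n, tau) {
  f <- function(t, y, p) list(-k * max(y, 0)^n)
  deSolve::ode(c0, c(0, tau), f, NULL, rtol = 1e-10, atol = 1e-10)[2, 2]
}
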