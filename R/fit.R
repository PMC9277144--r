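#' Goodness-of-fit statistics for a rate-law fit
#'
#' Computes the sum of squared errors `SSE = sum((y - yfit)^2)`, the
#' coefficient of determination `R^2 = 1 - SSE / sum((y - mean(y))^2)`, the
#' residual degrees of freedom `dof = N - n_params`, the standard error
#' `SE = sqrt(SSE / dof)` and the two-tailed 95% Student-t critical value
#' at `dof`.
#'
#' @param y Observed rates.
#' @param yfit Fitted rates (same length).
#' @param n_params Number of fitted parameters (1 for fixed order, 2 free).
#' @return A one-row tibble with columns `sse`, `r2`, `se`, `dof`, `t_crit`.
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4), n_params = 1)
#' @export
goodness_of_fit <- function(y, yfit, n_params) {
  if (length(y) != length(yfit)) {
    abort("y and yfit must have the same length", class = "sulfkin_domain_error")
  }
  if (length(y) < n_params + 1) {
    abort("need at least n_params + 1 observations", class = "sulfkin_data_error")
  }
  sse <- sum((y - yfit)^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0 && sse > 0) {
    abort("R^2 is undefined: observed rates have zero variance but nonzero SSE",
          class = "sulfkin_degenerate_fit")
  }
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  dof <- length(y) - n_params
  se <- sqrt(sse / dof)
  tibble::tibble(sse = sse, r2 = r2, se = se, dof = dof,
                 t_crit = qt(0.975, dof))
}

# Closed-form rate constant that maps c0 -> ca in residence time tau at
# order n. Used for exact single-point fits and to seed the optimizer.
.invert_k <- function(c0, ca, n, tau) {
  if (ca >= c0) return(0)
  if (n == 1) return(-log(ca / c0) / tau)
  (ca^(1 - n) - c0^(1 - n)) / ((n - 1) * tau)
}

.sse_kn <- function(k, n, pts) {
  sum((pts$y - mean_rate(pts$c0, k, n, pts$flow_per_volume))^2)
}

#' Fit first-order or nth-order plug-flow kinetics
#'
#' Estimates the rate constant `k` (and, unless `order_fixed` is given, the
#' reaction order `n`) of the rate law \eqn{r = -k C^n} by nonlinear least
#' squares against observed segment-mean rates, using the analytic
#' plug-flow model curve of [mean_rate()]. Because `k` and `n` are strongly
#' correlated, the free-order fit screens a coarse grid of starting values
#' (orders 0.5-4 in steps of 0.5 crossed with `log10 k` from -9 to 0,
#' augmented with closed-form `k` seeds from the data) and polishes at
#' least `n_starts` of the best candidates with bounded quasi-Newton
#' (L-BFGS-B) minimisation of the SSE; ties go to the smaller order.
#'
#' @param points Rate-point tibble from [build_rate_points()] (columns
#'   `flow_per_volume`, `c0`, `y` required).
#' @param order_fixed If non-`NULL`, hold the reaction order at this value
#'   and fit only `k` (e.g. `order_fixed = 1` for a first-order fit).
#' @param n_starts Minimum number of local optimizations for the
#'   free-order fit (>= 8 recommended; default 8).
#' @param order_bounds Search bounds for the free reaction order.
#' @return An object of class `srk_fit`: a list with elements `k`, `n`,
#'   `order_fixed`, `sse`, `r2`, `se`, `dof`, `t_crit`, `n_points`,
#'   `trace` (multi-start summary tibble), `flags` and `data`.
#'   [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [autoplot()][ggplot2::autoplot] methods are provided.
#' @examples
#' cfg <- reactor_config("demo", primary_donor = "lactate")
#' pts <- tibble::tibble(
#'   dilution_rate = 0.042, flow_per_volume = c(0.042 / 0.33, 0.042 / 0.66, 0.042),
#'   c0 = 1000,
#'   ca = pfr_outlet_concentration(1000, 0.07, 1, 1 / c(0.042 / 0.33, 0.042 / 0.66, 0.042))
#' )
#' pts$y <- pts$flow_per_volume * (pts$c0 - pts$ca)
#' fit_kinetics(pts, order_fixed = 1)
#' @export
fit_kinetics <- function(points, order_fixed = NULL, n_starts = 8,
                         order_bounds = c(0.2, 6)) {
  req <- c("flow_per_volume", "c0", "y")
  if (!all(req %in% names(points))) {
    abort(paste0("points must have columns: ", paste(req, collapse = ", ")),
          class = "sulfkin_data_error")
  }
  pts <- dplyr::filter(points, !is.na(.data$y))
  np <- nrow(pts)
  free_order <- is.null(order_fixed)
  n_params <- if (free_order) 2L else 1L
  min_pts <- if (free_order) 3L else 1L
  if (np < min_pts) {
    abort(sprintf("insufficient data: %d point(s), need >= %d", np, min_pts),
          class = "sulfkin_data_error")
  }
  if (all(pts$y == 0)) {
    abort("degenerate fit: all observed rates are zero (k = 0)",
          class = "sulfkin_degenerate_fit", k = 0)
  }

  flags <- character()
  log_k_bounds <- c(-12, 3)

  if (!free_order) {
    n_fix <- order_fixed
    if (n_fix <= 0) abort("order_fixed must be > 0", class = "sulfkin_domain_error")
    if (np == 1) {
      # exact interpolation through the single point
      ca_target <- pts$c0 - pts$y / pts$flow_per_volume
      k_hat <- .invert_k(pts$c0, max(ca_target, 0), n_fix, 1 / pts$flow_per_volume)
      best <- list(k = k_hat, n = n_fix, sse = 0)
      trace <- tibble::tibble(start_log10k = NA_real_, start_n = n_fix,
                              k = k_hat, n = n_fix, sse = 0)
    } else {
      opt <- optimize(function(lk) .sse_kn(10^lk, n_fix, pts),
                      interval = log_k_bounds, tol = 1e-12)
      # polish: optimize() can stall on flat stretches of a log axis
      pol <- optim(opt$minimum, function(lk) .sse_kn(10^lk, n_fix, pts),
                   method = "Brent", lower = opt$minimum - 0.5,
                   upper = opt$minimum + 0.5)
      best <- list(k = 10^pol$par, n = n_fix, sse = pol$value)
      trace <- tibble::tibble(start_log10k = opt$minimum, start_n = n_fix,
                              k = best$k, n = n_fix, sse = best$sse)
    }
  } else {
    n_grid <- seq(0.5, 4, by = 0.5)
    lk_grid <- seq(-9, 0, by = 1)
    starts <- tidyr::expand_grid(n0 = n_grid, lk0 = lk_grid)
    # data-driven seeds: closed-form k through the median-removal point
    mid <- pts[order(pts$y)[ceiling(np / 2)], ]
    seed_k <- vapply(n_grid, function(nn) {
      ca <- max(mid$c0 - mid$y / mid$flow_per_volume, 1e-6)
      max(.invert_k(mid$c0, ca, nn, 1 / mid$flow_per_volume), 1e-12)
    }, numeric(1))
    starts <- dplyr::bind_rows(starts,
                               tibble::tibble(n0 = n_grid, lk0 = log10(seed_k)))
    starts$sse0 <- purrr::map2_dbl(starts$lk0, starts$n0,
                                   function(lk, nn) .sse_kn(10^lk, nn, pts))
    starts <- dplyr::arrange(starts, .data$sse0)
    n_polish <- max(n_starts, 8)
    cand <- head(starts, n_polish)

    runs <- purrr::pmap(list(cand$lk0, cand$n0), function(lk0, n0) {
      res <- tryCatch(
        optim(c(lk0, n0),
              function(p) .sse_kn(10^p[1], p[2], pts),
              method = "L-BFGS-B",
              lower = c(log_k_bounds[1], order_bounds[1]),
              upper = c(log_k_bounds[2], order_bounds[2]),
              control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL
      )
      if (is.null(res)) return(NULL)
      tibble::tibble(start_log10k = lk0, start_n = n0,
                     k = 10^res$par[1], n = res$par[2], sse = res$value)
    })
    trace <- dplyr::bind_rows(runs)
    if (nrow(trace) == 0) {
      abort("all optimizer starts failed", class = "sulfkin_fit_error")
    }
    # lowest SSE wins; near-ties (1e-8 relative) break toward smaller order
    trace <- dplyr::arrange(trace, .data$sse, .data$n)
    tol <- 1e-8 * max(trace$sse[1], .Machine$double.eps)
    tied <- trace[trace$sse <= trace$sse[1] + tol, ]
    best <- as.list(tied[which.min(tied$n), c("k", "n", "sse")])
  }

  yfit <- mean_rate(pts$c0, best$k, best$n, pts$flow_per_volume)
  if (np > n_params) {
    gof <- goodness_of_fit(pts$y, yfit, n_params)
  } else {
    gof <- tibble::tibble(sse = best$sse, r2 = NA_real_, se = NA_real_,
                          dof = 0L, t_crit = NA_real_)
    flags <- c(flags, "saturated: no residual degrees of freedom")
  }

  structure(
    list(
      k = best$k, n = best$n, order_fixed = !free_order,
      sse = gof$sse, r2 = gof$r2, se = gof$se, dof = gof$dof,
      t_crit = gof$t_crit, n_points = np,
      k_units = if (best$n == 1) "1/h"
                else sprintf("mg^%.4g L^%.4g 1/h", 1 - best$n, best$n - 1),
      trace = trace, flags = flags, data = pts
    ),
    class = "srk_fit"
  )
}

#' @export
print.srk_fit <- function(x, ...) {
  cat("<srk_fit> plug-flow ",
      if (x$order_fixed) sprintf("order-%g (fixed)", x$n)
      else sprintf("nth-order (n = %.3g)", x$n),
      " rate-law fit\n", sep = "")
  cat(sprintf("  k = %.5g %s\n", x$k, x$k_units))
  cat(sprintf("  SSE = %.5g, R2 = %s, SE = %s (dof = %d, %d points)\n",
              x$sse,
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)),
              ifelse(is.na(x$se), "NA", sprintf("%.4g", x$se)),
              x$dof, x$n_points))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fitted model curve with 95% confidence band
#'
#' Evaluates the fitted segment-mean rate curve over a grid of
#' flow-to-volume ratios and attaches the two-sided 95% confidence band
#' `fit +/- t_crit * SE`, with the half-width constant in rate units.
#'
#' @param fit An `srk_fit` from [fit_kinetics()].
#' @param c0 Inlet concentration (mg/L) at which to evaluate the curve.
#' @param fv_grid Grid of flow-per-volume values (1/h).
#' @return A tibble with columns `flow_per_volume`, `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(fit, c0, fv_grid) {
  stopifnot(inherits(fit, "srk_fit"))
  if (is.na(fit$dof) || fit$dof < 1) {
    abort("confidence band requires at least one residual degree of freedom",
          class = "sulfkin_data_error")
  }
  f <- mean_rate(c0, fit$k, fit$n, fv_grid)
  half <- fit$t_crit * fit$se
  tibble::tibble(flow_per_volume = fv_grid, fit = f,
                 lwr = f - half, upr = f + half)
}
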