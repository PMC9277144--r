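#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a plug-flow kinetic fit
#'
#' @param x An `srk_fit` from [fit_kinetics()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`k`, and `n` when fitted):
#'   `term`, `estimate`, `fixed`, `units`.
#' @export
tidy.srk_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "n"),
    estimate = c(x$k, x$n),
    fixed = c(FALSE, x$order_fixed),
    units = c(x$k_units, "dimensionless")
  )
}

#' Glance at a plug-flow kinetic fit
#'
#' @param x An `srk_fit` from [fit_kinetics()].
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n`, `order_fixed`, `sse`, `r2`, `se`,
#'   `dof`, `t_crit`, `n_points`.
#' @export
glance.srk_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = x$n, order_fixed = x$order_fixed, sse = x$sse, r2 = x$r2,
    se = x$se, dof = x$dof, t_crit = x$t_crit, n_points = x$n_points
  )
}
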