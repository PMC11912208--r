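#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a MASH trajectory into long format
#'
#' @param x a `mash_trajectory`.
#' @param variables columns to pivot; defaults to all phase-space columns.
#' @param ... unused.
#' @return long tibble with columns `t`, `variable`, `value`.
#' @export
tidy.mash_trajectory <- function(x, variables = NULL, ...) {
  df <- tibble::as_tibble(x)
  if (is.null(variables))
    variables <- setdiff(names(df), "t")
  tidyr::pivot_longer(df[, c("t", variables)], -"t",
                      names_to = "variable", values_to = "value")
}

#' One-row summary of a MASH trajectory
#'
#' @param x a `mash_trajectory`.
#' @param ... unused.
#' @return tibble with the method, step, number of steps, hop counts,
#'   energy drift over the run, and mean root-search iterations per hop.
#' @export
glance.mash_trajectory <- function(x, ...) {
  h <- hops(x)
  tibble::tibble(
    method = attr(x, "method"),
    dt = attr(x, "dt"),
    n_steps = round(abs((x$t[nrow(x)] - x$t[1]) / attr(x, "dt"))),
    n_hops = nrow(h),
    n_accepted = sum(h$kind == "accepted"),
    n_frustrated = sum(h$kind == "frustrated"),
    energy_drift = max(abs(x$energy - x$energy[1])),
    mean_root_iters = if (nrow(h) > 0) mean(h$root_iters) else NA_real_)
}

#' Fitted slopes of an order scan
#'
#' @param x a `mash_order_scan`.
#' @param ... unused.
#' @return the [order_slope()] table.
#' @export
glance.mash_order_scan <- function(x, ...) order_slope(x)

#' @export
tidy.mash_order_scan <- function(x, ...) tibble::as_tibble(x)

#' Plot a MASH trajectory
#'
#' @param object a `mash_trajectory`.
#' @param variables columns to facet.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mash_trajectory <- function(object, variables = c("q", "p", "Sz", "energy"),
                                     ...) {
  variables <- intersect(variables, names(object))
  ggplot2::ggplot(tidy.mash_trajectory(object, variables),
                  ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = hops(object)$t, linetype = 3,
                        colour = "grey40") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "t (a.u.)", y = NULL)
}

#' Plot an order scan on log-log axes
#'
#' @param object a `mash_order_scan`.
#' @param ... unused.
#' @return a ggplot of global error vs time-step per method and variable.
#' @export
autoplot.mash_order_scan <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$dt, y = .data$error,
                               colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~variable) +
    ggplot2::labs(x = expression(Delta * t ~ "(a.u.)"), y = "global error")
}

#' Plot ensemble populations with error bands
#'
#' @param object a population table from [adiabatic_populations()] or
#'   [diabatic_populations()].
#' @param band half-width of the error band in standard errors.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_populations <- function(object, band = 3, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$population,
                                       colour = .data$state,
                                       fill = .data$state)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$population - band * .data$se,
                                      ymax = .data$population + band * .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (a.u.)", y = "population")
}
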