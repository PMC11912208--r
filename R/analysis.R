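#' Global error of a trajectory against a benchmark
#'
#' Maximum absolute deviation of a phase-space variable over the time points
#' shared with a benchmark trajectory run at a much smaller time-step.
#'
#' @param traj,benchmark `mash_trajectory` objects on grids that share time
#'   points (the benchmark grid must contain the trajectory's).
#' @param variable column to compare (e.g. `"p"`, `"Sz"`, `"q"`).
#' @param norm `"max"` (default) or `"rms"` over the shared grid.
#' @return non-negative scalar; zero iff the trajectories agree on the grid.
#' @export
global_error <- function(traj, benchmark, variable, norm = c("max", "rms")) {
  norm <- match.arg(norm)
  tol <- max(1e-9, 1e-9 * max(abs(benchmark$t)))
  idx <- vapply(traj$t, function(tt) {
    j <- which(abs(benchmark$t - tt) <= tol)
    if (length(j) == 0L) NA_integer_ else j[1]
  }, integer(1))
  if (anyNA(idx))
    stop("trajectory and benchmark share no common grid at some time points",
         call. = FALSE)
  dev <- abs(traj[[variable]] - benchmark[[variable]][idx])
  if (norm == "max") max(dev) else sqrt(mean(dev^2))
}

#' Convergence-order scan over a time-step ladder
#'
#' Runs each method over a geometric ladder of time-steps, computes global
#' errors against a shared benchmark trajectory (by default `rev-pc-ld` at
#' `min(dts) / benchmark_ratio`, where every method agrees), and fits the
#' order of the global error as the log-log slope.
#'
#' @inheritParams propagate
#' @param methods methods to scan (default: all eight).
#' @param dts decreasing ladder of time-steps; each must be an integer
#'   multiple of the smallest so that all grids align with the benchmark.
#' @param variables trajectory columns to measure.
#' @param benchmark_ratio benchmark time-step divisor.
#' @param norm error norm passed to [global_error()].
#' @return a `mash_order_scan` tibble with columns `method`, `variable`,
#'   `dt`, `error`; fitted slopes are available via [order_slope()] /
#'   [glance()] and the benchmark is stored as an attribute.
#' @export
order_scan <- function(model, ic, dts, t_max, methods = mash_methods(),
                       variables = c("p", "Sz"), benchmark_ratio = 350,
                       xi = 1e-4, max_root_iters = 10L, swap_tol = 0.1,
                       norm = "max") {
  dts <- sort(dts, decreasing = TRUE)
  dt_min <- min(dts)
  mult <- dts / dt_min
  if (any(abs(mult - round(mult)) > 1e-8))
    stop("every dt must be an integer multiple of the smallest", call. = FALSE)
  dt_b <- dt_min / benchmark_ratio
  bench <- propagate(model, ic, dt_b, t_max, method = "rev-pc-ld",
                     record_every = as.integer(benchmark_ratio), xi = xi,
                     max_root_iters = max_root_iters, swap_tol = swap_tol)
  res <- purrr::map_dfr(methods, function(m) {
    purrr::map_dfr(dts, function(dt) {
      tr <- propagate(model, ic, dt, t_max, method = m, record_every = 1L,
                      xi = xi, max_root_iters = max_root_iters,
                      swap_tol = swap_tol)
      tibble::tibble(method = m, variable = variables,
                     dt = dt,
                     error = unname(vapply(variables, function(v)
                       global_error(tr, bench, v, norm = norm), numeric(1))))
    })
  })
  structure(res, class = c("mash_order_scan", class(res)),
            benchmark = bench, benchmark_dt = dt_b, norm = norm)
}

#' Fitted order of the global error
#'
#' Least-squares slope of `log(error)` versus `log(dt)` per method and
#' variable, excluding points at the round-off floor (`error < 1e-12`) or
#' outside the asymptotic regime (`error` above 10 percent of the
#' variable's scale, taken as its range over the benchmark trajectory).
#'
#' @param scan a [order_scan()] result (or any tibble with columns
#'   `method`, `variable`, `dt`, `error`).
#' @param scales optional named vector of variable scales; defaults to the
#'   benchmark range stored in the scan.
#' @return tibble with columns `method`, `variable`, `slope`, `n_points`.
#' @export
order_slope <- function(scan, scales = NULL) {
  bench <- attr(scan, "benchmark")
  get_scale <- function(v) {
    if (!is.null(scales) && v %in% names(scales)) return(scales[[v]])
    if (!is.null(bench)) return(diff(range(bench[[v]])))
    Inf
  }
  dplyr::reframe(
    dplyr::group_by(tibble::as_tibble(scan), .data$method, .data$variable),
    {
      ok <- .data$error > 1e-12 & .data$error < 0.1 * get_scale(.data$variable[1])
      if (sum(ok) < 3)
        stop("fewer than 3 usable ladder points for ", .data$method[1], "/",
             .data$variable[1], call. = FALSE)
      fit <- stats::lm(log(.data$error[ok]) ~ log(.data$dt[ok]))
      tibble::tibble(slope = unname(stats::coef(fit)[2]), n_points = sum(ok))
    })
}

#' Forward-backward reversibility diagnostic
#'
#' Propagates forward for `t_max`, flips `(p, Sy)`, propagates backward with
#' the same method and step, and reports the maximum deviation between the
#' time-reflected backward trajectory and the forward one, normalized by
#' each variable's range over the forward trajectory.
#'
#' @inheritParams propagate
#' @param variables columns to compare.
#' @return tibble with columns `variable`, `deviation` (relative), plus the
#'   forward/backward trajectories as attributes.
#' @export
reversibility_check <- function(model, ic, dt, t_max, method,
                                variables = c("q", "p", "Sz"),
                                record_every = 1L, xi = 1e-4,
                                max_root_iters = 10L, swap_tol = 0.1) {
  fwd <- propagate(model, ic, dt, t_max, method = method,
                   record_every = record_every, xi = xi,
                   max_root_iters = max_root_iters, swap_tol = swap_tol)
  bwd <- propagate(model, final_state(fwd, flip = TRUE), dt, t_max,
                   method = method, record_every = record_every, xi = xi,
                   max_root_iters = max_root_iters, swap_tol = swap_tol)
  res <- reversibility_deviation(fwd, bwd, variables)
  attr(res, "forward") <- fwd
  attr(res, "backward") <- bwd
  res
}

#' Deviation between a forward and a (flipped) backward trajectory
#'
#' The backward trajectory is time-reflected, its momenta and `Sy` are
#' unflipped, and each variable is compared point-by-point with the forward
#' trajectory, normalized by the variable's forward range.
#'
#' @param forward,backward `mash_trajectory` objects on the same grid; the
#'   backward run starts from the flipped final state of the forward run.
#' @param variables columns to compare.
#' @return tibble with columns `variable`, `deviation`.
#' @export
reversibility_deviation <- function(forward, backward,
                                    variables = c("q", "p", "Sz")) {
  n <- nrow(forward)
  if (nrow(backward) != n)
    stop("forward and backward trajectories must share a grid", call. = FALSE)
  flip_sign <- function(v) if (grepl("^p", v) || v == "Sy") -1 else 1
  purrr::map_dfr(variables, function(v) {
    fb <- rev(flip_sign(v) * backward[[v]])
    rng <- diff(range(forward[[v]]))
    if (rng == 0) rng <- max(abs(forward[[v]]), 1)
    tibble::tibble(variable = v,
                   deviation = max(abs(fb - forward[[v]])) / rng)
  })
}
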