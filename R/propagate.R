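#' Phase-space initial condition
#'
#' @param q,p nuclear positions and momenta (length = degrees of freedom).
#' @param S Bloch spin vector `c(Sx, Sy, Sz)`; normalized to unit length
#'   when `normalize = TRUE` (the MASH spin lives on the unit sphere).
#' @param normalize normalize `S` to unit length?
#' @return a `mash_ic` list.
#' @export
mash_ic <- function(q, p, S, normalize = TRUE) {
  S <- as.numeric(S)
  if (normalize) S <- S / sqrt(sum(S^2))
  structure(list(q = as.numeric(q), p = as.numeric(p), S = S),
            class = "mash_ic")
}

as_mash_ic <- function(ic) {
  if (inherits(ic, "mash_ic")) return(ic)
  if (is.list(ic) && all(c("q", "p", "S") %in% names(ic)))
    return(mash_ic(ic$q, ic$p, ic$S, normalize = FALSE))
  if (is.data.frame(ic) && nrow(ic) == 1L) {
    qc <- grep("^q[0-9]*$", names(ic), value = TRUE)
    pc <- grep("^p[0-9]*$", names(ic), value = TRUE)
    return(mash_ic(as.numeric(ic[1, qc]), as.numeric(ic[1, pc]),
                   c(ic$Sx, ic$Sy, ic$Sz), normalize = FALSE))
  }
  stop("initial condition must be a mash_ic, a list(q, p, S), or a one-row data frame",
       call. = FALSE)
}

#' Propagate a MASH trajectory
#'
#' Integrates the coupled nuclear (velocity-Verlet) and Bloch-spin dynamics
#' with the chosen method, processing hops deterministically whenever the
#' spin crosses the equator. A negative `dt` (or `t_max`) propagates
#' backward in time by flipping `p` and `Sy`, running forward, and mapping
#' the result back, which is exact for every method in the family.
#'
#' @param model a [tully_model()] or [lvc_model()].
#' @param ic initial condition: a [mash_ic()], a `list(q, p, S)`, or a
#'   one-row data frame with columns `q*`, `p*`, `Sx`, `Sy`, `Sz`. The
#'   active surface is the hemisphere of `Sz`.
#' @param dt time-step (atomic units; negative for backward propagation).
#' @param t_max propagation time (atomic units); the number of steps is
#'   `round(t_max / dt)`.
#' @param method one of [mash_methods()].
#' @param record_every record every k-th step (the initial and final states
#'   are always recorded).
#' @param xi equator error band for the piecewise-continuous hop-time root
#'   search: the search stops once `|Sz(tau)| <= xi`.
#' @param max_root_iters maximum sub-step propagations per root search.
#' @param e_tol energy-conservation threshold for variable time-stepping;
#'   steps whose energy change exceeds it are undone and recursively
#'   bisected. `0` (default) disables variable stepping.
#' @param swap_tol overlap-diagonal threshold below which a step is
#'   rejected as a state-character swap (see [wf_overlap()]); set to 0 to
#'   tolerate trivial crossings (the rotation angle is then clamped to the
#'   principal branch).
#' @param t0 time of the initial state.
#' @return a `mash_trajectory`: a tibble with columns `t`, positions,
#'   momenta, `Sx`, `Sy`, `Sz`, `active`, `energy` and the local
#'   adiabatic-diabatic mixing angle `theta`, with the hop log, method and
#'   settings stored as attributes (see [hops()], [glance.mash_trajectory()]).
#' @examples
#' traj <- propagate(tully_model(), mash_ic(-4, 12, c(0, 0, -1)),
#'                   dt = 2, t_max = 200, method = "rev-nacs")
#' tail(traj, 3)
#' @export
propagate <- function(model, ic, dt, t_max, method = "rev-pc-ld",
                      record_every = 1L, xi = 1e-4, max_root_iters = 10L,
                      e_tol = 0, swap_tol = 0.1, t0 = 0) {
  ic <- as_mash_ic(ic)
  method <- match.arg(method, mash_methods())
  backward <- FALSE
  if (dt < 0 || t_max < 0) {
    if (dt * t_max < 0)
      stop("`dt` and `t_max` must have the same sign", call. = FALSE)
    backward <- TRUE
    dt <- abs(dt); t_max <- abs(t_max)
    ic <- mash_ic(ic$q, -ic$p, ic$S * c(1, -1, 1), normalize = FALSE)
  }
  nsteps <- round(t_max / dt)
  if (nsteps < 1) stop("`t_max` must cover at least one step", call. = FALSE)
  res <- cpp_propagate(model_list(model), ic$q, ic$p, ic$S, method, dt,
                       as.integer(nsteps), as.integer(record_every), xi,
                       as.integer(max_root_iters), e_tol, 0, swap_tol)
  F <- model$ndof
  qn <- if (F == 1L) "q" else paste0("q", seq_len(F))
  pn <- if (F == 1L) "p" else paste0("p", seq_len(F))
  Q <- res$q; P <- res$p
  tt <- res$t
  Sx <- res$S[, 1]; Sy <- res$S[, 2]; Sz <- res$S[, 3]
  hops <- tibble::tibble(
    t = res$hops$t,
    kind = ifelse(res$hops$kind == 0, "accepted", "frustrated"),
    gap = res$hops$gap, dp_norm = res$hops$dp_norm,
    root_iters = res$hops$root_iters)
  if (backward) {
    P <- -P; Sy <- -Sy
    tt <- t0 - tt
    hops$t <- t0 - hops$t
  } else {
    tt <- t0 + tt
    hops$t <- t0 + hops$t
  }
  out <- tibble::as_tibble(stats::setNames(as.data.frame(Q), qn))
  out <- dplyr::bind_cols(tibble::tibble(t = tt), out,
                          stats::setNames(tibble::as_tibble(as.data.frame(P)), pn),
                          tibble::tibble(Sx = Sx, Sy = Sy, Sz = Sz,
                                         active = res$active,
                                         energy = res$energy,
                                         theta = res$theta))
  structure(out,
            class = c("mash_trajectory", class(out)),
            hops = hops, method = method, dt = if (backward) -dt else dt,
            xi = xi, model = model, step_sizes = res$step_sizes,
            backward = backward)
}

#' Propagate with variable time-stepping
#'
#' After each step the energy change is compared with `e_tol`; offending
#' steps are undone (the dynamics are deterministic) and redone as two
#' half-steps, recursively. With `e_tol = Inf` this reduces exactly to
#' [propagate()].
#'
#' @inheritParams propagate
#' @param e_tol maximum allowed energy change per step (hartree); must be
#'   positive.
#' @return a `mash_trajectory`; the sizes of the leaf steps actually taken
#'   are in `attr(x, "step_sizes")`.
#' @export
propagate_variable <- function(model, ic, dt, t_max, e_tol,
                               method = "rev-pc-ld", ...) {
  stopifnot(e_tol > 0)
  if (!is.finite(e_tol)) e_tol <- 0  # disabled limit: plain propagation
  propagate(model, ic, dt, t_max, method = method, e_tol = e_tol, ...)
}

#' Hop events of a trajectory
#'
#' @param traj a `mash_trajectory`.
#' @return tibble with one row per attempted hop: time, kind
#'   (accepted/frustrated), gap at the hop geometry, mass-weighted momentum
#'   change, and root-search propagations used (piecewise-continuous
#'   methods).
#' @export
hops <- function(traj) attr(traj, "hops")

#' Final phase-space point of a trajectory
#'
#' @param traj a `mash_trajectory`.
#' @param flip flip `p` and `Sy` (the time-reversal operation), e.g. to
#'   start a backward run.
#' @return a [mash_ic()].
#' @export
final_state <- function(traj, flip = FALSE) {
  n <- nrow(traj)
  qc <- grep("^q[0-9]*$", names(traj), value = TRUE)
  pc <- grep("^p[0-9]*$", names(traj), value = TRUE)
  s <- if (flip) c(1, -1, 1) else c(1, 1, 1)
  mash_ic(as.numeric(traj[n, qc]), (if (flip) -1 else 1) * as.numeric(traj[n, pc]),
          c(traj$Sx[n], traj$Sy[n], traj$Sz[n]) * s, normalize = FALSE)
}

#' Total energy of a phase-space point
#'
#' `E = sum_j p_j^2 / (2 m_j) + V_active(q)`: kinetic energy plus the
#' potential of the active adiabatic surface (the hemisphere of `Sz`).
#'
#' @param model a `mash_model`.
#' @param ic a [mash_ic()] or `list(q, p, S)`.
#' @return energy in hartree.
#' @export
state_energy <- function(model, ic) {
  ic <- as_mash_ic(ic)
  el <- adiabatize(model, ic$q)
  sum(ic$p^2 / (2 * model_masses(model))) +
    if (ic$S[3] > 0) el$V1 else el$V0
}
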