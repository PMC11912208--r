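#' Sample nuclear phase space from a Gaussian Wigner distribution
#'
#' Minimum-uncertainty wavepacket convention (hbar = 1): independent
#' Gaussians with `Var(q) = 1/(4 gamma)` and `Var(p) = gamma`, so
#' `sd(q) sd(p) = 1/2`. This is the standard convention for scattering
#' calculations on the avoided-crossing models.
#'
#' @param n number of draws.
#' @param q_bar,p_bar distribution centre (atomic units).
#' @param gamma width parameter (1/bohr^2).
#' @param seed integer seed; draws are a pure function of
#'   `(parameters, n, seed)`.
#' @return tibble with columns `q`, `p`.
#' @export
sample_wigner_gaussian <- function(n, q_bar, p_bar, gamma, seed) {
  stopifnot(n >= 1, gamma > 0)
  withr::with_seed(seed, {
    tibble::tibble(q = stats::rnorm(n, q_bar, sqrt(1 / (4 * gamma))),
                   p = stats::rnorm(n, p_bar, sqrt(gamma)))
  })
}

#' Sample from the ground-state harmonic Wigner distribution
#'
#' Per dimensionless mass-weighted mode, `q` and `p` are independent
#' Gaussians with variance 1/2 (the ground-state Wigner function), so the
#' sampled mean harmonic energy is the zero-point energy `sum omega_j / 2`.
#'
#' @param n number of draws.
#' @param omega mode frequencies (sets the number of modes; the
#'   dimensionless draws themselves do not depend on it).
#' @param seed integer seed.
#' @return tibble with columns `q1..qF`, `p1..pF` (or `q`, `p` for one
#'   mode).
#' @export
sample_wigner_harmonic <- function(n, omega, seed) {
  stopifnot(n >= 1, all(omega > 0))
  F <- length(omega)
  withr::with_seed(seed, {
    qs <- matrix(stats::rnorm(n * F, 0, sqrt(0.5)), n, F)
    ps <- matrix(stats::rnorm(n * F, 0, sqrt(0.5)), n, F)
    qn <- if (F == 1L) "q" else paste0("q", seq_len(F))
    pn <- if (F == 1L) "p" else paste0("p", seq_len(F))
    dplyr::bind_cols(stats::setNames(tibble::as_tibble(as.data.frame(qs)), qn),
                     stats::setNames(tibble::as_tibble(as.data.frame(ps)), pn))
  })
}

#' Sample spin vectors uniformly from a Bloch hemisphere
#'
#' Draws unit vectors uniformly from the hemisphere `axis . S > 0` together
#' with the MASH weighting factor `w = 2 |axis . S|` (the component along
#' the axis is uniform on (0, 1], so the mean weight is exactly 1).
#' Orient `axis` to choose the hemisphere, e.g. `c(0, 0, -1)` for the lower
#' adiabatic state.
#'
#' @param n number of draws.
#' @param axis unit 3-vector defining the hemisphere.
#' @param seed integer seed.
#' @return tibble with columns `Sx`, `Sy`, `Sz`, `weight`.
#' @export
sample_spin_hemisphere <- function(n, axis, seed) {
  axis <- as.numeric(axis)
  stopifnot(n >= 1, abs(sum(axis^2) - 1) < 1e-8)
  withr::with_seed(seed, {
    u <- stats::runif(n)        # component along axis, uniform on (0, 1]
    phi <- stats::runif(n, 0, 2 * pi)
    fr <- orthonormal_frame(axis)
    r <- sqrt(pmax(0, 1 - u^2))
    S <- outer(u, axis) + outer(r * cos(phi), fr$e1) + outer(r * sin(phi), fr$e2)
    tibble::tibble(Sx = S[, 1], Sy = S[, 2], Sz = S[, 3], weight = 2 * u)
  })
}

orthonormal_frame <- function(axis) {
  e1 <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- e1 - sum(e1 * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Bloch axis of a diabatic state at a geometry
#'
#' The adiabatic-frame direction whose hemisphere corresponds to the given
#' diabatic state: `n = R_y(2 alpha) z-hat` with `alpha` the rotation angle
#' of the adiabatizing eigenvector matrix, oriented so that
#' `n . S = S_dia_z`, the diabatic population difference (state 2 minus
#' state 1).
#'
#' @param model a `mash_model`.
#' @param q geometry.
#' @param state initial diabatic state (1 or 2).
#' @return unit 3-vector.
#' @export
diabatic_axis <- function(model, q, state = 2) {
  el <- adiabatize(model, q)
  alpha <- atan2(el$U[2, 1], el$U[1, 1])
  n <- cpp_rotate(c(0, 0, 1), c(0, 1, 0), 2 * alpha)
  if (state == 1) -n else n
}

#' Sample a diabatic-state ensemble for an LVC model
#'
#' Nuclear coordinates from the ground-state harmonic Wigner distribution
#' and, per draw, a spin sampled uniformly from the Bloch hemisphere of the
#' chosen initial diabatic state at that geometry, with the MASH weight
#' `2 |n(q) . S|`. The active surface of each trajectory is then the
#' hemisphere of the adiabatic `Sz`.
#'
#' @param model an [lvc_model()].
#' @param n number of trajectories.
#' @param state initial diabatic state (default 2, the upper state).
#' @param seed integer seed.
#' @return tibble of initial conditions: `q*`, `p*`, `Sx`, `Sy`, `Sz`,
#'   `weight`.
#' @export
sample_diabatic_ensemble <- function(model, n, state = 2, seed = 1) {
  stopifnot(model$type == "lvc")
  F <- model$ndof
  nuc <- sample_wigner_harmonic(n, model$omega, seed)
  qc <- grep("^q[0-9]*$", names(nuc), value = TRUE)
  withr::with_seed(seed + 1L, {
    u <- stats::runif(n)
    phi <- stats::runif(n, 0, 2 * pi)
  })
  S <- matrix(0, n, 3)
  w <- numeric(n)
  for (i in seq_len(n)) {
    ax <- diabatic_axis(model, as.numeric(nuc[i, qc]), state)
    fr <- orthonormal_frame(ax)
    r <- sqrt(max(0, 1 - u[i]^2))
    S[i, ] <- u[i] * ax + r * cos(phi[i]) * fr$e1 + r * sin(phi[i]) * fr$e2
    w[i] <- 2 * u[i]
  }
  dplyr::bind_cols(nuc, tibble::tibble(Sx = S[, 1], Sy = S[, 2], Sz = S[, 3],
                                       weight = w))
}
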