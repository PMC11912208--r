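#' Rotate a Bloch spin vector
#'
#' Exact (Rodrigues) rotation of `S` about `omega / |omega|` by the angle
#' `|omega| * dt`. Rotations preserve `|S|` to machine precision and
#' `spin_rotate(S, omega, -dt)` inverts `spin_rotate(S, omega, dt)`.
#'
#' @param S Bloch vector `c(Sx, Sy, Sz)` (unit norm for MASH states).
#' @param omega angular-velocity vector (rad per atomic time unit); the
#'   generators produced in this package have the form `c(0, wy, wz)`
#'   (real wavefunctions: coupling rotates about y, the gap about z).
#' @param dt duration (may be negative for backward propagation).
#' @return the rotated spin vector.
#' @examples
#' spin_rotate(c(1, 0, 0), c(0, 0, pi), 0.5)  # quarter turn about z
#' @export
spin_rotate <- function(S, omega, dt) {
  cpp_rotate(as.numeric(S), as.numeric(omega), dt)
}

#' Spin generator from the nonadiabatic coupling vector
#'
#' `omega = c(0, -2 v.d, gap)` (hbar = 1): the gap precesses the spin about
#' z while the time-derivative coupling `v.d` rotates it about y. The signs
#' reproduce the Schroedinger evolution of real-wavefunction coefficients
#' with `Sz` the upper-minus-lower population difference.
#'
#' @param elec electronic evaluation from [adiabatize()].
#' @param v velocity vector `p / m`.
#' @return angular-velocity vector `c(0, wy, wz)`.
#' @export
spin_generator_nac <- function(elec, v) {
  c(0, -2 * sum(as.numeric(v) * elec$d), elec$gap)
}

#' Spin generator from the averaged time-derivative coupling (ATDC)
#'
#' The wavefunction rotation angle over the step, `chi_wf`, divided by the
#' step duration is the averaged time-derivative coupling; the gap is
#' averaged with the trapezium rule. Equal to [spin_generator_nac()] when
#' the coupling and gap are constant over the step.
#'
#' @param ov overlap data from [wf_overlap()] (requires `ov$dt > 0`).
#' @param gap0,gap1 adiabatic gaps at the two ends of the step (hartree).
#' @return angular-velocity vector `c(0, wy, wz)`.
#' @export
spin_generator_atdc <- function(ov, gap0, gap1) {
  stopifnot(ov$dt > 0)
  c(0, -2 * ov$chi_wf / ov$dt, (gap0 + gap1) / 2)
}

#' Local-diabatization spin step
#'
#' Treats the adiabatic states as a locally diabatic basis across the step:
#' half a step of gap precession in the initial basis, the basis rotation
#' `R_y(-2 chi_wf)` (the Hilbert-space angle is doubled on the Bloch
#' sphere), and half a step of gap precession in the final basis. The map is
#' orthogonal; applying it with the gaps swapped and `dt` negated undoes it.
#' For a linear-in-time diabatic Hamiltonian (Landau-Zener form) the
#' interpolation underlying this construction is exact.
#'
#' @inheritParams spin_generator_atdc
#' @param S Bloch vector at the start of the step.
#' @return the spin vector propagated across the step.
#' @export
spin_step_ld <- function(S, ov, gap0, gap1) {
  stopifnot(ov$dt > 0)
  S <- cpp_rotate(as.numeric(S), c(0, 0, gap0), ov$dt / 2)
  S <- cpp_rotate(S, c(0, 1, 0), -2 * ov$chi_wf)
  cpp_rotate(S, c(0, 0, gap1), ov$dt / 2)
}

#' Hop detection from the sign of Sz
#'
#' A hop is attempted when `Sz` changes hemisphere across a spin update.
#' `sgn(0)` inherits the sign before the update, so a trajectory grazing the
#' equator does not hop.
#'
#' @param Sz_before,Sz_after z component of the spin before and after the
#'   update.
#' @return logical: did the spin cross the equator?
#' @examples
#' detect_hop(-0.05, 0.02)   # TRUE
#' detect_hop(-1e-5, 0)      # FALSE (tie-break)
#' @export
detect_hop <- function(Sz_before, Sz_after) {
  if (Sz_after == 0) return(FALSE)
  if (Sz_before == 0) return(FALSE)
  (Sz_before > 0) != (Sz_after > 0)
}

#' Momentum rescaling or reflection at an attempted hop
#'
#' The mass-weighted momentum `p_j / sqrt(m_j)` is decomposed along the unit
#' mass-weighted NAC direction (`d_j / sqrt(m_j)`, normalized). If the
#' kinetic energy in that component suffices to reach the other surface, the
#' component is rescaled (keeping its sign) so total energy is conserved and
#' the active surface switches; otherwise the component is reflected, `Sz`
#' is inverted so the spin remains in the initial hemisphere, and the
#' surface is kept (a frustrated hop). Components orthogonal to the NAC are
#' untouched.
#'
#' @param model a `mash_model`.
#' @param q hop geometry.
#' @param p momentum vector.
#' @param S Bloch spin vector.
#' @param active current surface (0 lower, 1 upper).
#' @return list with updated `p`, `S`, `active`, the hop `kind`
#'   (`"accepted"` or `"frustrated"`), the `gap` at the hop geometry and
#'   `dp_norm`, the magnitude of the mass-weighted momentum change.
#' @examples
#' m <- lvc_model(omega = 5e-4, E = c(0, 0.09), lambda = 1e-6)
#' hop_rescale(m, q = 0, p = 20, S = c(0.6, 0, -0.8), active = 0)
#' @export
hop_rescale <- function(model, q, p, S, active) {
  cpp_rescale_or_reflect(model_list(model), as.numeric(q), as.numeric(p),
                         as.numeric(S), as.integer(active))
}
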