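#' Evaluate the diabatic potential matrix and its gradients
#'
#' @param model a [tully_model()] or [lvc_model()].
#' @param q position vector (length = degrees of freedom; bohr, or
#'   dimensionless mass-weighted coordinates for LVC models).
#' @return list with `H` (2x2 symmetric diabatic matrix, hartree) and `dH`
#'   (matrix with one row per degree of freedom and columns `d11`, `d22`,
#'   `d12`, hartree/bohr).
#' @export
eval_diabatic <- function(model, q) {
  cpp_eval_diab(model_list(model), as.numeric(q))
}

#' Adiabatize a geometry: energies, forces, NAC vector, eigenvectors
#'
#' Diagonalizes the diabatic matrix at `q`. Forces are
#' `F_n = -u_n' (dH) u_n` and the nonadiabatic coupling vector is
#' `d_j = u_0' (dH_j) u_1 / (V1 - V0)`. Eigenvector signs are fixed against
#' `U_ref` (the previous step's frame) when supplied; otherwise the upper
#' column has its larger-magnitude component positive and the lower column
#' is chosen so that `det(U) = +1`.
#'
#' @inheritParams eval_diabatic
#' @param U_ref optional 2x2 reference eigenvector matrix for sign
#'   continuity.
#' @return list with `V0`, `V1`, `gap`, `F0`, `F1`, `d` and the 2x2
#'   eigenvector matrix `U` (columns = lower, upper state in the diabatic
#'   basis).
#' @examples
#' adiabatize(tully_model(), q = 0)
#' @export
adiabatize <- function(model, q, U_ref = NULL) {
  cpp_adiabatize(model_list(model), as.numeric(q), U_ref)
}

#' Wavefunction overlap between two geometries
#'
#' Computes the 2x2 overlap matrix `O_raw[i, j] = u_i(prev) . u_j(next)`,
#' sign-fixes the columns of the later frame so both diagonal entries are
#' positive (the smooth-continuation phase convention), takes the
#' special-orthogonal polar factor `O`, and extracts the wavefunction
#' rotation angle `chi_wf = atan2(O[1, 2], O[1, 1])`. For a smooth segment
#' `chi_wf / dt` converges to the time-derivative coupling `v . d` as
#' `dt -> 0`.
#'
#' @param U_prev,U_next 2x2 orthogonal eigenvector matrices at consecutive
#'   geometries.
#' @param dt elapsed time of the segment (atomic units).
#' @param swap_tol error threshold on the sign-fixed overlap diagonal;
#'   entries below it indicate a state-character swap (trivial crossing)
#'   that the step cannot represent. Set to 0 to disable the check.
#' @return list with `O_raw` (sign-fixed), `O` (special-orthogonal polar
#'   factor), `chi_wf` (radians, |chi_wf| < pi/2) and `dt`.
#' @export
wf_overlap <- function(U_prev, U_next, dt, swap_tol = 0.1) {
  cpp_overlap(U_prev, U_next, dt, swap_tol)
}
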