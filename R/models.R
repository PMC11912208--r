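#' Tully's single avoided-crossing model
#'
#' The standard one-dimensional two-state diabatic model of an avoided
#' crossing: `H11 = A(1 - exp(-Bq))` for `q > 0`, `-A(1 - exp(Bq))` for
#' `q <= 0`, `H22 = -H11`, and a Gaussian coupling `H12 = C exp(-D q^2)`.
#' Defaults are the standard parameter set (atomic units) with a nuclear
#' mass of 2000.
#'
#' @param A,B,C,D diabatic model parameters (hartree, 1/bohr, hartree,
#'   1/bohr^2).
#' @param mass nuclear mass (electron masses).
#' @param degen_thr adiabatic energies closer than this (hartree) are treated
#'   as a degenerate-geometry error.
#' @return a `mash_model` object.
#' @examples
#' m <- tully_model()
#' eval_diabatic(m, 0)
#' @export
tully_model <- function(A = 0.01, B = 1.6, C = 0.005, D = 1.0, mass = 2000,
                        degen_thr = 1e-12) {
  structure(
    list(type = "tully1", A = A, B = B, C = C, D = D, mass = mass,
         degen_thr = degen_thr, ndof = 1L),
    class = "mash_model")
}

#' Linear vibronic coupling (LVC) model
#'
#' Two electronic states coupled through harmonic modes in the dimensionless
#' mass-weighted convention (kinetic energy `sum_j omega_j p_j^2 / 2`, so the
#' effective mass of mode j is `1/omega_j`). The diabatic Hamiltonian is
#' `H = sum_j (omega_j/2) q_j^2 I + diag(E1 + sum kappa1_j q_j,
#' E2 + sum kappa2_j q_j)` with off-diagonal coupling `sum_j lambda_j q_j`.
#'
#' @param omega mode frequencies.
#' @param E vertical energies `c(E1, E2)` of the two diabatic states at the
#'   origin.
#' @param kappa1,kappa2 intrastate linear (tuning) couplings per mode.
#' @param lambda interstate linear couplings per mode (zero on tuning modes).
#' @param units `"hartree"` (default) or `"ev"`; with `"ev"` every energy
#'   parameter is converted to hartree on construction.
#' @param degen_thr degeneracy threshold in hartree.
#' @return a `mash_model` object.
#' @examples
#' # single-mode toy with symmetric tuning
#' m <- lvc_model(omega = 1e-3, E = c(0, 0), kappa1 = 2e-3, kappa2 = -2e-3,
#'                lambda = 5e-4)
#' adiabatize(m, 0.5)
#' @export
lvc_model <- function(omega, E, kappa1 = NULL, kappa2 = NULL, lambda = NULL,
                      units = c("hartree", "ev"), degen_thr = 1e-12) {
  units <- match.arg(units)
  F <- length(omega)
  kappa1 <- if (is.null(kappa1)) numeric(F) else kappa1
  kappa2 <- if (is.null(kappa2)) numeric(F) else kappa2
  lambda <- if (is.null(lambda)) numeric(F) else lambda
  if (length(E) != 2L)
    stop("`E` must contain the two vertical energies c(E1, E2)", call. = FALSE)
  if (length(kappa1) != F || length(kappa2) != F || length(lambda) != F)
    stop("`kappa1`, `kappa2` and `lambda` must have one entry per mode",
         call. = FALSE)
  conv <- if (units == "ev") 1 / HARTREE_EV else 1
  structure(
    list(type = "lvc",
         omega = omega * conv, E1 = E[1] * conv, E2 = E[2] * conv,
         kappa1 = kappa1 * conv, kappa2 = kappa2 * conv,
         lambda = lambda * conv,
         mass = 1 / (omega * conv), degen_thr = degen_thr, ndof = F),
    class = "mash_model")
}

#' Read a model definition from a YAML config file
#'
#' The config declares the model type (`tully1` or `lvc`), its parameter
#' block, and optionally `units: {energy: eV}` for automatic conversion to
#' hartree. An example LVC parameter file for the 2-state 3-mode pyrazine
#' model ships with the package (see the example).
#'
#' @param path path to a YAML file.
#' @return a `mash_model` object.
#' @examples
#' cfg <- system.file("extdata", "pyrazine_lvc.yaml", package = "revmash")
#' m <- read_model_config(cfg)
#' m
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  type <- cfg$model %||% cfg$type
  if (is.null(type)) stop("config must declare a `model` type", call. = FALSE)
  eunit <- tolower(cfg$units$energy %||% "hartree")
  if (!eunit %in% c("hartree", "ev"))
    stop("unsupported energy unit '", eunit, "'", call. = FALSE)
  if (identical(type, "tully1")) {
    p <- cfg$params %||% cfg
    conv <- if (eunit == "ev") 1 / HARTREE_EV else 1
    tully_model(A = (p$A %||% 0.01) * conv, B = p$B %||% 1.6,
                C = (p$C %||% 0.005) * conv, D = p$D %||% 1.0,
                mass = p$mass %||% 2000)
  } else if (identical(type, "lvc")) {
    lvc_model(omega = as.numeric(cfg$omega), E = as.numeric(cfg$E),
              kappa1 = as.numeric(cfg$kappa1), kappa2 = as.numeric(cfg$kappa2),
              lambda = as.numeric(cfg$lambda), units = eunit)
  } else {
    stop("unknown model type '", type, "'", call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mash_model <- function(x, ...) {
  if (x$type == "tully1") {
    cat(sprintf("<mash_model> avoided crossing (tully1): A=%g B=%g C=%g D=%g mass=%g\n",
                x$A, x$B, x$C, x$D, x$mass))
  } else {
    cat(sprintf("<mash_model> linear vibronic coupling: %d modes, E = (%.4g, %.4g) hartree\n",
                x$ndof, x$E1, x$E2))
    cat("  omega :", signif(x$omega, 4), "\n")
    cat("  kappa1:", signif(x$kappa1, 4), "\n")
    cat("  kappa2:", signif(x$kappa2, 4), "\n")
    cat("  lambda:", signif(x$lambda, 4), "\n")
  }
  invisible(x)
}

# strip to the plain list the C++ layer expects
model_list <- function(model) {
  stopifnot(inherits(model, "mash_model"))
  unclass(model)
}

#' Masses of the nuclear degrees of freedom
#'
#' @param model a `mash_model`.
#' @return numeric vector of per-dof masses (for LVC models, `1/omega`).
#' @export
model_masses <- function(model) model_list(model)$mass
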