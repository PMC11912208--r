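#' Shipped simulation presets
#'
#' Ready-made study setups on the shipped models:
#'
#' * `"tully-hopping"`: the avoided-crossing trajectory
#'   `q0 = -1.5, p0 = 16.16`, spin along `[0.02, 0.056, -0.998]`
#'   (normalized), which crosses the interaction region and hops twice.
#'   Used for reversibility demonstrations and the with-hops convergence
#'   study (`dt = 1` a.u., `t_max = 800` a.u.).
#' * `"tully-nohop"`: `q0 = -1.5, p0 = 15.6`, spin along
#'   `[-0.04, -0.08, 0.9]` (normalized), integrated over a window
#'   (`t_max = 220` a.u.) that traverses the coupling peak without any
#'   equator crossing; the passage in this momentum range is marginal
#'   between hopping and non-hopping, so the hop-free window is the robust
#'   realization of a hop-free convergence study.
#' * `"tully-wigner"`: ensemble spec for the avoided-crossing model:
#'   Gaussian Wigner nuclei (`gamma = 0.1`, centre `q = -1.5` with
#'   configurable momentum) and spins uniform on the lower Bloch
#'   hemisphere.
#' * `"pyrazine"`: the 2-state 3-mode linear-vibronic-coupling model of
#'   pyrazine internal conversion (parameters read from the shipped YAML
#'   config), initialized from the harmonic Wigner ground state in the
#'   upper diabatic state; `dt = 1.2` fs, `t_max = 150` fs, `n = 5000`
#'   trajectories.
#'
#' @param name preset name.
#' @param p_bar centre momentum for the `"tully-wigner"` ensemble preset.
#' @return list with elements among `model`, `ic`, `dt`, `t_max`,
#'   `method`, `sampling`, `n`, `xi`, `max_root_iters`, `swap_tol`.
#' @export
mash_preset <- function(name = c("tully-hopping", "tully-nohop",
                                 "tully-wigner", "pyrazine"),
                        p_bar = 16) {
  name <- match.arg(name)
  switch(name,
    "tully-hopping" = list(
      model = tully_model(),
      ic = mash_ic(-1.5, 16.16, c(0.02, 0.056, -0.998)),
      dt = 1.0, t_max = 800, method = "rev-pc-nacs",
      xi = 1e-4, max_root_iters = 10L, swap_tol = 0.1),
    "tully-nohop" = list(
      model = tully_model(),
      ic = mash_ic(-1.5, 15.6, c(-0.04, -0.08, 0.9)),
      dt = 1.0, t_max = 220, method = "rev-pc-ld",
      xi = 1e-4, max_root_iters = 10L, swap_tol = 0.1),
    "tully-wigner" = list(
      model = tully_model(),
      sampling = list(nuclear = "wigner-gaussian", q_bar = -1.5,
                      p_bar = p_bar, gamma = 0.1,
                      spin = "hemisphere", axis = c(0, 0, -1)),
      dt = 1.0, t_max = 800, method = "rev-pc-nacs", n = 5000L,
      xi = 1e-4, max_root_iters = 10L, swap_tol = 0.1),
    "pyrazine" = list(
      model = read_model_config(system.file("extdata", "pyrazine_lvc.yaml",
                                            package = "revmash")),
      sampling = list(nuclear = "wigner-harmonic",
                      spin = "diabatic-hemisphere", state = 2L),
      dt = 1.2 * FS_AU, t_max = 150 * FS_AU, method = "rev-pc-ld",
      n = 5000L, xi = 1e-4, max_root_iters = 60L, swap_tol = 0))
}

#' Draw the initial-condition table of an ensemble preset
#'
#' @param preset a [mash_preset()] with a `sampling` block.
#' @param n number of trajectories (defaults to the preset's).
#' @param seed integer seed.
#' @return tibble of initial conditions for [run_ensemble()].
#' @export
preset_ensemble_ics <- function(preset, n = preset$n, seed = 1) {
  sp <- preset$sampling
  if (is.null(sp)) stop("preset has no sampling block", call. = FALSE)
  if (sp$nuclear == "wigner-harmonic") {
    sample_diabatic_ensemble(preset$model, n, state = sp$state, seed = seed)
  } else {
    nuc <- sample_wigner_gaussian(n, sp$q_bar, sp$p_bar, sp$gamma, seed)
    spin <- sample_spin_hemisphere(n, sp$axis, seed + 1L)
    dplyr::bind_cols(nuc, spin)
  }
}
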