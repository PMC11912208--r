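#' Write and read trajectories as plain-text tables
#'
#' Columnar records `(t, positions, momenta, Sx, Sy, Sz, active, energy,
#' theta)` as tab-separated text; hop events are written alongside with the
#' suffix `_hops` before the extension. Reading restores the tibble and the
#' hop table (other attributes are not persisted).
#'
#' @param traj a `mash_trajectory`.
#' @param path output file path; a `.rds` extension selects a compact
#'   binary container instead of the canonical plain text.
#' @return `path`, invisibly (`write_trajectory`); a tibble with a `hops`
#'   attribute (`read_trajectory`).
#' @export
write_trajectory <- function(traj, path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(list(states = tibble::as_tibble(traj), hops = hops(traj)), path)
    return(invisible(path))
  }
  utils::write.table(as.data.frame(traj), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(as.data.frame(hops(traj)), hops_path(path), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    out <- obj$states
    attr(out, "hops") <- obj$hops
    return(out)
  }
  out <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  hp <- hops_path(path)
  if (file.exists(hp)) {
    attr(out, "hops") <- tibble::as_tibble(
      utils::read.table(hp, header = TRUE, sep = "\t",
                        colClasses = c(kind = "character")))
  }
  out
}

hops_path <- function(path) {
  sub("(\\.[^.]+)?$", "_hops\\1", path)
}

# parse "1.2 fs" / "4.84 eV" / plain numbers into atomic units
parse_quantity <- function(x, kind = c("time", "energy")) {
  kind <- match.arg(kind)
  if (is.numeric(x)) return(x)
  parts <- strsplit(trimws(as.character(x)), "\\s+")[[1]]
  val <- as.numeric(parts[1])
  if (is.na(val)) stop("cannot parse quantity '", x, "'", call. = FALSE)
  if (length(parts) == 1L) return(val)
  unit <- tolower(parts[2])
  switch(unit,
    "fs" = val * FS_AU,
    "au" = , "a.u." = val,
    "ev" = val / HARTREE_EV,
    "hartree" = val,
    stop("unknown unit '", unit, "' in '", x, "'", call. = FALSE))
}

#' Read a run configuration
#'
#' A YAML file with a `model` (preset name, path to a model config, or an
#' inline block), a `method`, `dt` and `t_max` (numbers in atomic units or
#' strings with `fs` units), and exactly one of an explicit `initial` state
#' (`q`, `p`, `S`) or a `sampling` block (`n`, `seed`, plus the sampler
#' parameters). Optional keys: `xi`, `max_root_iters`, `e_tol`, `swap_tol`,
#' `record_every`, `output`, `seed`.
#'
#' @param path path to a YAML run config (or a list already parsed).
#' @return validated config list with model object and quantities in atomic
#'   units.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  bad <- function(field, msg) stop("config field `", field, "`: ", msg, call. = FALSE)

  mdl <- cfg$model
  model <- if (is.character(mdl) && mdl %in% c("tully1", "tully")) {
    tully_model()
  } else if (is.character(mdl) && file.exists(mdl)) {
    read_model_config(mdl)
  } else if (is.character(mdl) && mdl == "pyrazine") {
    read_model_config(system.file("extdata", "pyrazine_lvc.yaml",
                                  package = "revmash"))
  } else if (is.list(mdl)) {
    tf <- tempfile(fileext = ".yaml"); on.exit(unlink(tf))
    yaml::write_yaml(mdl, tf)
    read_model_config(tf)
  } else bad("model", "must be a preset name, a file path, or a block")

  method <- cfg$method %||% "rev-pc-ld"
  if (!method %in% mash_methods())
    bad("method", paste0("unknown method '", method, "'; valid: ",
                         paste(mash_methods(), collapse = ", ")))
  if (is.null(cfg$dt)) bad("dt", "is required")
  if (is.null(cfg$t_max)) bad("t_max", "is required")

  has_init <- !is.null(cfg$initial)
  has_samp <- !is.null(cfg$sampling)
  if (has_init == has_samp)
    bad("initial/sampling", "exactly one of the two blocks must be present")

  out <- list(
    model = model, method = method,
    dt = parse_quantity(cfg$dt, "time"),
    t_max = parse_quantity(cfg$t_max, "time"),
    xi = cfg$xi %||% 1e-4,
    max_root_iters = cfg$max_root_iters %||% 10L,
    e_tol = cfg$e_tol %||% 0,
    swap_tol = cfg$swap_tol %||% 0.1,
    record_every = cfg$record_every %||% 1L,
    seed = cfg$seed %||% 1L,
    output = cfg$output)
  if (has_init) {
    ini <- cfg$initial
    if (is.null(ini$q) || is.null(ini$p) || is.null(ini$S))
      bad("initial", "needs q, p and S")
    out$ic <- mash_ic(as.numeric(ini$q), as.numeric(ini$p), as.numeric(ini$S))
  } else {
    out$sampling <- cfg$sampling
    out$n <- cfg$sampling$n %||% 1000L
  }
  out
}

config_ics <- function(cfg) {
  sp <- cfg$sampling
  if (identical(sp$nuclear, "wigner-harmonic") ||
      identical(sp$spin, "diabatic-hemisphere")) {
    sample_diabatic_ensemble(cfg$model, cfg$n, state = sp$state %||% 2L,
                             seed = cfg$seed)
  } else {
    nuc <- sample_wigner_gaussian(cfg$n, sp$q_bar, sp$p_bar, sp$gamma, cfg$seed)
    spin <- sample_spin_hemisphere(cfg$n, as.numeric(sp$axis %||% c(0, 0, -1)),
                                   cfg$seed + 1L)
    dplyr::bind_cols(nuc, spin)
  }
}

#' Run a single trajectory from a config
#'
#' Propagates the configured trajectory, optionally writes it (and its hop
#' table) to `output`, and reports a one-line summary.
#'
#' @param config path to a YAML run config, or a parsed config list.
#' @param quiet suppress the summary line.
#' @return the `mash_trajectory`, invisibly.
#' @export
mash_run <- function(config, quiet = FALSE) {
  cfg <- read_run_config(config)
  if (is.null(cfg$ic))
    stop("`mash_run` needs an explicit `initial` block", call. = FALSE)
  traj <- propagate(cfg$model, cfg$ic, cfg$dt, cfg$t_max, method = cfg$method,
                    record_every = cfg$record_every, xi = cfg$xi,
                    max_root_iters = cfg$max_root_iters, e_tol = cfg$e_tol,
                    swap_tol = cfg$swap_tol)
  if (!is.null(cfg$output)) write_trajectory(traj, cfg$output)
  if (!quiet) {
    g <- glance(traj)
    message(sprintf("%s: %d steps, %d hops (%d accepted), energy drift %.2e",
                    g$method, g$n_steps, g$n_hops, g$n_accepted, g$energy_drift))
  }
  invisible(traj)
}

#' Run an ensemble and write population tables
#'
#' @inheritParams mash_run
#' @param frame `"diabatic"` or `"adiabatic"` populations.
#' @return the population tibble, invisibly.
#' @export
mash_ensemble <- function(config, frame = c("diabatic", "adiabatic"),
                          quiet = FALSE) {
  frame <- match.arg(frame)
  cfg <- read_run_config(config)
  if (is.null(cfg$sampling))
    stop("`mash_ensemble` needs a `sampling` block", call. = FALSE)
  ics <- config_ics(cfg)
  ens <- run_ensemble(cfg$model, ics, cfg$dt, cfg$t_max, method = cfg$method,
                      record_every = cfg$record_every, xi = cfg$xi,
                      max_root_iters = cfg$max_root_iters,
                      swap_tol = cfg$swap_tol)
  pops <- if (frame == "diabatic") diabatic_populations(ens)
          else adiabatic_populations(ens)
  if (!is.null(cfg$output))
    utils::write.table(as.data.frame(pops), cfg$output, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!quiet)
    message(sprintf("%s ensemble: n = %d, %d time points", cfg$method,
                    cfg$n, length(unique(pops$t))))
  invisible(pops)
}

#' Run a convergence-order scan from a config
#'
#' The config must give an explicit `initial` state and may give `dts`
#' (ladder of steps; default five halvings of `dt`), `methods`, and
#' `variables`.
#'
#' @inheritParams mash_run
#' @return the `mash_order_scan`, invisibly; slopes are messaged unless
#'   `quiet`.
#' @export
mash_order_scan <- function(config, quiet = FALSE) {
  raw <- if (is.list(config)) config else yaml::read_yaml(config)
  cfg <- read_run_config(config)
  if (is.null(cfg$ic))
    stop("`mash_order_scan` needs an explicit `initial` block", call. = FALSE)
  dts <- raw$dts %||% (cfg$dt / 2^(0:4))
  methods <- raw$methods %||% mash_methods()
  variables <- raw$variables %||% c("p", "Sz")
  scan <- order_scan(cfg$model, cfg$ic, dts = as.numeric(dts),
                     t_max = cfg$t_max, methods = methods,
                     variables = variables, xi = cfg$xi,
                     max_root_iters = cfg$max_root_iters,
                     swap_tol = cfg$swap_tol)
  sl <- order_slope(scan)
  if (!is.null(cfg$output))
    utils::write.table(as.data.frame(tibble::as_tibble(scan)), cfg$output,
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!quiet)
    for (i in seq_len(nrow(sl)))
      message(sprintf("%-12s %-3s slope %.3f", sl$method[i], sl$variable[i],
                      sl$slope[i]))
  invisible(scan)
}

#' Run a forward-backward reversibility check from a config
#'
#' @inheritParams mash_run
#' @return the deviation tibble from [reversibility_check()], invisibly.
#' @export
mash_reverse_check <- function(config, quiet = FALSE) {
  cfg <- read_run_config(config)
  if (is.null(cfg$ic))
    stop("`mash_reverse_check` needs an explicit `initial` block", call. = FALSE)
  dev <- reversibility_check(cfg$model, cfg$ic, cfg$dt, cfg$t_max,
                             method = cfg$method, xi = cfg$xi,
                             max_root_iters = cfg$max_root_iters,
                             swap_tol = cfg$swap_tol)
  if (!quiet)
    for (i in seq_len(nrow(dev)))
      message(sprintf("%-3s max relative deviation %.3e", dev$variable[i],
                      dev$deviation[i]))
  invisible(dev)
}
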