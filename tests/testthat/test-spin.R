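test_that("spin rotations are exact rotations", {
  # z-axis precession
  S <- spin_rotate(c(1, 0, 0), c(0, 0, 2), 0.4)
  expect_equal(S, c(cos(0.8), sin(0.8), 0), tolerance = 1e-14)
  # zero generator is the identity
  expect_identical(spin_rotate(c(0.3, -0.4, 0.5), c(0, 0, 0), 3), c(0.3, -0.4, 0.5))
  # norm preservation and exact inversion for random axes
  set.seed(1)
  for (k in 1:20) {
    S <- stats::rnorm(3); S <- S / sqrt(sum(S^2))
    w <- stats::rnorm(3); dt <- stats::runif(1, -3, 3)
    S1 <- spin_rotate(S, w, dt)
    expect_equal(sum(S1^2), 1, tolerance = 1e-14)
    expect_equal(spin_rotate(S1, w, -dt), S, tolerance = 1e-13)
  }
})

test_that("NAC generator reproduces the coefficient Schroedinger evolution", {
  # uncoupled surfaces: pure z precession at the gap
  el <- adiabatize(lvc_model(omega = 1e-6, E = c(-0.02, 0.02)), 0)
  expect_equal(spin_generator_nac(el, 0.1), c(0, 0, 0.04), tolerance = 1e-14)
  # brute-force coefficient ODE vs exact rotation, constant generator
  set.seed(2)
  for (k in 1:5) {
    S0 <- stats::rnorm(3); S0 <- S0 / sqrt(sum(S0^2))
    V0 <- stats::runif(1, -0.01, 0); V1 <- stats::runif(1, 0, 0.01)
    Tc <- stats::runif(1, -0.02, 0.02)
    S_ode <- coef_ode_rk4(S0, function(t) V0, function(t) V1, function(t) Tc,
                          0, 3, nsub = 4000)
    S_rot <- spin_rotate(S0, c(0, -2 * Tc, V1 - V0), 3)
    expect_equal(S_rot, S_ode, tolerance = 1e-10)
  }
})

test_that("NAC spin steps track a time-dependent coefficient ODE at third order", {
  # linearly varying gap and coupling across the step; midpoint generator
  V0f <- function(t) -0.005 - 1e-4 * t
  V1f <- function(t) 0.005 + 2e-4 * t
  Tf <- function(t) 0.01 + 5e-4 * t
  S0 <- c(0.3, -0.5, sqrt(1 - 0.34))
  err <- sapply(c(2, 1, 0.5), function(dt) {
    ref <- coef_ode_rk4(S0, V0f, V1f, Tf, 0, dt, nsub = 5000)
    # endpoint-averaged generator (the symmetric NAC update)
    w <- 0.5 * (c(0, -2 * Tf(0), V1f(0) - V0f(0)) +
                c(0, -2 * Tf(dt), V1f(dt) - V0f(dt)))
    max(abs(spin_rotate(S0, w, dt) - ref))
  })
  expect_lt(err[2], err[1] / 6)   # O(dt^3) per step
  expect_lt(err[3], err[2] / 6)
})

test_that("ATDC generator matches its contracts", {
  el <- adiabatize(tully, -0.4)
  # chi = 0: pure z rotation by the trapezium-averaged gap
  ov <- wf_overlap(el$U, el$U, dt = 2)
  expect_equal(spin_generator_atdc(ov, 0.01, 0.03), c(0, 0, 0.02), tolerance = 1e-14)
  # constant gap and coupling: ATDC equals fine-step NAC propagation
  a <- 0.013 * 1.5  # wavefunction rotation over the step: chi = T * dt
  R <- matrix(c(cos(-a), sin(-a), -sin(-a), cos(-a)), 2, 2)
  ov <- wf_overlap(el$U, el$U %*% R, dt = 1.5)
  w <- spin_generator_atdc(ov, 0.02, 0.02)
  S0 <- c(0.3, -0.5, sqrt(1 - 0.34))
  fine <- S0
  for (k in 1:1000) fine <- spin_rotate(fine, c(0, -2 * 0.013, 0.02), 1.5 / 1000)
  expect_equal(spin_rotate(S0, w, 1.5), fine, tolerance = 1e-12)
})

test_that("ATDC and NAC spin updates differ at third order on a smooth segment", {
  q0 <- -0.5; v <- 16 / 2000
  S0 <- c(0.1, 0.2, sqrt(1 - 0.05))
  err <- sapply(c(2, 1, 0.5), function(dt) {
    e0 <- adiabatize(tully, q0)
    e1 <- adiabatize(tully, q0 + v * dt, U_ref = e0$U)
    ov <- wf_overlap(e0$U, e1$U, dt)
    S_atdc <- spin_rotate(S0, spin_generator_atdc(ov, e0$gap, e1$gap), dt)
    w <- 0.5 * (spin_generator_nac(e0, v) + spin_generator_nac(e1, v))
    max(abs(S_atdc - spin_rotate(S0, w, dt)))
  })
  expect_lt(err[2], err[1] / 5)
  expect_lt(err[3], err[2] / 5)
})

test_that("local-diabatization step obeys its limiting cases", {
  el <- adiabatize(tully, -0.4)
  S0 <- c(0.3, -0.5, sqrt(1 - 0.34))
  # chi = 0: commuting z rotations, identical to ATDC
  ov0 <- wf_overlap(el$U, el$U, dt = 2)
  expect_equal(spin_step_ld(S0, ov0, 0.01, 0.03),
               spin_rotate(S0, spin_generator_atdc(ov0, 0.01, 0.03), 2),
               tolerance = 1e-13)
  # zero gaps: pure y rotation by twice the wavefunction angle
  a <- 0.3
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  ov <- wf_overlap(el$U, el$U %*% R, dt = 1)
  expect_equal(spin_step_ld(S0, ov, 0, 0),
               spin_rotate(S0, c(0, 1, 0), -2 * ov$chi_wf),
               tolerance = 1e-13)
})

# linear-in-time diabatic Hamiltonian H(t) = [[a t, c], [c, -a t]]
lz_frames <- function(a, cc) {
  list(
    gap = function(t) 2 * sqrt((a * t)^2 + cc^2),
    U_of = function(t, Uref = NULL) {
      phi <- 0.5 * atan2(2 * cc, 2 * a * t)
      U <- matrix(c(sin(phi), -cos(phi), cos(phi), sin(phi)), 2, 2)
      if (!is.null(Uref)) for (j in 1:2)
        if (sum(Uref[, j] * U[, j]) < 0) U[, j] <- -U[, j]
      U
    })
}

# LD propagation of S over [t0, t1] in nsub substeps with exact frames
lz_ld_prop <- function(S, lz, t0, t1, nsub) {
  h <- (t1 - t0) / nsub
  Uprev <- lz$U_of(t0)
  for (k in seq_len(nsub)) {
    ta <- t0 + (k - 1) * h; tb <- ta + h
    Unext <- lz$U_of(tb, Uprev)
    ov <- wf_overlap(Uprev, Unext, h)
    S <- spin_step_ld(S, ov, lz$gap(ta), lz$gap(tb))
    Uprev <- Unext
  }
  list(S = S, U1 = Uprev)
}

# independent oracle: RK4 of the diabatic-frame Schroedinger equation
lz_exact <- function(S0, a, cc, lz, t0, t1, nrk = 20000) {
  cd <- lz$U_of(t0) %*% bloch_to_coef(S0)
  h2 <- (t1 - t0) / nrk
  f <- function(cd, t) -1i * (matrix(c(a * t, cc, cc, -a * t), 2, 2) %*% cd)
  t <- t0
  for (k in seq_len(nrk)) {
    k1 <- f(cd, t); k2 <- f(cd + h2 / 2 * k1, t + h2 / 2)
    k3 <- f(cd + h2 / 2 * k2, t + h2 / 2); k4 <- f(cd + h2 * k3, t + h2)
    cd <- cd + h2 / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h2
  }
  cd
}

test_that("local diabatization solves the Landau-Zener model", {
  a <- 5e-5; cc <- 1.25e-3
  lz <- lz_frames(a, cc)
  S0 <- c(0.2, 0.3, -sqrt(1 - 0.13))
  # the substepped LD propagation is converged against a 1000-substep
  # reference across a full crossing
  full <- lz_ld_prop(S0, lz, -40, 40, 1000)
  finer <- lz_ld_prop(S0, lz, -40, 40, 8000)
  expect_lt(max(abs(full$S - finer$S)), 1e-8)
  # and agrees with the independent diabatic-frame Schroedinger oracle
  cd <- lz_exact(S0, a, cc, lz, -40, 40)
  S_ref <- coef_to_bloch(as.vector(t(full$U1) %*% cd))
  expect_equal(full$S, S_ref, tolerance = 1e-7)
  # a single LD step of typical size is already accurate at the crossing
  # point, converging at third order in the step
  errs <- sapply(c(2, 1, 0.5), function(w) {
    one <- lz_ld_prop(S0, lz, -w / 2, w / 2, 1)$S
    ref <- lz_ld_prop(S0, lz, -w / 2, w / 2, 1000)$S
    max(abs(one - ref))
  })
  expect_lt(errs[2], 1e-5)
  expect_lt(errs[2], errs[1] / 6)
  expect_lt(errs[3], errs[2] / 6)
})

test_that("all spin maps preserve the norm and are adjoint under time reversal", {
  q0 <- -0.35; v <- 16 / 2000; dt <- 1.5
  e0 <- adiabatize(tully, q0)
  e1 <- adiabatize(tully, q0 + v * dt, U_ref = e0$U)
  ov_f <- wf_overlap(e0$U, e1$U, dt)
  ov_b <- wf_overlap(e1$U, e0$U, dt)
  set.seed(3)
  for (k in 1:5) {
    S0 <- stats::rnorm(3); S0 <- S0 / sqrt(sum(S0^2))
    # averaged NACs
    wf <- 0.5 * (spin_generator_nac(e0, v) + spin_generator_nac(e1, v))
    wb <- 0.5 * (spin_generator_nac(e1, -v) + spin_generator_nac(e0, -v))
    S1 <- spin_rotate(S0, wf, dt)
    expect_equal(sum(S1^2), 1, tolerance = 1e-12)
    expect_equal(flip_spin(spin_rotate(flip_spin(S1), wb, dt)), S0,
                 tolerance = 1e-12)
    # ATDC
    S1 <- spin_rotate(S0, spin_generator_atdc(ov_f, e0$gap, e1$gap), dt)
    back <- spin_rotate(flip_spin(S1), spin_generator_atdc(ov_b, e1$gap, e0$gap), dt)
    expect_equal(flip_spin(back), S0, tolerance = 1e-12)
    # LD
    S1 <- spin_step_ld(S0, ov_f, e0$gap, e1$gap)
    expect_equal(sum(S1^2), 1, tolerance = 1e-12)
    back <- spin_step_ld(flip_spin(S1), ov_b, e1$gap, e0$gap)
    expect_equal(flip_spin(back), S0, tolerance = 1e-12)
  }
})

test_that("NAC, ATDC and LD spin maps agree at small steps", {
  q0 <- -0.45; v <- 16.16 / 2000
  S0 <- c(0.02, 0.056, -0.998); S0 <- S0 / sqrt(sum(S0^2))
  dev <- sapply(c(1, 0.5, 0.25), function(dt) {
    e0 <- adiabatize(tully, q0)
    e1 <- adiabatize(tully, q0 + v * dt, U_ref = e0$U)
    ov <- wf_overlap(e0$U, e1$U, dt)
    w_nac <- 0.5 * (spin_generator_nac(e0, v) + spin_generator_nac(e1, v))
    s1 <- spin_rotate(S0, w_nac, dt)
    s2 <- spin_rotate(S0, spin_generator_atdc(ov, e0$gap, e1$gap), dt)
    s3 <- spin_step_ld(S0, ov, e0$gap, e1$gap)
    max(abs(s1 - s2), abs(s1 - s3), abs(s2 - s3))
  })
  expect_lt(dev[2], dev[1] / 5)
  expect_lt(dev[3], dev[2] / 5)
})
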