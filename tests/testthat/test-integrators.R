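# An uncoupled two-state model: spin precesses about z only, nuclei follow
# single-surface Verlet exactly.
uncoupled <- lvc_model(omega = 1e-3, E = c(0, 0.1))

test_that("uncoupled dynamics reduce to Verlet plus z precession", {
  ic <- mash_ic(0.5, 0.3, c(0.6, 0, -0.8))
  for (m in c("nonrev-nacs", "rev-nacs", "asym-nacs")) {
    tr <- propagate(uncoupled, ic, dt = 5, t_max = 500, method = m)
    expect_equal(nrow(hops(tr)), 0L)
    expect_equal(tr$Sz, rep(-0.8, nrow(tr)), tolerance = 1e-12)
    # harmonic reference (Verlet, not the exact oscillator): energy bounded
    expect_lt(max(abs(tr$energy - tr$energy[1])), 1e-6)
  }
})

test_that("velocity-Verlet is second order and exactly reversible", {
  # free flight in the flat asymptotic region of the avoided-crossing model
  ic <- mash_ic(-30, 10, c(0, 0, -1))
  tr <- propagate(tully, ic, dt = 10, t_max = 100, method = "nonrev-nacs")
  expect_equal(tr$q[nrow(tr)], -30 + 10 / 2000 * 100, tolerance = 1e-9)
  # harmonic surface: global position error scales as dt^2 vs the closed form
  w_ho <- 1e-3
  ho <- lvc_model(omega = w_ho, E = c(0, 1))  # lower surface harmonic
  errs <- sapply(c(40, 20, 10), function(dt) {
    tr <- propagate(ho, mash_ic(1, 0, c(0, 0, -1)), dt, 2000, "nonrev-nacs")
    # exact oscillator: q(t) = cos(w t) in the dimensionless convention
    max(abs(tr$q - cos(w_ho * tr$t)))
  })
  expect_lt(errs[2], errs[1] / 3)
  expect_lt(errs[3], errs[2] / 3)
  # forward step then backward step returns the phase-space point
  ic <- mash_ic(-1.0, 16, c(0, 0, -1))
  f <- propagate(tully, ic, dt = 2, t_max = 2, method = "nonrev-nacs")
  b <- propagate(tully, final_state(f, flip = TRUE), dt = 2, t_max = 2,
                 method = "nonrev-nacs")
  expect_equal(b$q[2], ic$q, tolerance = 1e-13)
  expect_equal(-b$p[2], ic$p, tolerance = 1e-13)
})

test_that("standard symmetric steps are adjoint-reversible on hop-free segments, asym is not", {
  ic <- mash_ic(-1.5, 15.6, c(-0.04, -0.08, 0.9))
  for (m in c("nonrev-nacs", "nonrev-atdc", "nonrev-ld")) {
    rc <- reversibility_check(tully, ic, dt = 2, t_max = 200, method = m)
    expect_equal(nrow(hops(attr(rc, "forward"))), 0L)
    expect_lt(max(rc$deviation), 1e-12)
  }
  rc <- reversibility_check(tully, ic, dt = 2, t_max = 200, method = "asym-nacs")
  expect_gt(max(rc$deviation), 1e-6)
})

test_that("all method variants converge to a common state as dt shrinks", {
  ic <- mash_ic(-1.5, 15.6, c(-0.04, -0.08, 0.9))
  final_sz <- function(m, dt) {
    tr <- propagate(tully, ic, dt, t_max = 200, method = m, record_every = 1000L)
    tr$Sz[nrow(tr)]
  }
  spread <- sapply(c(2, 1, 0.5), function(dt) {
    vals <- sapply(mash_methods(), final_sz, dt = dt)
    diff(range(vals))
  })
  expect_lt(spread[2], spread[1] / 1.8)
  expect_lt(spread[3], spread[2] / 1.8)
})

test_that("rev-nacs retraces exactly through hops, rev-pc to the xi tolerance", {
  pre <- mash_preset("tully-hopping")
  fwd <- propagate(pre$model, pre$ic, pre$dt, pre$t_max, method = "rev-nacs")
  expect_gt(nrow(hops(fwd)), 0L)
  rc <- reversibility_check(pre$model, pre$ic, pre$dt, pre$t_max, "rev-nacs")
  expect_lt(max(rc$deviation), 1e-10)
  rc_pc <- reversibility_check(pre$model, pre$ic, pre$dt, pre$t_max, "rev-pc-nacs")
  expect_lt(max(rc_pc$deviation), 1e-5)
  expect_gt(nrow(hops(attr(rc_pc, "forward"))), 0L)
})

test_that("rev-nacs agrees with nonrev-nacs at third order per step", {
  ic <- mash_ic(-0.5, 16, c(0.1, 0.2, sqrt(1 - 0.05)))
  dev <- sapply(c(1, 0.5, 0.25), function(dt) {
    a <- propagate(tully, ic, dt, t_max = dt, method = "rev-nacs")
    b <- propagate(tully, ic, dt, t_max = dt, method = "nonrev-nacs")
    max(abs(a$Sz[2] - b$Sz[2]), abs(a$p[2] - b$p[2]))
  })
  expect_lt(dev[2], dev[1] / 5)
  expect_lt(dev[3], dev[2] / 5)
})

test_that("piecewise-continuous steps reduce to the standard step when no hop occurs", {
  ic <- mash_ic(-1.5, 15.6, c(-0.04, -0.08, 0.9))
  for (pair in list(c("rev-pc-nacs", "nonrev-nacs"),
                    c("rev-pc-atdc", "nonrev-atdc"),
                    c("rev-pc-ld", "nonrev-ld"))) {
    a <- propagate(tully, ic, dt = 2, t_max = 200, method = pair[1])
    b <- propagate(tully, ic, dt = 2, t_max = 200, method = pair[2])
    expect_equal(nrow(hops(a)), 0L)
    expect_identical(a$q, b$q)   # bitwise: the same code path runs
    expect_identical(a$Sz, b$Sz)
  }
})

test_that("hop-time root search converges quickly and conserves energy at large dt", {
  pre <- mash_preset("tully-hopping")
  tr <- propagate(pre$model, pre$ic, dt = 4, t_max = pre$t_max,
                  method = "rev-pc-nacs")
  h <- hops(tr)
  expect_gt(nrow(h), 0L)
  expect_true(all(h$root_iters <= 10))
  # the hop itself adds no energy error beyond the ambient Verlet fluctuation
  acc <- h[h$kind == "accepted", ]
  expect_gt(nrow(acc), 0L)
  dE <- abs(diff(tr$energy))
  hop_steps <- findInterval(acc$t, tr$t)
  expect_lt(max(dE[hop_steps]), 3 * max(dE[-hop_steps]) + 1e-8)
  expect_lt(max(abs(tr$energy - tr$energy[1])), 1e-5)
})

test_that("backward propagation via negative dt matches the explicit flip", {
  pre <- mash_preset("tully-hopping")
  fwd <- propagate(pre$model, pre$ic, pre$dt, 400, method = "rev-nacs")
  fin <- final_state(fwd)
  # negative-dt run from the final state
  bwd <- propagate(pre$model, fin, -pre$dt, -400, method = "rev-nacs",
                   t0 = fwd$t[nrow(fwd)])
  expect_equal(bwd$t[nrow(bwd)], 0, tolerance = 1e-10)
  expect_equal(bwd$q[nrow(bwd)], pre$ic$q, tolerance = 1e-9)
  expect_equal(bwd$p[nrow(bwd)], pre$ic$p, tolerance = 1e-8)
  expect_equal(bwd$Sz[nrow(bwd)], pre$ic$S[3], tolerance = 1e-9)
})

test_that("variable time-stepping subdivides only where the energy test fails", {
  pre <- mash_preset("tully-hopping")
  # smooth single-surface region: no subdivisions
  tr <- propagate(tully, mash_ic(-30, 10, c(0, 0, -1)), dt = 10, t_max = 200,
                  method = "rev-pc-nacs", e_tol = 1e-9)
  expect_true(all(attr(tr, "step_sizes") == 10))
  # infinite tolerance reduces to plain propagation
  a <- propagate_variable(pre$model, pre$ic, 4, 400, e_tol = Inf,
                          method = "rev-pc-nacs")
  b <- propagate(pre$model, pre$ic, 4, 400, method = "rev-pc-nacs")
  expect_identical(a$q, b$q)
  # near the coupling peak a large step gets bisected locally
  v <- propagate_variable(pre$model, pre$ic, 8, 400, e_tol = 1e-9,
                          method = "rev-pc-nacs")
  sizes <- attr(v, "step_sizes")
  expect_gt(length(sizes), 400 / 8)      # some steps were subdivided
  expect_true(any(sizes < 8))
  expect_true(any(sizes == 8))           # smooth stretches keep the large step
  # the subdivided trajectory still conserves energy tightly
  expect_lt(max(abs(v$energy - v$energy[1])), 1e-6)
})

test_that("|S| stays on the unit sphere for every method, including hop steps", {
  pre <- mash_preset("tully-hopping")
  for (m in mash_methods()) {
    tr <- propagate(pre$model, pre$ic, dt = 2, t_max = 600, method = m)
    expect_lt(max(abs(tr$Sx^2 + tr$Sy^2 + tr$Sz^2 - 1)), 1e-12)
    # hemisphere consistency (up to the xi band around the equator)
    ok <- tr$active == as.integer(tr$Sz > 0) | abs(tr$Sz) <= 1e-4
    expect_true(all(ok))
  }
})

test_that("invalid method names are rejected", {
  expect_error(propagate(tully, mash_ic(0, 1, c(0, 0, -1)), 1, 10,
                         method = "fssh"), "arg")
})
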