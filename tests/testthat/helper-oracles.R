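# Shared fixtures and independent oracles.

tully <- tully_model()

# one-mode LVC toy with symmetric tuning and a coupling on the same mode
toy_lvc <- function(omega = 1e-3, k = 2e-3, lam = 5e-4, E = c(0, 0)) {
  lvc_model(omega = omega, E = E, kappa1 = k, kappa2 = -k, lambda = lam)
}

# map a Bloch vector to complex coefficients (c_lower, c_upper) and back,
# with Sx = 2 Re(c1* c0), Sy = 2 Im(c1* c0), Sz = |c1|^2 - |c0|^2
bloch_to_coef <- function(S) {
  c0 <- sqrt((1 - S[3]) / 2)
  if (c0 < 1e-12) return(c(0 + 0i, 1 + 0i))
  c(c0 + 0i, complex(real = S[1], imaginary = -S[2]) / (2 * c0))
}
coef_to_bloch <- function(cc) {
  z <- Conj(cc[2]) * cc[1]
  c(2 * Re(z), 2 * Im(z), abs(cc[2])^2 - abs(cc[1])^2)
}

# fine-step RK4 on the adiabatic coefficient ODE
#   dc0/dt = -i V0 c0 - T c1 ;  dc1/dt = -i V1 c1 + T c0
# with V0(t), V1(t), T(t) supplied as functions of time
coef_ode_rk4 <- function(S0, V0f, V1f, Tf, t0, t1, nsub = 20000) {
  cc <- bloch_to_coef(S0)
  h <- (t1 - t0) / nsub
  f <- function(cc, t) {
    c(-1i * V0f(t) * cc[1] - Tf(t) * cc[2],
      -1i * V1f(t) * cc[2] + Tf(t) * cc[1])
  }
  t <- t0
  for (k in seq_len(nsub)) {
    k1 <- f(cc, t); k2 <- f(cc + h / 2 * k1, t + h / 2)
    k3 <- f(cc + h / 2 * k2, t + h / 2); k4 <- f(cc + h * k3, t + h)
    cc <- cc + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  coef_to_bloch(cc)
}

# central finite difference of a scalar or vector function
central_fd <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# time-reversal flip of a spin vector / state
flip_spin <- function(S) S * c(1, -1, 1)
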