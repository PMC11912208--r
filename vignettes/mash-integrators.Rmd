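---
title: "Time-reversible MASH integrators: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-reversible MASH integrators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revmash)
```

## The model and its assumptions

The mapping approach to surface hopping (MASH) simulates two-state
nonadiabatic dynamics with classical nuclei and a quantum electronic degree
of freedom carried by a unit Bloch spin vector $\mathbf S = (S_x, S_y,
S_z)$. The active adiabatic surface is chosen *deterministically* by the
hemisphere of $S_z$: the nuclei feel the lower-surface force $-\nabla V_0$
while $S_z < 0$ and the upper-surface force while $S_z > 0$. Between hops
the spin follows the electronic Schrödinger equation, which for real
adiabatic wavefunctions is an exact rotation

$$\dot{\mathbf S} = \boldsymbol\omega \times \mathbf S, \qquad
  \boldsymbol\omega = \bigl(0,\; -2\,\mathbf v\cdot\mathbf d,\;
  \Delta V/\hbar\bigr),$$

with $\mathbf d = \langle \Phi_0 | \nabla \Phi_1 \rangle$ the nonadiabatic
coupling (NAC) vector, $\mathbf v\cdot\mathbf d$ the time-derivative
coupling, and $\Delta V = V_1 - V_0 \ge 0$ the adiabatic gap. Our Bloch
convention is $S_z = |c_1|^2 - |c_0|^2$, $S_x = 2\,\mathrm{Re}(c_1^* c_0)$,
$S_y = 2\,\mathrm{Im}(c_1^* c_0)$; with this choice the generator above
reproduces the coefficient Schrödinger evolution exactly, which the test
suite pins with a brute-force ODE oracle. The factor 2 on the coupling axis
is the usual doubling of Hilbert-space angles on the Bloch sphere.

When $S_z$ crosses the equator the trajectory attempts a hop: the
mass-weighted momentum $\tilde p_j = p_j/\sqrt{m_j}$ is decomposed along the
normalized mass-weighted NAC $\tilde d_j \propto d_j/\sqrt{m_j}$, and the
parallel component is rescaled (keeping its sign) so the total energy
$E = \sum_j p_j^2/2m_j + V_\text{active}$ is conserved. If the parallel
kinetic energy cannot pay for an upward hop, the hop is *frustrated*: the
parallel momentum is reflected and $S_z$ is inverted so the spin stays in
the initial hemisphere. Because everything is deterministic, the equations
of motion are exactly time-reversible under $(\mathbf p, S_y) \to
(-\mathbf p, -S_y)$, and the package exploits this to build reversible
integrators — something stochastic surface-hopping methods cannot do.

## The integrator family

Eight methods are provided (`mash_methods()`), differing in (a) how the
spin generator is obtained and (b) where the spin update sits relative to
the nuclear velocity-Verlet step.

* **asym-nacs** — one full spin rotation per step using the NAC generator
  at the *end-point only*. Asymmetric, hence first order in $S_z$.
* **nonrev-nacs / nonrev-atdc / nonrev-ld** — one full spin step built
  symmetrically from both endpoints: the arithmetic mean of the endpoint
  NAC generators; the averaged time-derivative coupling (ATDC)
  $\omega_y = -2\chi/\Delta t$ obtained from the wavefunction-overlap
  rotation angle $\chi$ with a trapezium-averaged gap; or local
  diabatization (LD), $e^{Z_1\Delta t/2}\,R_y(-2\chi)\,e^{Z_0\Delta t/2}$
  with $Z_s$ the gap precession in the basis at each end. All three are
  adjoint-symmetric and hence reversible *on hop-free steps*; the hop
  processing at the end of the step breaks reversibility when a hop
  occurs.
* **rev-nacs** — the spin update is split into two half-rotations around
  the Verlet step. Within each half-rotation the axis is fixed, so
  $S_z(\varphi)$ is an explicit sinusoid and the equator crossing angle is
  available in closed form: the rotation is interrupted exactly at the
  crossing, the hop is processed there (at the current geometry), and the
  rotation continues with the post-hop generator. This makes the method
  exactly self-adjoint — forward-then-backward runs retrace to round-off
  *even through hops* — at the cost of an $O(\Delta t)$ hop-position error
  (the momentum is rescaled at the step-edge geometry, not at the true
  crossing geometry), which keeps it first order when hops occur. We
  found the closed-form split necessary: checking the sign of $S_z$ only
  after a completed half-step cannot be exactly reversible, because the
  update containing the crossing would use the pre-hop momentum forward
  but the post-hop momentum backward.
* **rev-pc-nacs / rev-pc-atdc / rev-pc-ld** — reversible
  piecewise-continuous methods. A trial standard step detects the
  crossing; an interpolation root search then locates the hop time $\tau$
  such that $|S_z(\tau)| \le \xi$; the final step is exactly two standard
  sub-steps split at $\tau$ with the rescale in between. These methods
  remain second order with hops and retrace forward-backward runs to
  about the $\xi$ tolerance.

The root search starts from linear interpolation between $S_z(0)$ and
$S_z(\Delta t)$ and then fits a polynomial (up to cubic, through the four
points nearest the current bracket) whose bracketed root gives the next
estimate; each estimate is realized by a *single* standard sub-step from
the step start, so the final trajectory is genuinely piecewise-continuous
with exactly two sub-steps. A safeguard falls back to bisection whenever
the interpolant root sticks to a bracket edge, and a bracket collapsed to
machine width is accepted as the hop time — that situation arises at
trivial-crossing-like passages where $S_z(\tau)$ is effectively
discontinuous and the root is determined exactly.

Backward propagation (`dt < 0`) is implemented by the flip
$(\mathbf p, S_y) \to (-\mathbf p, -S_y)$, running forward, and mapping
back; the conjugation symmetry of every component map makes this exact.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `dt` | — | a.u. of time | integration step (1 a.u. ≈ 0.0242 fs) |
| `xi` | `1e-4` | dimensionless | equator band for the hop-time search; the rev-pc methods are reversible up to this tolerance |
| `max_root_iters` | 10 | — | sub-step propagations allowed per root search (about 2–3 are typical; the pyrazine preset raises it to 60 because conical-intersection passages can demand bisection-level counts) |
| `e_tol` | 0 (off) | hartree | variable-stepping threshold: steps with a larger energy change are undone and bisected recursively |
| `swap_tol` | 0.1 | dimensionless | overlap-diagonal guard against state-character swaps; 0 disables it and clamps the overlap rotation to the principal branch |
| `degen_thr` | `1e-12` | hartree | gap below which a geometry is treated as degenerate (an error; conical-intersection seams are not handled geometrically) |

## Shipped models and study presets

`tully_model()` is the standard one-dimensional avoided-crossing model
($A = 0.01$, $B = 1.6$, $C = 0.005$, $D = 1$, $m = 2000$, atomic units).
`lvc_model()` implements linear vibronic coupling Hamiltonians in the
dimensionless mass-weighted convention (kinetic energy $\sum_j \omega_j
p_j^2/2$, mode mass $1/\omega_j$); the shipped
`inst/extdata/pyrazine_lvc.yaml` carries the standard 2-state 3-mode
pyrazine parameter set (energies in eV, converted on load).

Presets encode the study conditions used throughout the tests and the
acceptance script:

* `tully-hopping`: $q_0 = -1.5$, $p_0 = 16.16$, $\mathbf S(0) \propto
  [0.02, 0.056, -0.998]$, $\Delta t = 1$, $t_\text{max} = 800$ a.u. This
  trajectory crosses the interaction region and hops twice (both hops
  accepted). The step size is our choice — large enough that the hop-time
  error is visible — since only the phase-space point is printed in the
  literature for this demonstration.
* `tully-nohop`: $q_0 = -1.5$, $p_0 = 15.6$, $\mathbf S(0) \propto
  [-0.04, -0.08, 0.9]$, $t_\text{max} = 220$ a.u. At this momentum the
  passage is marginally between hopping and non-hopping: an independent
  clamped-surface Schrödinger integration shows the spin skimming the
  equator (minimum $S_z \approx -0.17$ over a full passage), and the hop
  outcome depends on details below any physical robustness. The preset
  therefore ends the window right after the coupling peak and before the
  marginal crossing, which realizes a genuinely hop-free passage at the
  printed phase-space point; the convergence-order pattern is insensitive
  to this choice.
* `pyrazine`: harmonic-Wigner ground-state nuclei, spins sampled uniformly
  from the Bloch hemisphere of the upper diabatic state at each drawn
  geometry with MASH weights $2|\mathbf n \cdot \mathbf S|$,
  $\Delta t = 1.2$ fs over 150 fs, $n = 5000$ trajectories.

## Observables

Adiabatic populations are weighted means of $h(\pm S_z)$. Diabatic
populations rotate the spin into the diabatic frame with the local mixing
angle of the adiabatizing eigenvector matrix ($S^\text{dia}_z = S_z \cos
2\theta + S_x \sin 2\theta$) and apply the same Heaviside estimator; with
hemisphere sampling this estimator gives initial-state population exactly 1
at $t = 0$ and obeys the two-state sum rule. By default the weights are
normalized by their ensemble mean (a self-normalized estimator), which
makes the sum rule exact at finite $n$; `normalize_weights = FALSE`
recovers the raw-weight estimator, which satisfies the sum rules in
expectation only. The decomposition of diabatic observables into separately
weighted population/coherence correlation functions used elsewhere in the
MASH literature is an acknowledged alternative; the rotated-spin form was
chosen because its $t = 0$ sum rules are exact by construction.

## Error analysis

The global error of a trajectory is the maximum over shared grid points of
$|x(t) - x_\text{exact}(t)|$, with the benchmark $x_\text{exact}$ computed
by `rev-pc-ld` at $\Delta t_0 = \Delta t_\text{min}/350$ (at that step all
methods agree; the ratio follows the convention used for such studies). An
RMS variant exists, and fitted orders agree between the two norms to
within 0.1, as the suite verifies. Slopes are least-squares fits of $\log
\varepsilon$ versus $\log \Delta t$ excluding points below the round-off
floor ($10^{-12}$) or above 10 % of the variable's range (out of the
asymptotic regime).

On the hop-free window all eight methods show slope ≈ 2 in momentum (the
underlying velocity-Verlet order) and all symmetric methods slope ≈ 2 in
$S_z$, while asym-nacs drops to ≈ 1. With hops, only the
piecewise-continuous methods preserve slope ≈ 2; the one-sided hop
processing of the nonreversible methods and of rev-nacs injects an
$O(\Delta t)$ error per hop, giving slope ≈ 1.

## Numerical choices and degenerate inputs

* Eigenvector sign continuity is threaded through trajectories by fixing
  signs against the previous step's frame; the positive-overlap-diagonal
  rule is the single source of truth. Absent a reference the upper column
  takes its larger component positive and the lower column is chosen so
  $\det U = +1$.
* The overlap matrix of the analytic models is orthogonal to round-off;
  the special-orthogonal polar factor is taken anyway so downstream
  formulas may assume $O \in SO(2)$ exactly.
* $\mathrm{sgn}(0)$ inherits the previous sign in hop detection, so
  equator-grazing trajectories do not hop; inside a step the detection
  actually compares the hemisphere with the active surface, which is the
  same rule under the trajectory invariant but remains well defined inside
  the $\xi$ band.
* At most one hop per (sub-)step is assumed; if a second crossing is
  detected in the remainder of a piecewise-continuous step, the remainder
  is recursively halved (a robustness extension; depth-capped).
* Degeneracy below `degen_thr` and a vanishing NAC at an attempted hop are
  explicit errors, not silently handled.

## Problem sizes used in the shipped studies

The test suite and the acceptance script run desk-scale versions of the
studies: single-trajectory reversibility and order scans on the
avoided-crossing model (ladders of five steps, benchmarks at
$\Delta t/350$; seconds to a couple of minutes), and the pyrazine ensemble
at $n = 5000$ trajectories with a $\Delta t/350$ benchmark under shared
initial conditions. The published ensemble studies used up to $10^5$
trajectories; $n = 5000$ resolves the population curves to a Monte-Carlo
standard error of about 0.008, which is sufficient to separate the
integrator families cleanly.

## What the synthetic studies do and do not show

The shipped models are analytic: potentials are smooth, overlaps are exact,
and there is no electronic-structure noise. Passing the suite shows the
integrators have their designed orders, symmetry and conservation
properties under these conditions. It does not show robustness to noisy
forces or wavefunctions from ab initio backends (no such interface is
provided), nor anything about the physical accuracy of MASH itself against
exact quantum dynamics, which is outside the package's scope. Trivial
crossings (near-zero overlap diagonals) are handled by principal-branch
clamping when `swap_tol = 0`; systems dominated by such events need
smaller steps regardless of integrator.

## Known limitations

Two electronic states only; real-valued wavefunctions (no spin–orbit
coupling); no multistate generalization; no decoherence corrections (MASH
by construction needs none); conical-intersection seams are errors rather
than handled geometrically; variable time-stepping uses energy conservation
as its only trigger, which — as the reversibility studies show — is a
weaker remedy than using a reversible integrator in the first place.
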