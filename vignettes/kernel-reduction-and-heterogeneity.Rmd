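---
title: "Compartmental models as renewal equations: the integrated form and separable heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental models as renewal equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmreduce)
```

## The model

The age-of-infection view of an outbreak in a closed population of size $N$
tracks the *cumulative force of infection* $w(t) = \int_{-\infty}^t F(\sigma)\,
d\sigma$, in terms of which the susceptible count is $S = N e^{-w}$ and $w$
solves the scalar renewal equation

$$ w(t) = \int_0^\infty b(\tau)\, \Psi(w(t-\tau))\, d\tau, \qquad
   \Psi(w) = N(1 - e^{-w}), $$

where $b(\tau)$ is the expected contribution of an individual infected
$\tau$ time units ago to the current force of infection, and $\Psi(w)$ is
the expected mass of no-longer-susceptible individuals given $w$.

Every compartmental model whose state-at-infection is a fixed probability
vector corresponds to the special kernel

$$ b(\tau) = U e^{\tau \Sigma} V, $$

coded by the triple $(V, \Sigma, U)$: $V$ (length $n$, dimensionless) is the
distribution over infected compartments at the moment of infection, $\Sigma$
($n \times n$, units 1/time) is the transition-rate matrix among infected
compartments, and $U$ (length $n$, units 1/(time·individual)) weights each
compartment's contribution to the force of infection. For this kernel the
renewal equation closes into the $n$-dimensional **integrated form**

$$ \frac{dQ}{dt} = \Sigma Q + V\, \Psi(UQ), \qquad w = UQ, $$

with $Q$ the time-integral of the compartment contents, and equivalently
into the conventional **standard form** in $(\bar s, Y)$ with
$d\bar s/dt = -(UY)\bar s$ and $dY/dt = \Sigma Y + (UY)\,\Psi'(-\log\bar s)V$.

**Separable static heterogeneity** — hosts carrying a lifelong trait $x$
with distribution $\Phi$, relative susceptibility $a(x)$ and relative
infectiousness $c(\xi)$, the kernel factorising as $a(x)b(\tau)c(\xi)$ —
changes *only* the function $\Psi$:

$$ \Psi(w) = N \int_\Omega c(\xi)\bigl(1 - e^{-a(\xi) w}\bigr)\,\Phi(d\xi),
   \qquad
   \Psi'(w) = N \int_\Omega c(\xi)\,a(\xi)\, e^{-a(\xi) w}\,\Phi(d\xi). $$

Both maps are normalised at a reference trait $\bar x$ with
$a(\bar x) = c(\bar x) = 1$; $w$ then means the cumulative force on
reference-trait individuals, $\bar s = e^{-w}$ their susceptible fraction,
and the population-wide susceptible fraction is
$s_{\mathrm{tot}} = \int \bar s^{\,a(\xi)}\Phi(d\xi)$.

For Gamma-distributed susceptibility ($a(x) = x$, mean 1, variance $1/p$)
the integral is a Laplace transform and $\Psi$ has closed forms:
$N[1 - (w/p + 1)^{-p}]$ when $c \equiv 1$ and $N[1 - (w/p+1)^{-p-1}]$ when
$c(x) = x$; the dynamics can then also be written directly in
$s_{\mathrm{tot}}$ with $ds_{\mathrm{tot}}/dt = -\bar F\,
s_{\mathrm{tot}}^{1+1/p}$ and the compartment source term
$H(s) = N s^{1+1/p}$ (resp. $N(1+1/p)s^{1+2/p}$).

## What the package computes

```{r example}
m <- sir_model(beta = 0.0005, alpha = 0.25, N = 1000)
epidemic_indices(m)
```

* `r0()`: $R_0 = \Psi'(0) \cdot (-U\Sigma^{-1}V)$ by a linear solve. The
  literature states the kernel-mass formula for the homogeneous case
  ($\Psi'(0) = N$); the heterogeneous extension with $\Psi'(0)$ in place of
  $N$ is adopted here because it is the unique definition under which the
  Euler–Lotka equation has root 0 exactly at $R_0 = 1$.
* `growth_rate()`: the real root of
  $\Psi'(0)\,U(\lambda I - \Sigma)^{-1}V = 1$, strictly decreasing above the
  spectral abscissa of $\Sigma$, found by bracketing with a Newton polish
  (residual below $10^{-12}$).
* `generation_time()`: $-(U\Sigma^{-2}V)/(U\Sigma^{-1}V)$.
* `final_size()` / `herd_immunity_threshold()`: the positive roots of
  $w = (-U\Sigma^{-1}V)\Psi(w)$ and $(-U\Sigma^{-1}V)\Psi'(w^*) = 1$
  (steady state and linearisation of the renewal equation), with attack
  rate and threshold reported as $1 - \int e^{-a(\xi)w}\Phi(d\xi)$. These
  fixed-point definitions are the natural consequences of the reduction;
  they are one-dimensional and monotone, so bisection-style bracketing is
  exact business logic, not approximation.
* `simulate_integrated()`, `simulate_standard()`,
  `simulate_gamma_stot()`: the three ODE representations.
* `solve_re()` / `solve_re_system()`: a direct trapezoidal solver for the
  renewal equation itself, kept import-free of the ODE code so it can act
  as an independent oracle for the reductions.
* Two-sex / host–vector models (`two_sex_model()`, `multitype_*`): per-type
  triples on a zero-diagonal arc structure, with per-type $\Psi_i$; the
  next-generation matrix has entries $\Psi_j'(0)(-U_j\Sigma_j^{-1}V_j)$ on
  present arcs.

## Seeding: replacing the infinite past

The renewal formulation poses the outbreak on $(-\infty, t]$ with $F$
negligible in the infinite past; a numerical run must start at a finite
time. The package's convention (`seed_eigen(w0)`) starts on the linearised
exponential ray: with $r$ the Euler–Lotka root,

$$ Q(0) = \Psi'(0)\, w_0\, (rI - \Sigma)^{-1} V, \qquad
   w(t) = w_0 e^{rt} \;(t \le 0), \qquad Y(0) = r\,Q(0), $$

which satisfies $UQ(0) = w_0$ exactly and is the unique initialisation
consistent with both the ODE and the renewal history, making oracle
comparisons well-posed. `w0` defaults to $10^{-6}$ (a warning is issued
above $10^{-2}$, where linearisation is doubtful). Subcritical models have
no growing ray; eigen seeding refuses them and `seed_explicit()` must be
used. How a *real* outbreak's finite initial condition maps onto the
infinite-past formulation is not prescribed by the theory; this convention
is the package's own choice.

## Numerical choices

* **Matrix exponential**: dense, via `Matrix::expm` (scaling-and-squaring
  class), accurate to near machine precision for the small $n$ of
  compartmental models. On uniform grids the kernel is tabulated by
  repeated multiplication with the single-step matrix $e^{h\Sigma}$, whose
  sub-stochastic character keeps accumulated rounding near machine level.
* **ODE integration**: `deSolve`'s `lsoda` (stiff-capable; quarantine rates
  can exceed recovery rates by orders of magnitude), relative tolerance
  $10^{-9}$, absolute tolerance $10^{-12}N$, output on a uniform grid.
* **Standard form in log space**: the state integrated is $w = -\log\bar s$
  (so $dw/dt = UY$) rather than $\bar s$ itself; the two systems are
  identical mathematically, but the log form cannot underflow when $\bar s$
  becomes tiny. $\bar s = e^{-w}$ is reported clipped to $[0,1]$. The
  cumulative state $Q = Q(0) + \int Y$ is carried along exactly.
* **Renewal solver**: uniform-step trapezoidal marching. The kernel is
  truncated where its *exact* tail integral
  $U(-\Sigma^{-1})e^{\tau\Sigma}V$ drops below `tail_tol` (default
  $10^{-10}$) — the matrix-exponential form makes the tail available in
  closed form, so no norm bound is needed. The implicit $\tau = 0$ node is
  resolved by fixed-point iteration to relative machine precision (looser
  inner tolerances visibly pollute the scheme's second-order convergence);
  the iteration contracts when $\tfrac h2 b(0) \Psi'(0) < 1$ and $h$ is
  halved automatically (at most 5 times) otherwise. The scheme is
  second-order: halving $h$ reduces the discrepancy against the ODE
  reduction by a factor of about 4.
* **Quadrature for $\Psi$**: trait integrals use fixed nodes so that $\Psi$
  is deterministic. Gamma traits use a 200-node generalized Gauss–Laguerre
  rule (weight $x^{p-1}e^{-x}$, computed by Golub–Welsch), which absorbs
  the density's endpoint singularity for $p < 1$ exactly — a generic
  $t/(1-t)$ Gauss–Legendre transform cannot reach $10^{-8}$ there. Generic
  continuous densities use the $t/(1-t)$ transform with 200 Gauss–Legendre
  nodes and must integrate to 1 within $10^{-8}$ on their nodes (checked).
  $\Psi'$ is always built analytically alongside $\Psi$; finite differences
  appear only in tests.
* **Root-finding**: all index roots are one-dimensional and monotone;
  bracketing (`uniroot` at tight tolerance, doubling brackets) with
  explicit residuals is used throughout, no derivative-free black boxes.
* **Closed-form $c$-modes**: `psi_gamma()` implements exactly the two
  printed cases ($c \equiv 1$, $c(x) = x$); other polynomial $c$ under a
  Gamma trait are routed through quadrature rather than ad-hoc closed
  forms.

## The fixture generator

`random_kernel_fixture(n, seed)` draws subgenerator triples with
nonnegative off-diagonal rates, strictly dominant negative diagonals,
nonnegative $U$ and a probability vector $V$;
`random_model_fixture()` rescales $U$ so $R_0$ hits a prescribed target.
These synthetic models emulate the *structure* of compartmental epidemic
models (phase-type sojourn, subcritical-to-supercritical range
$R_0 \in [1.3, 3]$, population $N = 1000$) and are used to exercise the
equivalence theorems across many random instances. They do not emulate
real surveillance data: no observation noise, no reporting delay, no
time-varying contact rates, and only the separable form of heterogeneity.
Passing tests therefore demonstrate the internal mathematical consistency
of the reductions — renewal vs integrated vs standard agreement, index
identities — not fit to any empirical outbreak.

Test problem sizes are chosen to keep each check in the seconds range:
renewal/ODE comparisons run the SIR-class benchmarks on $[0, 200]$ at
$h = 0.01$ and $0.005$; equivalence batteries use 5 fixture models at
output step 0.1; index consistency uses 50 fixtures with quadrature
cross-checks.

## Validation contracts

The suite checks, among others: $w$ nondecreasing and $S = N\,
s_{\mathrm{tot}}(w)$ along every run; $\Psi$ concave, saturating at
$N\int c\,d\Phi$, with analytic derivative matching central differences;
closed-form Gamma $\Psi$ against Laguerre quadrature; the quarantine
model's printed $-\Sigma^{-1}$, $R_0$ and generation-time formulas against
the generic machinery across random parameter draws; the homogeneous
limits ($a \equiv c \equiv 1$ atoms, $\epsilon_1 = \epsilon_2 = 1$,
$p \to \infty$); and the analytic checkpoints at $R_0 = 2$ — homogeneous
attack rate $\approx 0.797$ and HIT $1/2$; Gamma $p = 1$, $c \equiv 1$
attack rate exactly $1/2$ (from $1 + w_\infty = R_0$) and HIT
$1 - 2^{-1/2}$.

## Limitations

* Demographic turnover and waning immunity are out of scope: with
  reinfection the integrals defining $Q$ diverge, so no integrated form
  exists for such models.
* Only separable kernels $a(x)b(\tau)c(\xi)$ are reducible this way;
  non-separable $A(\tau, x, \xi)$ and dynamically changing traits are not
  supported.
* $\Sigma$ is restricted to subgenerators (nonnegative off-diagonals,
  eigenvalues with negative real part). The matrix-exponential form could
  in principle represent e.g. oscillatory kernels; these are excluded
  because the probabilistic interpretation and several index formulas rely
  on invertibility and nonnegativity. Tabulated kernels of any shape can
  still be fed to the renewal solver directly.
* The renewal solver assumes absolutely continuous kernels; kernels with
  atoms (Dirac contributions) are not handled.
* The two-sex bookkeeping does not enforce the male–female contact
  consistency constraint (total contacts of each sex with the other must
  balance); a model that violates it is accepted silently.
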