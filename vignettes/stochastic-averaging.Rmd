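---
title: "Stationary responses of noisy predator-prey systems by stochastic averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stationary responses of noisy predator-prey systems by stochastic averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The models

`lvjump` analyses two classical refinements of the Lotka–Volterra
predator–prey system, driven by a combination of continuous (Gaussian
white) and impulsive (Poisson white) environmental noise.

* **Predator saturation** (abundant prey): the interaction term is
  $b x_1 x_2 / (1 + A x_1)$ — per-predator consumption saturates as
  prey density grows.
* **Predator competition** (large predator population): the interaction
  term is $b x_1 x_2 / (1 + B x_2)$ — predators compete for a limited
  prey supply.

Both include weak prey self-competition $-s x_1^2$. The coefficients
$s$, $A$, $B$, the Gaussian intensities $2D_i$, and the jump-magnitude
variances $E[Y_i^2]$ are all *effective* parameters: the formal small
parameter of the perturbation analysis is absorbed into them, so they
are exactly the numbers one would quote for a study (e.g. $A = 0.05$,
$2D_i = 0.001$). Only these combinations enter the second-order theory;
the fourth jump moments are $3(E[Y^2])^2$ because magnitudes are
zero-mean Gaussian.

Both variants can be written on a common skeleton
$$\dot x_1 = x_1\left[\bar a - \bar b x_2 - \tfrac{s}{\bar f}(-c + \bar f x_1) + g_1\right],
\qquad \dot x_2 = x_2\left[-c + \bar f x_1 + g_2\right],$$
with *barred* effective rates and case-specific correction rates
$g_1, g_2$ that vanish when $A$ (resp. $B$) is zero. For the saturation
case $\bar f = f - cA$, $\bar b = b\bar f/f$, $\bar a = a - sc/\bar f$;
for the competition case the three defining relations are solved
jointly, which reduces to a quadratic in $\bar b$ whose positive root
is taken (the other root is non-positive for valid rates). These
definitions are pinned down by a property test asserting that the
skeleton-plus-corrections reproduces the original per-capita rates to
$10^{-12}$ relative at random parameters and states: any other reading
of the barred-parameter algebra fails that identity.

Noise enters the prey growth rate and the predator death rate. In the
stochastic model the noises are read in the Stratonovich sense and the
jump response is multiplicative, $X \to X e^{Y}$: populations remain
positive, and a jump of magnitude $Y$ shifts the log-population by $Y$.

## The averaging pipeline

The unperturbed skeleton conserves the first integral
$$r(x_1,x_2) = \bar f x_1 - c - c\log\frac{\bar f x_1}{c}
  + \bar b x_2 - \bar a - \bar a\log\frac{\bar b x_2}{\bar a} \ge 0 ,$$
whose level sets are the closed orbits around the coexistence
equilibrium $(c/\bar f,\ \bar a/\bar b)$. Under weak noise, $r$ drifts
slowly while the state circulates quickly, so the generator of $r$ is
averaged over one quasi-period $T(r)$. The jump noise contributes
third- and fourth-order derivative terms, giving a generalized
Fokker–Planck–Kolmogorov equation for the density of $r$ with
coefficients $\bar A_{11}, \bar A_{21}$ (drift/diffusion) and
$\bar A_{12}, \bar A_{22}, \bar A_{31}, \bar A_{41}$ (jump-specific,
proportional to $3\lambda_i (E[Y_i^2])^2$).

**Orbit averaging.** Time averages over one period are computed by
integrating the unperturbed flow in log coordinates
$(u,v) = (\log x_1, \log x_2)$, where it is canonically Hamiltonian
with Hamiltonian $r$ — conservation is then excellent and positivity
automatic. One circuit is two section-return legs against the section
$x_2 = \bar a/\bar b$, detected by root-finding inside an adaptive
integrator (tolerances $10^{-10}$); the classical singular quadrature
form of $T(r)$ is kept only as a cross-check in the tests. Every
averaged quantity the coefficients need is a polynomial in $x_1$ or
$x_2$ alone, so the orbit table stores only $T$ and the monomial
averages $\langle x_i^k\rangle$, $k \le 4$, plus the
noise-independent part of the drift correction; one table therefore
serves every noise setting of the same ecosystem (this is what makes
the arrival-rate sweeps cheap). The table uses levels log-spaced
between $r_{lo} = 10^{-4}\,\bar a c$ and $r_{max}$; $r_{max}$ is
enlarged automatically until the stationary tail mass beyond it is
below $10^{-8}$. Below $r_{lo}$ the analytic harmonic-limit values are
used. The default 101 levels give five-digit stability of the headline
discrepancy metrics (doubling all grids changes them by $<10^{-4}$
relative); the defaults keep a full two-case analysis in a few
seconds.

**Stationary solution.** With natural boundary behaviour (zero
probability flux at $r \to 0^+$, decay at infinity) the leading-order
balance is solved in closed form,
$p_0(r) \propto e^{\Phi(r)}/\bar A_{21}(r)$ with
$\Phi' = 2\bar A_{11}/\bar A_{21}$. Near $r = 0$,
$p_0 \sim r^{\kappa-1}$ with
$\kappa = 2\bar A_{11}(0)/\bar A_{21}'(0)$; for this noise structure
the equipartition of the harmonic limit forces $\kappa = 1$ (the
computed value is asserted to $10^{-3}$), i.e. a finite positive
density at the equilibrium level. $p_0$ is simultaneously the
*Gaussian approximation*: the solution for Gaussian forcing of equal
total intensity $2D_i + \lambda_i E[Y_i^2]$.

The first-order correction vanishes: it satisfies the same homogeneous
zero-flux equation as $p_0$, and the normalization of the perturbation
series excludes the only admissible solution (a multiple of $p_0$).
The second-order correction $p_2$ solves the same operator with a
forcing built from up to third derivatives of coefficient-times-$p_0$
products. Integrating once in $r$ (the constant vanishes by decay) and
using $p_0$ as the homogeneous solution, variation of constants gives
$p_2 = p_0 \int 2G/(\bar A_{21} p_0)$, with the free multiple of $p_0$
fixed by $\int p_2 = 0$.

**A numerical point worth recording.** The forcing $G$ needs third
derivatives in $r$. Differentiating interpolants of the products on a
fine grid fails badly near $r=0$: the chain-rule factors $r^{-k}$
amplify interpolation noise without bound, while the true functions
are analytic there. The implementation therefore (i) expands all
product derivatives through the logarithmic derivative
$L = p_0'/p_0$, so $p_0$ is never differentiated through an
interpolant, and (ii) extracts derivatives of $\log p_0$ and of the
smooth coefficient functions by local quartic least-squares fits over
windows of half-width $\max(0.35 r, 0.02)$ — wide relative to the grid,
narrow relative to the scale on which the functions vary. The tests
confirm the result against a fully independent finite-difference
construction to better than $10^{-3}$ relative $L^2$.

**Observables.** The joint stationary density is
$p(x_1,x_2) = p_R(r(x_1,x_2)) / (T(r)\,x_1 x_2)$ — probability spreads
uniformly in orbit time, and the $1/(x_1x_2)$ factor is the Jacobian
of the log-coordinate change. Marginals are adaptive quadratures of
the joint density; moments reuse the orbit averages directly, which
forces $E[X_1] = c/\bar f$ and $E[X_2] = \bar a/\bar b$ for any noise
level — a structural property of the averaged theory, not a numerical
accident. The discrepancy between the perturbation and Gaussian
marginals is measured by $\ell_2 = \int (p_{X_i} - p^G_{X_i})^2 dx_i$.
Because the two marginals differ by orders of magnitude less than
their own size at large arrival rates, the implementation integrates
the marginal of the *signed correction density* once and squares it,
rather than subtracting two separately-computed marginals.

"Relative fluctuation" is reported as the coefficient of variation
$\sqrt{\mathrm{Var}}/E$ (the dimensionless usage); the ratio
$\mathrm{Var}/E$ is exported alongside (`var_over_mean_*`) since both
readings of the phrase occur. The variance is of course computed with
the density weight (the standard definition).

## The Monte Carlo validator

`simulate_paths()` realizes the jump-diffusion model in log
coordinates, where both the Stratonovich diffusion and the jump
response are exactly additive: between jumps
$du = h_1\,dt + \sqrt{2D_1}\,dW$ with the *exact* original-model
per-capita drift, and a type-$i$ jump adds $N(0, E[Y_i^2])$ to the log
state. Because jumps are additive, drawing a per-step Poisson count
$N \sim \mathrm{Pois}(\lambda\,dt)$ and one $N(0, N\,E[Y^2])$
increment is exact in distribution for the jump component; the only
discretization error is the $O(dt)$ drift error, so nothing is gained
by event-time splitting and the path loop vectorizes across paths.
The drift step itself is a midpoint (RK2) step: a plain Euler step
spirals outward on the oscillatory Lotka–Volterra core and measurably
inflates the stationary spread when the physical dissipation is weak;
with the midpoint step the stationary moments are insensitive to $dt$
at the default $dt = 2\times10^{-3}\,T_{harm}$.

What the simulator emulates — and what it does not: it realizes
exactly the stochastic model the averaging starts from, under the
stated study conditions (e.g. 100 paths of length $t = 2000$ with 400
time units of burn-in for the validation runs). Passing validation
therefore says the *perturbation solution approximates that model*
well; it says nothing about real ecosystems, demographic
(finite-population) noise, non-Gaussian jump magnitudes, or parameter
regimes with strong noise where the slow/fast separation behind
averaging breaks down.

One honest discrepancy is documented rather than hidden: the averaged
theory pins the stationary means at the equilibrium coordinates
exactly, but the true process has an $O(\varepsilon^2)$ mean shift
(about $+1\%$ at the sparse-jump validation conditions, verified
step-size-independent). A long, converged simulation resolves this
shift far beyond its bootstrap standard error, so a "means within
3 SE" check fails even though the distributional agreement is
excellent — the corresponding assertion is kept and fails visibly in
the test suite.

## Design choices on genuinely open points

* **Boundary conditions** for the stationary equation: zero flux at
  $r \to 0^+$ and decay at infinity — the standard choice for a
  nonnegative slow variable with an inaccessible boundary; it also
  makes all once-integrated constants vanish.
* **Printed-form ambiguities.** The source algebra for the barred
  parameters admits two readings of $\bar b$; the consistency identity
  selects $\bar b = b\bar f/f$. The Itô-correction constant in the
  drift of $r$ is taken as $\bar a D_2$ (chain rule on
  $\partial^2 R/\partial X_2^2 = \bar a/X_2^2$), and the second-order
  operator uses the drift/diffusion pair $(\bar A_{11}, \bar A_{21})$,
  matching the lower orders. Differences are higher-order in every
  case.
* **Saturation denominators** $(1 + A x_1)$, $(1 + B x_2)$ are kept
  unexpanded both in the simulator drift (exactness) and inside the
  averaged drift correction (they are what the correction rates
  state); expanding them first would change nothing at the order
  retained.
* **Negative tail values of $p_R$** (the perturbation correction can
  undershoot where the density is already tiny) are *retained*, not
  clipped: clipping would silently bias the discrepancy metrics. Their
  mass is recorded as a diagnostic and warned about above $10^{-4}$.
* **Arrival-rate sweeps at constant intensity** keep
  $2D_i + \lambda E[Y^2]$ fixed, so $p_0$ is common to the whole sweep
  and every jump-specific coefficient is proportional to
  $3\lambda (E[Y^2])^2 = 3 I^2/\lambda$. The discrepancy metrics are
  then *exactly* proportional to $\lambda^{-2}$ — a structural
  consequence of second-order perturbation theory worth knowing when
  comparing against independently computed tables.

## Limitations

Transient (time-dependent) statistics are out of scope; so are
higher-than-second-order corrections, non-Gaussian jump magnitudes,
and any stability or bifurcation analysis of the deterministic
skeletons. The perturbation solution degrades as the per-jump response
becomes comparable to the stationary spread of $r$ (small $\lambda$ at
fixed intensity); that degradation is precisely what the discrepancy
tables quantify.

## A short tour

```{r, eval = FALSE}
library(lvjump)

params <- lv_params("saturation", a = 1, b = 1, c = 0.5, f = 0.5,
                    s = 0.1, A = 0.05)
noise <- lv_noise(two_D1 = 0.001, two_D2 = 0.001,
                  lambda1 = 0.1, lambda2 = 0.1, m1 = 0.08, m2 = 0.08)
fit <- lvsa(params, noise)
summary(fit)
plot(fit)

# validation against direct simulation
sim <- simulate(fit, nsim = 100, seed = 1, t_end = 2000, burn_in = 400)
mc_moments(sim)

# the arrival-rate sweep at constant jump intensity
lambda_sweep(params, c(0.05, 0.08, 0.2, 0.4, 0.6, 0.8, 1.0, 2.0),
             intensity = 0.008)
```
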