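# lvjump

Stationary statistics of Lotka–Volterra predator–prey ecosystems driven
by **combined Gaussian and Poisson white noise**, computed by stochastic
averaging of the first integral and a second-order perturbation solution
of the resulting generalized Fokker–Planck–Kolmogorov (GFPK) equation.
A jump-diffusion Monte Carlo simulator is built in for validation.

The package is for modellers in theoretical ecology and stochastic
dynamics who want the stationary probability density functions (PDFs)
and moments of population densities when the environment delivers both
continuous fluctuations and sparse random shocks (floods, fires,
outbreaks), without brute-force simulation.

## The models and the method

Two classical refinements of the Lotka–Volterra system are covered:

* **predator saturation** (abundant prey):
  interaction `b*x1*x2 / (1 + A*x1)`;
* **predator competition** (large predator population):
  interaction `b*x1*x2 / (1 + B*x2)`;

both with weak prey self-competition `-s*x1^2`. Gaussian white noises
(intensities `2*D_i`) and Poisson white noises (arrival rates
`lambda_i`, zero-mean Gaussian impulse magnitudes with variance
`E[Y_i^2]`) perturb the prey growth rate and the predator death rate.

Both variants are rewritten on a common skeleton with effective
("barred") rates; its unperturbed core conserves the first integral

```
r(x1,x2) = f̄·x1 − c − c·log(f̄·x1/c) + b̄·x2 − ā − ā·log(b̄·x2/ā) ≥ 0,
```

whose level sets are the closed orbits around the coexistence
equilibrium `(c/f̄, ā/b̄)`. Averaging the slow dynamics of `r` over one
orbit period `T(r)` yields a one-dimensional GFPK equation whose
third/fourth-order terms carry the jump statistics. Its stationary
solution is built as `p_R = p0 + p2`:

* `p0` — the zero-flux drift/diffusion solution, which equals the
  **Gaussian approximation** (Gaussian forcing of equal total intensity
  `2D + lambda·E[Y^2]`);
* `p2` — the second-order jump correction (the first-order term
  vanishes identically).

Joint and marginal population PDFs follow from
`p(x1,x2) = p_R(r)/(T(r)·x1·x2)`, and the jump-vs-Gaussian discrepancy
is measured by the L2 metric `∫ (p_Xi − p_Xi_Gaussian)² dxi`.

## Worked example

```r
library(lvjump)

params <- lv_params("saturation", a = 1, b = 1, c = 0.5, f = 0.5,
                    s = 0.1, A = 0.05)
noise  <- lv_noise(two_D1 = 0.001, two_D2 = 0.001,
                   lambda1 = 0.1, lambda2 = 0.1, m1 = 0.08, m2 = 0.08)
fit <- lvsa(params, noise)
summary(fit)
```

```
Stochastic-averaging fit: saturation case
Unified-form effective parameters (saturation case)
  a_bar = 0.8947368421, b_bar = 0.95, f_bar = 0.475, c = 0.5
  equilibrium (x1*, x2*) = (1.052631579, 0.9418282548)
...
  stationary grid: r in [4.47e-05, 2.86], kappa = 1
  max pG = 9.4509, max pR = 11.312
  Second-order perturbation solution:
     E[X1] = 1.05263, E[X2] = 0.941828
    Var[X1] = 0.230032, Var[X2] = 0.102909
    relative fluctuations: 0.455636, 0.340608
  Gaussian approximation:
     E[X1] = 1.05263, E[X2] = 0.941828
    Var[X1] = 0.226728, Var[X2] = 0.101431
    relative fluctuations: 0.452352, 0.338153
```

Reading this: the stationary means sit at the coexistence equilibrium
(a structural property of the averaged theory), while the jump noise
raises the density peak above the Gaussian approximation
(`max pR = 11.31 > max pG = 9.45`) and widens the variances slightly —
sparse large shocks concentrate more probability near the equilibrium
*and* fatten the tails relative to equally-intense Gaussian forcing.

Sweeping the arrival rate at constant jump intensity
`lambda*E[Y^2] = 0.008` shows Poisson forcing converging to Gaussian
forcing as shocks become dense and small:

```r
lambda_sweep(params, c(0.05, 0.2, 1.0), intensity = 0.008)
```

```
  lambda     m        l2_x1        l2_x2
1   0.05 0.160 1.285601e-02 1.662331e-02
2   0.20 0.040 8.034985e-04 1.038955e-03
3   1.00 0.008 3.213951e-05 4.155799e-05
```

`plot(fit)` draws both marginals against their Gaussian
approximations; `simulate(fit, nsim = 100, seed = 1)` runs the
jump-diffusion Monte Carlo validator, and `empirical_pdf()` /
`mc_moments()` summarize it.

Configuration-driven runs (YAML, see `inst/extdata/*.yaml`) are
available through `run_solve()`, `run_compare()`, `run_simulate()`, or
from a shell via `inst/cli/lvjump.R`:

```sh
Rscript inst/cli/lvjump.R compare \
  --config inst/extdata/case1_jump_validation.yaml --out out/
```

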