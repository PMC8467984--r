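# Predator-saturation ecosystem with sparse, large Poisson jumps
# (lambda = 0.1, E[Y^2] = 0.08: intensity 0.008) and weak Gaussian noise
model:
  case: saturation
  a: 1.0
  b: 1.0
  c: 0.5
  f: 0.5
  s: 0.1
  A: 0.05
noise:
  two_D1: 0.001
  two_D2: 0.001
  lambda1: 0.1
  lambda2: 0.1
  m1: 0.08
  m2: 0.08
numerics:
  seed: 1
compare:
  intensity: 0.008
  lambdas: [0.05, 0.08, 0.2, 0.4, 0.6, 0.8, 1.0, 2.0]
simulate:
  n_paths: 100
  t_end: 2000
  burn_in: 400
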