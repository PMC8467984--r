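# Predator-competition ecosystem, reference study conditions
model:
  case: competition
  a: 1.0
  b: 1.0
  c: 0.5
  f: 0.5
  s: 0.1
  B: 0.05
noise:
  two_D1: 0.005
  two_D2: 0.005
  lambda1: 0.5
  lambda2: 0.5
  m1: 0.02
  m2: 0.02
numerics:
  seed: 1
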