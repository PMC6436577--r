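# spectfuse pipeline configuration (defaults shown).
# Every value is optional; unset keys use the package defaults.

seed: 1

nsct:
  levels: 3            # pyramid levels J
  dirs: [2, 3, 3]      # directional stages per level: 2^n bands each
  filter_family: maxflat

pcnn:
  iterations: 50       # simulation steps T per firing-count map
  fixed:               # parameters of the nsct_pcnn baseline / injection
    alpha_theta: 0.2
    beta: 0.2
    v_theta: 20

sfla:                  # per-band optimization budget
  pop_size: 12
  memeplexes: 3
  local_steps: 5
  shuffles: 5
  bounds:
    lower: [0.01, 0.0, 1.0]    # alpha_theta, beta, V_theta
    upper: [1.0,  1.0, 50.0]

fusion:
  fitness: entropy     # entropy | gradient | entropy_gradient
  tie_policy: mean     # mean | first
  low_rule: pcnn       # pcnn | energy (regional average energy)
  shared_optimization: false
  inject_fixed: false
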