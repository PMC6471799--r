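eps: 0.35
eps_relaxed: 0.7
f: 5
xi: 0.35
zeta: 0.2
w1: 1.0
w2: 1.0
overlap_factor: 0.65
exclusion_depth: 3
theta_grid_step: 0.05
central_norm: per-angle
break_threshold: 2.0
max_recursions: 1000000
seed: 1
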