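# Example experiment configuration: one phantom on a 5 mm grid, all six
# planning strategies, both breath-hold reproducibility sets, 200 simulated
# treatments per plan per set (a quick run; the study-scale value is 10000).
n_phantoms: 1
n_samples: 200
seed: 1
eval_sets: [A, B]
strategies:
  - proton3D-PS
  - proton3D-BH
  - proton4D-BH
  - photon3D-PS
  - photon3D-BH
  - photon4D-BH
pars:
  layer_spacing_mm: 8
  spot_spacing_mm: 8
obj:
  n_shell: 400
  n_cw: 200
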