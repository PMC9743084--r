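# Asymmetric variant: well C is shallower (2.5 kT), for
# mechanism-difference demonstrations.
potential:
  centers:
    - [0.0, 1.0]
    - [-0.8660254037844387, -0.5]
    - [0.8660254037844384, -0.5]
  depths: [4.0, 4.0, 2.5]
  widths: [0.3, 0.3, 0.3]
states:
  labels: [A, B, C]
  centers:
    - [0.0, 1.0]
    - [-0.8660254037844387, -0.5]
    - [0.8660254037844384, -0.5]
  radii: [0.3, 0.3, 0.3]
dynamics:
  timestep: 0.005
  diffusion: 1.0
sampler:
  n_trials: 2000
  max_length_factor: 50
  equilibrate: true
  max_equil_trials: 5000
analysis:
  bin_width: 0.1
  xlim: [-2.0, 2.0]
  ylim: [-2.0, 2.0]
  decorrelated_only: false
seed: 42
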