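# Illustrative 7 T cardiac 31P prior knowledge (synthetic fixture values).
# Shifts in ppm relative to PCr at 0 ppm; linewidths in Hz FWHM; phases in
# degrees. All peaks share one zero-order phase. ATP multiplets carry
# literature-style J-couplings; the bounds below are fixtures chosen for
# synthetic data, not literature claims.
version: 1
peaks:
- name: PCR
  shift: 0.0
  shift_bounds: [-0.5, 0.5]
  linewidth: 12.0
  linewidth_bounds: [3.0, 60.0]
  amplitude: 10.0
  amplitude_bounds: [0.0, .inf]
  group_phase: phase0
- name: ATP_GAMMA
  shift: -2.48
  shift_bounds: [-2.98, -1.98]
  linewidth: 14.0
  linewidth_bounds: [3.0, 60.0]
  amplitude: 5.0
  amplitude_bounds: [0.0, .inf]
  multiplet_n: 2
  j_coupling: 17.0
  group_phase: phase0
- name: ATP_ALPHA
  shift: -7.52
  shift_bounds: [-8.02, -7.02]
  linewidth: 14.0
  linewidth_bounds: [3.0, 60.0]
  amplitude: 5.0
  amplitude_bounds: [0.0, .inf]
  multiplet_n: 2
  j_coupling: 16.0
  group_phase: phase0
- name: ATP_BETA
  shift: -16.26
  shift_bounds: [-16.76, -15.76]
  linewidth: 16.0
  linewidth_bounds: [3.0, 60.0]
  amplitude: 5.0
  amplitude_bounds: [0.0, .inf]
  multiplet_n: 3
  j_coupling: 16.0
  group_phase: phase0
- name: PDE
  shift: 2.6
  shift_bounds: [2.1, 3.1]
  linewidth: 18.0
  linewidth_bounds: [3.0, 80.0]
  amplitude: 2.0
  amplitude_bounds: [0.0, .inf]
  group_phase: phase0
- name: DPG23
  shift: 5.6
  shift_bounds: [5.0, 6.2]
  linewidth: 20.0
  linewidth_bounds: [3.0, 80.0]
  amplitude: 2.0
  amplitude_bounds: [0.0, .inf]
  group_phase: phase0
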