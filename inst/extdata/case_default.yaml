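# Default study case: severe adult sagittal imbalance from thoracolumbar
# kyphosis (type K deformity). PI appears as 59 in the source case
# description and as 60 in the outcome arithmetic; 60 is used here so that
# the pre-operative PI - LL mismatch is exactly 72 degrees.
patient:
  PI: 60
  PT: 49
  TK: 50
  LL: -12
  lumbar_cobb_coronal: 3
  body_mass: 60
plan:
  uiv: T10
  liv: S1
  pso_level: L3
  facetectomy_factor: 0.5
  pso_wedge_cap: 35
  target_LL: 48
  target_TK: 36.5
  flexion_angle: 10
  head_offset: 45
solver:
  load_steps: 10
  tol: 1.0e-6
  max_iter: 50
  elements_per_segment: 8
  n_fibers: 32
seed: 1
output_dir: results
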