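# Example cellflow run configuration.  Unset keys take the calibrated
# defaults; unknown keys are rejected.
seed: 7
resolution: scaled

cell:
  diameter_um: 16
  nuclear_cytoplasmic_ratio: 0.29

cytoskeleton:
  k_s: 120        # nucleus_network k_s follows as 5 x 120 = 600
  k_v: 10
  rho: 0.8
  w: 5
  topology: M2

units:
  length_um: 1
  pressure_Pa: 6
  time_s: 1.0e-5
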