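# Reference survey-generator profiles (synthetic emulation).
# Level centers are inspired by published stratum-specific centroid
# locations for clinicians vs laypeople on the 5-level HL7 severity scale:
# doctors place Absent lower and Severe/Extreme higher than laypeople,
# while Mild/Moderate roughly coincide. They parameterize an emulator and
# are not estimates of any deposited dataset.
profiles:
  doctor:
    level_centers: {Absent: 9, Mild: 26, Moderate: 47, Severe: 67, Extreme: 88}
    center_sd: 5
    half_width_mean: 8
    half_width_sd: 3
    rp_jitter_sd: 4
  patient:
    level_centers: {Absent: 14, Mild: 26.5, Moderate: 41, Severe: 58, Extreme: 71}
    center_sd: 5
    half_width_mean: 8
    half_width_sd: 3
    rp_jitter_sd: 4
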