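# Default timing distributions for the division-movie generator.
# Each entry is mean/sd (minutes) of a normal truncated at zero.
cluster_appearance:   # mid-cell cluster appearance before completion of cytokinesis
  mean: 20
  sd: 15
cluster_lifetime:     # only used when clusters are allowed to outlive completion
  mean: 20
  sd: 16
burst_onset:          # biosensor-ratio rise before completion of cytokinesis
  mean: 22
  sd: 12
burst_duration:       # length of the high-ratio state
  mean: 19
  sd: 9
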