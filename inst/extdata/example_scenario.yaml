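# Synthetic single-channel scenario: 13-receiver array, sheared flow,
# mixed swim behaviors. Values are the generator defaults written out.
n_receivers: 13
nominal_spacing: 70
pri: 5
beacon_interval: 30
sound_speed: 1470
arrival_noise_sd: 0.0002
detection_prob: 0.7
corrupt_frac: 0.001
channel:
  length: 1000
  width: 50
  depth: 4
  peak_speed: 0.5
  roughness_z0: 0.003
behaviors:
  - label: positive_rheotaxis
    fraction: 0.25
    swim_speed: 0.10
    diel: false
  - label: negative_rheotaxis
    fraction: 0.25
    swim_speed: 0.10
    diel: false
  - label: lateral
    fraction: 0.25
    swim_speed: 0.09
    diel: false
  - label: passive
    fraction: 0.25
    swim_speed: 0.0
    diel: false
fork_length_mm: [76.6, 3]
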