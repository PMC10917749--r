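# Small end-to-end demo: four model groups (2D, 3D, semantic, NAM) injected
# at distinct latencies into a 6-participant synthetic cohort.
seed: 1
n_conditions: 12
n_participants: 8
n_trials_per_condition: 5
n_channels: 12
epoch_window: [-0.2, 0.6]
baseline_window: [-0.2, 0.0]
latencies: [0.13, 0.17, 0.16, 0.30]
amplitude: 4
n_boot: 500
peak_window: [0.0, 0.6]
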