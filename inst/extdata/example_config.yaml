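# Example configuration: interacting groups under moderate selection on a
# low-resource landscape (unspecified keys take package defaults).
resource_level: 50
selection_differential: 0.5
interaction_radius: 2
innovation_cost: 10
learning_cost: 0
n_steps: 1000
n_runs: 10
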