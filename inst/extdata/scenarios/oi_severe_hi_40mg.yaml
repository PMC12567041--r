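scenario_id: oi_severe_hi_40mg
type: oi
impairment: CP-C-ugt-modified
dose: 40
n_trials: 10
n_subjects: 10
seed: 20
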