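scenario_id: table2_40mg_single_hv
type: pk_summary
analyte: asciminib
regimens:
  asciminib: {dose: 40, interval: single}
population: {base: healthy, impairment: none}
n_trials: 10
n_subjects: 10
seed: 20
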