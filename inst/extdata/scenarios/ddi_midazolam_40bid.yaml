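scenario_id: ddi_midazolam_40bid
type: ddi
analyte: midazolam
regimens:
  asciminib: {dose: 40, interval: BID, n_days: 5}
  midazolam: {dose: 4, interval: single, start_day: 3}
population: {base: healthy, impairment: none}
n_trials: 10
n_subjects: 10
seed: 20
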