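scenario_id: ddi_clarithromycin_40mg
type: ddi
analyte: asciminib
regimens:
  clarithromycin: {dose: 500, interval: BID, n_days: 8}
  asciminib: {dose: 40, interval: single, start_day: 5}
population: {base: healthy, impairment: none}
n_trials: 10
n_subjects: 10
seed: 20
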