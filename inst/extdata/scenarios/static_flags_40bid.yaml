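scenario_id: static_flags_40bid
type: static
dose: 40
interval: BID
seed: 1
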