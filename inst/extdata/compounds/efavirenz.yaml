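# Synthetic reduced stand-in for efavirenz 600 mg QD (moderate CYP3A4
# inducer).
schema_version: 1
name: efavirenz
model_type: reduced
physchem: {molecular_weight: 315.7}
binding: {fu_plasma: 0.006}
pk:
  ka: 0.6
  vc: 250
  q: 0
  vp: 1
  clint_u_h: 1550   # CL ~ 9 L/h
  cl_other: 0.0
  fg_base: 1.0
  fu_gut: 1.0
  q_gut: 18
  kpuu_liver: 1.0
pathways: []
gut_enzyme: none
act_enzyme: none
interactions:
  induction:
    - {target: CYP3A4, indc50_u: 0.017, indmax: 3.3}
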