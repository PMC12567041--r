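# Synthetic reduced stand-in for fluconazole (moderate CYP3A4 inhibitor,
# also a UGT2B7 inhibitor).
schema_version: 1
name: fluconazole
model_type: reduced
physchem: {molecular_weight: 306.3}
binding: {fu_plasma: 0.89}
pk:
  ka: 1.2
  vc: 46
  q: 0
  vp: 1
  clint_u_h: 0.75   # CL ~ 0.66 L/h hepatic
  cl_other: 0.55    # renal
  fg_base: 1.0
  fu_gut: 1.0
  q_gut: 18
  kpuu_liver: 1.0
pathways: []
gut_enzyme: none
act_enzyme: none
interactions:
  inhibition:
    - {target: CYP3A4, ki_u: 10.7}
    - {target: CYP2C9, ki_u: 30.3}
    - {target: UGT2B7, ki_u: 700}
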