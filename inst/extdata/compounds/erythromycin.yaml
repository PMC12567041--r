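# Synthetic reduced stand-in for erythromycin 500 mg QID (moderate CYP3A4
# inhibitor, time-dependent inactivation).
schema_version: 1
name: erythromycin
model_type: reduced
physchem: {molecular_weight: 733.9}
binding: {fu_plasma: 0.30}
pk:
  ka: 1.0
  vc: 55
  q: 0
  vp: 1
  clint_u_h: 170    # CL ~ 26 L/h
  cl_other: 6.0
  fg_base: 0.75
  fu_gut: 1.0
  q_gut: 13
  kpuu_liver: 1.0
pathways: []
gut_enzyme: none
act_enzyme: none
interactions:
  tdi:
    - {target: CYP3A4, ki_app_u: 21.0, kinact: 2.2}
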