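# Synthetic reduced stand-in for omeprazole (CYP2C19/CYP3A4 substrate,
# CYP2C19 normal-metabolizer phenotype).
schema_version: 1
name: omeprazole
model_type: reduced
physchem: {molecular_weight: 345.4}
binding: {fu_plasma: 0.03}
pk:
  ka: 2.0
  tlag: 0.35       # gastric-emptying lag, shared on co-administration
  vc: 15
  q: 0
  vp: 1
  clint_u_h: 2600   # CL_h ~ 28 L/h
  cl_other: 0.0
  fg_base: 0.95
  fu_gut: 1.0
  q_gut: 18
  kpuu_liver: 1.0
pathways:
  - {enzyme: CYP2C19, fm: 0.87, inducible: false}
  - {enzyme: CYP3A4,  fm: 0.10, inducible: true}
gut_enzyme: CYP3A4
act_enzyme: CYP3A4
interactions: {}
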