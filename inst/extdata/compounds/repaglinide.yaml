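# Synthetic reduced stand-in for repaglinide (CYP2C8/CYP3A4 substrate).
# OATP1B1 uptake is not modeled; the residual (non-CYP) fraction absorbs it.
schema_version: 1
name: repaglinide
model_type: reduced
physchem: {molecular_weight: 452.6}
binding: {fu_plasma: 0.015}
pk:
  ka: 2.5
  tlag: 0.35       # gastric-emptying lag, shared on co-administration
  vc: 25
  q: 0
  vp: 1
  clint_u_h: 5300
  cl_other: 0.0
  fg_base: 0.87
  fu_gut: 1.0
  q_gut: 18
  kpuu_liver: 1.0
pathways:
  - {enzyme: CYP2C8, fm: 0.63, inducible: false}
  - {enzyme: CYP3A4, fm: 0.25, inducible: true}
gut_enzyme: CYP3A4
act_enzyme: CYP3A4
interactions: {}
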