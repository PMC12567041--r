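# Synthetic reduced stand-in for caffeine as a CYP1A2 probe substrate.
schema_version: 1
name: caffeine
model_type: reduced
physchem: {molecular_weight: 194.2}
binding: {fu_plasma: 0.68}
pk:
  ka: 4.0
  tlag: 0.35       # gastric-emptying lag, shared on co-administration
  vc: 36
  q: 0
  vp: 1
  clint_u_h: 9.3    # low extraction, CL ~ 6 L/h
  cl_other: 0.1
  fg_base: 1.0
  fu_gut: 1.0
  q_gut: 18
  kpuu_liver: 1.0
pathways:
  - {enzyme: CYP1A2, fm: 0.95, inducible: true}
gut_enzyme: none
act_enzyme: CYP1A2
interactions: {}
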