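# Synthetic reduced stand-in for S-warfarin as a CYP2C9 probe substrate.
schema_version: 1
name: warfarin
model_type: reduced
physchem: {molecular_weight: 308.3}
binding: {fu_plasma: 0.008}
pk:
  ka: 1.0
  tlag: 0.35       # gastric-emptying lag, shared on co-administration
  vc: 9
  q: 0
  vp: 1
  clint_u_h: 20.5   # low-extraction: CL ~ fu x CLint ~ 0.16 L/h
  cl_other: 0.0
  fg_base: 1.0
  fu_gut: 1.0
  q_gut: 18
  kpuu_liver: 1.0
pathways:
  - {enzyme: CYP2C9, fm: 0.85, inducible: false}
gut_enzyme: none
act_enzyme: none
interactions: {}
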