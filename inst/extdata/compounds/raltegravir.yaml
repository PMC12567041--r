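# Synthetic reduced stand-in for raltegravir as a UGT1A1 probe substrate
# (all non-renal clearance assigned to UGT1A1, a conservative convention).
schema_version: 1
name: raltegravir
model_type: reduced
physchem: {molecular_weight: 444.4}
binding: {fu_plasma: 0.17}
pk:
  ka: 1.2
  tlag: 0.35       # gastric-emptying lag, shared on co-administration
  vc: 90
  q: 0
  vp: 1
  clint_u_h: 290    # CL_h ~ 30 L/h
  cl_other: 3.0     # renal
  fg_base: 1.0
  fu_gut: 1.0
  q_gut: 18
  kpuu_liver: 1.0
pathways:
  - {enzyme: UGT1A1, fm: 1.0, inducible: false}
gut_enzyme: none
act_enzyme: none
interactions: {}
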