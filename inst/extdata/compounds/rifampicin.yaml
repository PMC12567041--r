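# Synthetic reduced stand-in for rifampicin 600 mg QD (strong CYP3A4
# inducer), with autoinduced steady-state clearance and published-style
# in vivo induction parameters (unbound IndC50, Indmax).
schema_version: 1
name: rifampicin
model_type: reduced
physchem: {molecular_weight: 822.9}
binding: {fu_plasma: 0.15}
pk:
  ka: 1.15
  vc: 55
  q: 0
  vp: 1
  clint_u_h: 110     # CL ~ 13 L/h (autoinduced steady state)
  cl_other: 2.0
  fg_base: 1.0
  fu_gut: 1.0
  q_gut: 13
  kpuu_liver: 1.0
pathways: []
gut_enzyme: none
act_enzyme: none
interactions:
  induction:
    - {target: CYP3A4, indc50_u: 0.32, indmax: 8.0}
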