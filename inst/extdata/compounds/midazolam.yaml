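# Synthetic reduced (compartmental) stand-in for midazolam as a CYP3A4
# probe substrate; PK anchored to literature healthy-volunteer exposure.
schema_version: 1
name: midazolam
model_type: reduced
physchem: {molecular_weight: 325.8}
binding: {fu_plasma: 0.03}
pk:
  ka: 3.0          # 1/h
  tlag: 0.35       # gastric-emptying lag, shared on co-administration
  vc: 30           # L
  q: 30            # L/h inter-compartmental
  vp: 40           # L
  clint_u_h: 1600  # L/h unbound hepatic intrinsic clearance
  cl_other: 0.0    # L/h non-hepatic
  fg_base: 0.57
  fu_gut: 1.0
  q_gut: 13.7      # L/h
  kpuu_liver: 1.0
pathways:
  - {enzyme: CYP3A4, fm: 0.94, inducible: true}
gut_enzyme: CYP3A4
act_enzyme: CYP3A4
interactions: {}
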