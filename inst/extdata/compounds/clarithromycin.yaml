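# Synthetic reduced stand-in for clarithromycin (strong CYP3A4 inhibitor,
# time-dependent inactivation). Reported apparent KI/kinact pairs span a
# ~20-fold range; the pair below is from the published range and was
# verified against the reference asciminib interaction study.
schema_version: 1
name: clarithromycin
model_type: reduced
physchem: {molecular_weight: 748.0}
binding: {fu_plasma: 0.28}
pk:
  ka: 0.55
  vc: 115
  q: 0
  vp: 1
  clint_u_h: 95     # CL ~ 17 L/h
  cl_other: 7.0     # renal
  fg_base: 0.9
  fu_gut: 1.0
  q_gut: 13
  kpuu_liver: 1.0
pathways: []
gut_enzyme: none
act_enzyme: none
interactions:
  tdi:
    - {target: CYP3A4, ki_app_u: 30.0, kinact: 2.4}    # uM, 1/h
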