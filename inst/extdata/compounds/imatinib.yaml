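# Synthetic reduced stand-in for imatinib 400 mg QD (CYP3A4, UGT1A3/4,
# UGT2B17 and BCRP inhibitor). The BCRP IC50 uses the 10-fold lower value
# (0.094 uM) adopted after vesicle data confirmed higher potency; UGT
# IC50s are the printed recombinant values (Ki = IC50/2). Hepatic uptake
# (OCT1) is represented by a liver-to-plasma unbound partition of 2.
schema_version: 1
name: imatinib
model_type: reduced
physchem: {molecular_weight: 493.6}
binding: {fu_plasma: 0.05}
pk:
  ka: 0.61
  vc: 180
  q: 20
  vp: 120
  clint_u_h: 250    # CL ~ 12 L/h
  cl_other: 1.5
  fg_base: 1.0
  fu_gut: 1.0
  q_gut: 18
  kpuu_liver: 2.0
pathways: []
gut_enzyme: none
act_enzyme: CYP3A4
interactions:
  tdi:
    - {target: CYP3A4, ki_app_u: 25.0, kinact: 2.88}  # published-range values
  inhibition:
    - {target: CYP3A4,  ki_u: 2.0}
    - {target: BCRP,    ki_u: 0.047}   # IC50 0.094 uM / 2
    - {target: UGT1A3,  ki_u: 10.0}    # IC50 20 uM / 2
    - {target: UGT1A4,  ki_u: 7.5}     # IC50 15 uM / 2
    - {target: UGT2B17, ki_u: 0.035}   # IC50 0.07 uM / 2
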