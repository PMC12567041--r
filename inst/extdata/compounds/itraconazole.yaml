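# Synthetic reduced stand-in for itraconazole capsule (strong CYP3A4
# inhibitor). The hydroxy metabolite is not modeled separately; its
# contribution is folded into an effective parent unbound Ki.
schema_version: 1
name: itraconazole
model_type: reduced
physchem: {molecular_weight: 705.6}
binding: {fu_plasma: 0.0036}
pk:
  ka: 0.6
  vc: 70
  q: 60
  vp: 500
  clint_u_h: 150000   # CL ~ 14 L/h at fu 0.0036
  cl_other: 0.0
  fg_base: 0.9
  fu_gut: 1.0
  q_gut: 13
  kpuu_liver: 1.0
pathways: []
gut_enzyme: none
act_enzyme: none
interactions:
  inhibition:
    - {target: CYP3A4, ki_u: 0.0013}   # effective parent+metabolite
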