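# Asciminib whole-body PBPK compound file (victim and perpetrator).
# All concentrations in uM, time in h, volumes in L unless noted.
schema_version: 1
name: asciminib
model_type: full
physchem:
  molecular_weight: 449.85      # g/mol
  logp: 3.9
  compound_class: monoprotic base
  pka: 4.0
binding:
  fu_plasma: 0.027
  fu_plasma_renal_impaired: 0.018   # sensitivity-adjusted for severe RI
  blood_to_plasma: 0.80
absorption:
  # first-order absorption; fa stored as the effective absorbed fraction
  # (user-set 1.00 with a model-predicted output of 0.96; 0.96 is what
  # enters F = fa x Fg x Fh = 0.73 and is the default here)
  fa: 0.96
  fa_user: 1.00
  fa_cv: 9.0
  ka: 1.3            # 1/h
  ka_cv: 9.0
  tlag: 0.374        # h
  tlag_cv: 0.4
  fu_gut: 0.25
  q_gut: 5.3         # L/h
  q_gut_cv: 30
  fg_target: 0.83    # midpoint of the predicted 0.82-0.84 range
  peff_human: 3.729  # 1e-4 cm/s, informational only
distribution:
  kp_method: tissue-composition-predicted
  kp_scalar: 0.025
  vss_target: 0.8    # L/kg, whole-body incl. permeability-limited liver
enzymes:
  - {enzyme: CYP3A4,  vmax: 3.8,   km_u: 15.7,  fu_mic: 0.160,  fm_target: 0.351}
  - {enzyme: CYP2C8,  vmax: 0.136, km_u: 7.6,   fu_mic: 0.0829, fm_target: 0.005}
  - {enzyme: CYP2D6,  vmax: 0.736, km_u: 30.7,  fu_mic: 0.0680, fm_target: 0.002}
  - {enzyme: CYP2J2,  vmax: 0.355, km_u: 0.694, fu_mic: 0.0925, fm_target: 0.0076}
  - {enzyme: UGT1A3,  vmax: 1.73,  km_u: 12.9,  fu_mic: 0.0811, fm_target: 0.033}
  - {enzyme: UGT1A4,  vmax: 0.73,  km_u: 12.9,  fu_mic: 0.0811, fm_target: 0.033}
  - {enzyme: UGT2B7,  vmax: 2.04,  km_u: 12.7,  fu_mic: 0.0811, fm_target: 0.131}
  - {enzyme: UGT2B17, vmax: 17.7,  km_u: 9.41,  fu_mic: 0.0811, fm_target: 0.076}
transporters:
  - transporter: BCRP
    location: liver canalicular
    jmax: 0.2782        # pmol/min/10^6 cells, in vitro
    km: 0.0070865       # uM, intracellular unbound, optimized
    cl_pd: 0.06         # mL/min/10^6 hepatocytes, passive diffusion
    ft_target_low_dose: 0.311   # fraction of CL/F at 20 mg BID
    # global activity scalar calibrated once so the simulated with/without
    # BCRP CL/F gap at 20 mg BID equals ft_target_low_dose, then held fixed
    activity_scalar: 0.5171
renal:
  cl_renal: 0.108      # L/h (1.8 mL/min/1.73 m2)
  fe_target: 0.044
additional_clearance:
  hlm_clint_u: 0.65    # uL/min/mg microsomal protein
  hlm_clint_cv: 30
  pathway_label: hydrolysis
  fm_target: 0.0071
clearance:
  oral_clearance_target: 7.19   # L/h, CL/F with BCRP at the 20 mg BID anchor
  oral_clearance_no_bcrp: 4.96  # L/h, CL/F with the BCRP pathway removed
  reference_dose_mg: 20
  reference_regimen: BID
  # multiplier on all metabolic intrinsic clearances from the whole-body
  # calibration at the 20 mg BID anchor (see calibrate_clearances)
  metab_scale: 0.8959
inhibition:   # asciminib as perpetrator; unbound Ki (uM)
  - {target: CYP1A2,  ki_u: 10.4,  ic50_u: 20.8, conversion: half}
  - {target: CYP2A6,  ki_u: 43.6,  ic50_u: 87.1, conversion: half}
  - {target: CYP2B6,  ki_u: 2.62,  conversion: direct}
  - {target: CYP2C8,  ki_u: 0.466, conversion: direct}
  - {target: CYP2C9,  ki_u: 0.03,  conversion: direct, ki_u_invitro: 0.407}
    # 0.03 uM from sensitivity analysis against the S-warfarin interaction;
    # the in vitro value 0.407 uM is kept for the static flag table
  - {target: CYP2C19, ki_u: 1.5,   ic50_u: 3.0,  conversion: half}
  - {target: CYP2D6,  ki_u: 8.5,   ic50_u: 17.0, conversion: half}
  - {target: CYP2E1,  ki_u: 37.5,  ic50_u: 75.0, conversion: half}
  - {target: CYP3A4,  ki_u: 0.348, conversion: direct}
  - {target: UGT1A1,  ki_u: 0.35,  ic50_u: 0.56, conversion: substrate-corrected,
     s_probe: 10.0, km_probe: 16.8}
  - {target: UGT2B7,  ki_u: 7.28,  ic50_u: 7.28, conversion: direct}
transporter_inhibition:   # total Ki (uM), static screen only
  - {target: P-gp,    ki: 21.7}
  - {target: BCRP,    ki: 0.088}
  - {target: OATP1B1, ki: 2.46}
  - {target: OATP1B3, ki: 1.92}
  - {target: OAT1,    ki: 6.90}
  - {target: OAT3,    ki: 1.01}
  - {target: OCT1,    ki: 3.41}
  - {target: OCT2,    ki: 8.22}
  - {target: MATE1,   ki: 6.22}
  - {target: MATE2K,  ki: 2.36}
induction:
  - target: CYP3A4
    indc50: 2.057      # uM, calibrated against the rifampicin reference
    indmax: 1.53       # fold (= Emax + 1), calibrated
    calibrated: true
    indc50_invitro: 2.7
    indmax_invitro: 5.4
  - target: CYP1A2
    indc50: 0.59
    indmax: 4.5
    calibrated: false
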