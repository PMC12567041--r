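# Reference human physiology for the virtual-population generator.
# Central values are documented defaults assembled from published
# reference-human tables and enzyme/transporter abundance meta-analyses;
# the commercial population libraries they stand in for are proprietary,
# so these values are synthetic-but-realistic and versioned here.
schema_version: 1
reference:
  body_weight_kg: 73
  cardiac_output_blood_l_h: 390
  hematocrit: 0.45
  plasma_volume_l: 3.1
  arterial_plasma_l: 0.8
  venous_plasma_l: 2.3
  gfr_ml_min: 120            # per 1.73 m2, healthy young adult
  liver_mass_g: 1680
  liver_extracellular_l: 0.45
  liver_cell_l: 1.20
  mppgl_mg_g: 39.8           # microsomal protein per g liver
  hpgl_million_g: 120        # hepatocellularity, 10^6 cells per g liver
# organ volumes (L) and blood-flow fractions of cardiac output for the
# 73-kg reference adult; gut and spleen drain to the liver (portal vein)
tissues:
  lung:    {volume_l: 0.53, flow_frac: 1.00,  kp_base: 2.5}
  adipose: {volume_l: 18.2, flow_frac: 0.050, kp_base: 23.0}
  bone:    {volume_l: 10.5, flow_frac: 0.050, kp_base: 4.0}
  brain:   {volume_l: 1.45, flow_frac: 0.120, kp_base: 8.0}
  gut:     {volume_l: 1.65, flow_frac: 0.160, kp_base: 5.5}
  heart:   {volume_l: 0.33, flow_frac: 0.040, kp_base: 4.5}
  kidney:  {volume_l: 0.31, flow_frac: 0.190, kp_base: 5.0}
  muscle:  {volume_l: 29.0, flow_frac: 0.170, kp_base: 5.6}
  skin:    {volume_l: 3.30, flow_frac: 0.050, kp_base: 6.5}
  spleen:  {volume_l: 0.15, flow_frac: 0.020, kp_base: 4.5}
  rest:    {volume_l: 4.00, flow_frac: 0.085, kp_base: 5.0}
hepatic_arterial_flow_frac: 0.065
# kp_base: tissue-to-plasma partition coefficients precomputed with standard
# tissue-composition equations for a lipophilic weak base (logP 3.9, pKa 4,
# essentially un-ionized at pH 7.4); the compound-level Kp scalar multiplies
# these.
sex:
  male:   {body_weight_kg: 81, adipose_scale: 1.00, muscle_scale: 1.00, co_scale: 1.00}
  female: {body_weight_kg: 66, adipose_scale: 1.40, muscle_scale: 0.80, co_scale: 0.92}
# hepatic enzyme abundances (pmol per mg microsomal protein) with
# between-subject log-normal CV (%); healthy adult liver. The UGT1A4 and
# UGT2B7 central values match the healthy baselines quoted for the
# cirrhosis-modified population (52 and 71 pmol/mg).
enzyme_abundance:
  CYP3A4:  {mean: 137, cv: 35}
  CYP2C8:  {mean: 24,  cv: 40}
  CYP2C9:  {mean: 73,  cv: 35}
  CYP2D6:  {mean: 8,   cv: 60}
  CYP2J2:  {mean: 1.2, cv: 40}
  CYP1A2:  {mean: 52,  cv: 40}
  UGT1A3:  {mean: 26,  cv: 40}
  UGT1A4:  {mean: 52,  cv: 40}
  UGT2B7:  {mean: 71,  cv: 40}
  UGT2B17: {mean: 27,  cv: 70}
transporter_activity:
  BCRP: {mean: 1.0, cv: 30}
variability:
  body_weight_cv: 15
  liver_mass_cv: 20
  mppgl_cv: 25
  hpgl_cv: 25
  clpd_cv: 30
  gfr_healthy_mean: 105
  gfr_healthy_cv: 16
# population bases
bases:
  healthy: {fu_scalar: 1.00, cyp_scalar: 1.00, ugt_scalar: 1.00}
  # cancer population: minor documented modifiers (slightly raised acute-phase
  # binding proteins, slightly reduced CYP activity); simulated asciminib PK
  # differs from healthy by well under 15%
  cancer:  {fu_scalar: 0.95, cyp_scalar: 0.90, ugt_scalar: 1.00}
# hepatic impairment (Child-Pugh) modifiers: functional liver mass, hepatic
# enzyme abundance, hepatic/portal blood flow, plasma-protein binding
# (fraction-unbound scalar), GFR, hepatocellularity and canalicular
# transporter activity; assembled from published cirrhosis physiology.
# UGT abundance is left unchanged in CP-A/CP-B; the "ugt-modified" CP-C
# variant additionally reduces UGT1A4 and UGT2B7 abundance by 85%
# (52 -> 7.8 and 71 -> 10.65 pmol/mg).
impairment:
  CP-A: {liver_mass: 0.90, cyp_abundance: 0.75, q_hepatic: 0.85, fu_scalar: 1.08,
         gfr: 0.95, hepatocellularity: 0.95, transporter: 0.95, ugt_reduction: 1.00}
  CP-B: {liver_mass: 0.80, cyp_abundance: 0.60, q_hepatic: 0.75, fu_scalar: 1.15,
         gfr: 0.90, hepatocellularity: 0.90, transporter: 0.90, ugt_reduction: 1.00}
  CP-C: {liver_mass: 0.70, cyp_abundance: 0.45, q_hepatic: 0.60, fu_scalar: 1.25,
         gfr: 0.80, hepatocellularity: 0.85, transporter: 0.80, ugt_reduction: 1.00}
  CP-C-ugt-modified: {liver_mass: 0.70, cyp_abundance: 0.45, q_hepatic: 0.60,
         fu_scalar: 1.25, gfr: 0.80, hepatocellularity: 0.85, transporter: 0.80,
         ugt_reduction: 0.15}
# renal impairment GFR bins (mL/min per 1.73 m2)
ri_bins:
  RI-mild:     {gfr_low: 60, gfr_high: 90}
  RI-moderate: {gfr_low: 30, gfr_high: 60}
  RI-severe:   {gfr_low: 8,  gfr_high: 30}
# enzyme turnover half-lives for induction / inactivation dynamics
kdeg_per_h:
  liver_CYP3A4: 0.0193
  gut_CYP3A4: 0.0288
  liver_CYP1A2: 0.0183
  default: 0.0193
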