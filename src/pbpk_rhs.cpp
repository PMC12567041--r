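#include <Rcpp.h>
using namespace Rcpp;

// Whole-body PBPK right-hand side.
//
// State layout (0-based):
//   0      gut lumen depot (absorbable), umol
//   1..11  tissues: lung, adipose, bone, brain, gut, heart, kidney,
//          muscle, skin, spleen, rest
//   12     arterial plasma
//   13     venous plasma
//   14     liver extracellular (vascular + interstitial, plasma-like)
//   15     liver intracellular
//   16     bile transit (enterohepatic recirculation)
//   17     bile excreted, cumulative
//   18     urine, cumulative
//   19     gut-wall first-pass metabolism, cumulative
//   20..28 cumulative amounts per hepatic pathway:
//          CYP3A4, CYP2C8, CYP2D6, CYP2J2, UGT1A3, UGT1A4, UGT2B7,
//          UGT2B17, hydrolysis
//   29     unabsorbed fraction bucket (event-filled)
//   30     hepatic CYP3A4 activity (fraction of baseline)
//   31     gut CYP3A4 activity
// then per reduced compound j (base = 32 + 5 j):
//   +0 depot, +1 central, +2 peripheral, +3 liver activity, +4 gut activity
//
// phys: 0..10 V(tissue), 11..21 Q(tissue, plasma), 22 V_art, 23 V_ven,
//       24 V_EW, 25 V_cell, 26 Q_hepatic_arterial, 27 Q_portal,
//       28..38 Kp(tissue)
//
// vic:  0 ka, 1 fa, 2 fu_gut, 3 Q_gut, 4 CLint_gut_u, 5 fu_p, 6 CLPD_u,
//       7 fu_cell, 8..16 CLint_u per pathway, 17..25 Km_u per pathway,
//       26 Jmax_total (umol/h), 27 Km_BCRP, 28 CL_renal, 29 ehc_fraction,
//       30 ehc_ktr, 31 kdeg_liver_3A4, 32 kdeg_gut_3A4, 33 bcrp_on,
//       34 linearize_mm
//
// red (one row per reduced compound):
//       0 ka, 1 Vc, 2 Q, 3 Vp, 4 fu, 5 CLint_u_h, 6 CL_other, 7 fu_gut,
//       8 Q_gut, 9 CLint_gut_u, 10 kpuu_liver, 11 kdeg_liver, 12 kdeg_gut,
//       13 act_enzyme id, 14/15/16 enz1,fm1,inducible1, 17..19 enz2,
//       20..22 enz3
//
// inter (one row per interaction term):
//       0 perpetrator compound (0 full victim, 1..n reduced),
//       1 target compound, 2 target enzyme id, 3 mechanism
//       (0 reversible, 1 induction, 2 inactivation), 4 site
//       (0 liver, 1 gut), 5 c1 (Ki_u / IndC50_u / KI_u),
//       6 c2 (unused / Emax / kinact)
//
// Enzyme ids: 1 CYP3A4, 2 CYP2C8, 3 CYP2D6, 4 CYP2J2, 5 UGT1A3,
// 6 UGT1A4, 7 UGT2B7, 8 UGT2B17, 9 HYD, 10 BCRP, 11 CYP2C9, 12 CYP2C19,
// 13 CYP1A2, 14 UGT1A1, 15 OATP1B1.

static const int N_ENZ = 16;  // ids 0..15 (0 unused)

// [[Rcpp::export]]
NumericVector pbpk_rhs_cpp(double t, NumericVector y, NumericVector phys,
                           NumericVector vic, NumericMatrix red,
                           NumericMatrix inter) {
  const int n_red = red.nrow();
  const int n = 32 + 5 * n_red;
  NumericVector dy(n);

  // --- physiology
  const double *V = &phys[0];
  const double *Q = &phys[11];
  const double V_art = phys[22], V_ven = phys[23];
  const double V_EW = phys[24], V_cell = phys[25];
  const double Q_ha = phys[26], Q_pv = phys[27];
  const double *Kp = &phys[28];
  // cardiac output as the sum of regional flows (stays consistent when
  // impairment modifiers rescale individual beds)
  double Q_co = Q_ha;
  for (int i = 1; i <= 10; ++i) Q_co += Q[i];
  const double Q_h = Q_ha + Q[4] + Q[9];  // arterial + gut + spleen

  // --- victim concentrations (plasma-referenced, uM)
  const double C_art = y[12] / V_art;
  const double C_ven = y[13] / V_ven;
  const double C_EW = y[14] / V_EW;
  const double C_cell = y[15] / V_cell;
  const double fu_p = vic[5], fu_cell = vic[7];
  const double Cu_EW = fu_p * C_EW;
  const double Cu_cell = fu_cell * C_cell;

  // --- perpetrator site concentrations (unbound, uM) per compound
  std::vector<double> I_liv(n_red + 1), I_gut(n_red + 1), I_pl(n_red + 1);
  I_liv[0] = Cu_cell;
  I_gut[0] = fu_p * (C_art + vic[0] * y[0] / Q_pv);
  I_pl[0] = fu_p * C_ven;
  for (int j = 0; j < n_red; ++j) {
    const int b = 32 + 5 * j;
    const double Cc = y[b + 1] / red(j, 1);
    const double fu = red(j, 4);
    I_liv[j + 1] = fu * Cc * red(j, 10);
    I_gut[j + 1] = fu * (Cc + red(j, 0) * y[b] / Q_pv);
    I_pl[j + 1] = fu * Cc;
  }

  // --- accumulate interaction terms per (target compound, enzyme, site)
  // inhibition sums I/Ki; induction production folds; inactivation rates
  const int n_tgt = n_red + 1;
  std::vector<double> inh_liv(n_tgt * N_ENZ, 0.0), inh_gut(n_tgt * N_ENZ, 0.0);
  std::vector<double> prod_liv(n_tgt, 0.0), prod_gut(n_tgt, 0.0);
  std::vector<double> lam_liv(n_tgt, 0.0), lam_gut(n_tgt, 0.0);
  for (int r = 0; r < inter.nrow(); ++r) {
    const int perp = (int) inter(r, 0);
    const int tgt = (int) inter(r, 1);
    const int enz = (int) inter(r, 2);
    const int mech = (int) inter(r, 3);
    const int site = (int) inter(r, 4);
    const double c1 = inter(r, 5), c2 = inter(r, 6);
    const double I = (site == 0) ? I_liv[perp] : I_gut[perp];
    if (mech == 0) {
      double &s = (site == 0) ? inh_liv[tgt * N_ENZ + enz]
                              : inh_gut[tgt * N_ENZ + enz];
      s += I / c1;
    } else if (mech == 1) {
      double &s = (site == 0) ? prod_liv[tgt] : prod_gut[tgt];
      s += c2 * I / (c1 + I);
    } else {
      double &s = (site == 0) ? lam_liv[tgt] : lam_gut[tgt];
      s += c2 * I / (c1 + I);
    }
  }

  // ============================== victim ==============================
  const double ka = vic[0];
  const double actL = y[30], actG = y[31];

  // gut wall first pass (Q_gut model, CYP3A4)
  const double gmod = actG / (1.0 + inh_gut[0 * N_ENZ + 1]);
  const double clg = vic[4] * gmod;
  const double Fg = vic[3] / (vic[3] + vic[2] * clg);
  const double Rabs = ka * y[0];

  // hepatic pathway rates (Michaelis-Menten on intracellular unbound)
  const bool linear = vic[34] > 0.5;
  double rate[9];
  double met_tot = 0.0;
  for (int e = 0; e < 9; ++e) {
    const int id = e + 1;  // pathway ids 1..9
    const double mod = ((e == 0) ? actL : 1.0) /
      (1.0 + inh_liv[0 * N_ENZ + id]);
    const double cl = vic[8 + e] * mod;
    const double km = vic[17 + e];
    rate[e] = linear ? cl * Cu_cell
                     : cl * km / (km + Cu_cell) * Cu_cell;
    met_tot += rate[e];
  }
  // BCRP canalicular efflux (competitive inhibition on Km)
  double Jb = 0.0;
  if (vic[33] > 0.5) {
    const double kmB = vic[27] * (1.0 + inh_liv[0 * N_ENZ + 10]);
    Jb = linear ? vic[26] / kmB * Cu_cell
                : vic[26] * Cu_cell / (kmB + Cu_cell);
  }

  const double PS = vic[6] * (Cu_EW - Cu_cell);

  // perfusion-limited tissues
  dy[1] = Q_co * (C_ven - y[1] / V[0] / Kp[0]);                    // lung
  const int per_idx[7] = {2, 3, 4, 6, 8, 9, 11};  // adipose..rest excl gut/kid/spleen
  for (int k = 0; k < 7; ++k) {
    const int i = per_idx[k];
    dy[i] = Q[i - 1] * (C_art - y[i] / V[i - 1] / Kp[i - 1]);
  }
  // kidney with renal excretion from the venous-equilibrated tissue
  const double C_kid_out = y[7] / V[6] / Kp[6];
  dy[7] = Q[6] * (C_art - C_kid_out) - vic[28] * C_kid_out;
  dy[18] = vic[28] * C_kid_out;
  // splanchnic tissues drain into the liver
  const double C_gut_out = y[5] / V[4] / Kp[4];
  const double C_spl_out = y[10] / V[9] / Kp[9];
  dy[5] = Q[4] * (C_art - C_gut_out);
  dy[10] = Q[9] * (C_art - C_spl_out);

  // liver
  dy[14] = Q_ha * C_art + Q[4] * C_gut_out + Q[9] * C_spl_out +
           Fg * Rabs - Q_h * C_EW - PS;
  dy[15] = PS - met_tot - Jb;

  // bile and enterohepatic recirculation
  const double ehc = vic[29];
  if (ehc > 0.0) {
    const double out = vic[30] * y[16];
    dy[16] = Jb - out;
    dy[17] = (1.0 - ehc) * out;
    dy[0] = -Rabs + ehc * out;
  } else {
    dy[16] = 0.0;
    dy[17] = Jb;
    dy[0] = -Rabs;
  }

  // blood pool
  dy[12] = Q_co * (y[1] / V[0] / Kp[0] - C_art);
  double ven_in = Q_h * C_EW;
  for (int k = 0; k < 7; ++k) {
    const int i = per_idx[k];
    ven_in += Q[i - 1] * (y[i] / V[i - 1] / Kp[i - 1]);
  }
  ven_in += Q[6] * C_kid_out;
  dy[13] = ven_in - Q_co * C_ven;

  // cumulative pathway amounts and gut-wall loss
  for (int e = 0; e < 9; ++e) dy[20 + e] = rate[e];
  dy[19] = (1.0 - Fg) * Rabs;
  dy[29] = 0.0;

  // enzyme-activity turnover (induction production, inactivation loss)
  dy[30] = vic[31] * (1.0 + prod_liv[0] - actL) - lam_liv[0] * actL;
  dy[31] = vic[32] * (1.0 + prod_gut[0] - actG) - lam_gut[0] * actG;

  // ========================= reduced compounds ========================
  for (int j = 0; j < n_red; ++j) {
    const int b = 32 + 5 * j;
    const double ka_j = red(j, 0), Vc = red(j, 1);
    const double Qj = red(j, 2), Vp = red(j, 3);
    const double fu = red(j, 4);
    const double Cc = y[b + 1] / Vc;
    const double Cp = y[b + 2] / Vp;
    const double aL = y[b + 3], aG = y[b + 4];
    const int tgt = j + 1;
    const int act_enz = (int) red(j, 13);

    // gut availability
    double gm = 1.0;
    if (red(j, 9) > 0.0 && act_enz > 0) {
      gm = aG / (1.0 + inh_gut[tgt * N_ENZ + act_enz]);
    }
    const double Fg_j = red(j, 8) / (red(j, 8) + red(j, 7) * red(j, 9) * gm);

    // hepatic clearance with pathway modifiers (well-stirred)
    double frac = 0.0, fm_sum = 0.0;
    for (int k = 0; k < 3; ++k) {
      const int enz = (int) red(j, 14 + 3 * k);
      if (enz <= 0) continue;
      const double fm = red(j, 15 + 3 * k);
      const bool inducible = red(j, 16 + 3 * k) > 0.5;
      const double mod = ((inducible && enz == act_enz) ? aL : 1.0) /
        (1.0 + inh_liv[tgt * N_ENZ + enz]);
      frac += fm * mod;
      fm_sum += fm;
    }
    frac += 1.0 - fm_sum;
    const double clint_eff = red(j, 5) * frac;
    const double qh_fu_cl = fu * clint_eff;
    const double CLh = Q_h * qh_fu_cl / (Q_h + qh_fu_cl);

    dy[b] = -ka_j * y[b];
    dy[b + 1] = ka_j * y[b] * Fg_j - CLh * Cc - red(j, 6) * Cc -
                Qj * (Cc - Cp);
    dy[b + 2] = Qj * (Cc - Cp);
    dy[b + 3] = red(j, 11) * (1.0 + prod_liv[tgt] - aL) - lam_liv[tgt] * aL;
    dy[b + 4] = red(j, 12) * (1.0 + prod_gut[tgt] - aG) - lam_gut[tgt] * aG;
  }

  return dy;
}
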