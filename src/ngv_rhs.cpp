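// Compiled right-hand side of the reduced NGV model.
//
// This mirrors the R process registry (R/processes.R) process-for-process;
// a package test asserts equality of both implementations at random states.
// A model context resolves all parameter and state positions by name once,
// so the per-call cost is pure arithmetic.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

static const int N_PROC = 81;

struct CellPar {
  double hk_vmax, pfk_vmax, ald_vmax, lgly_vmax, mpc_vmax, pdh_vmax, pc_vmax,
    etc_vmax, km_etc_nadh, ant_k, ims_exp_k, ppp_vmax, bhb_ut_vmax, hk_atpase,
    mas_k;
  double vc, vm, vi; // volume fractions: cytosol, mito, IMS
};

struct Ctx {
  // global kinetic parameters
  double blood_relax_k, o2_blood, o2_supply_k;
  double glc_b_set, lac_b_set, bhb_b_set;
  double glut1_be_vmax, glut1_ee_vmax, glut1_ea_vmax, glut1_an_vmax,
    glut3_vmax, km_glut1, km_glut3;
  double mct_be_vmax, mct_ee_vmax, mct_ea_vmax, mct_an_vmax, mct_n_vmax,
    km_mct;
  double bhbt_be_vmax, bhbt_ee_vmax, bhbt_ea_vmax, bhbt_an_vmax, bhbt_n_vmax,
    km_bhbt;
  double km_hk_glc, km_hk_atp, ki_hk_hkpf;
  double km_pfk_hkpf, km_pfk_atp, ki_pfk_atp, ka_pfk_adp, hill_pfk;
  double km_ald, tpi_k, keq_tpi;
  double km_lgly_gap, km_lgly_nad, km_lgly_adp, ldh_k, keq_ldh;
  double km_mpc, km_pdh_pyr, km_pdh_coa, km_pdh_nad, km_pc;
  double cs_vmax, km_cs_accoa, km_cs_oxa, acn_vmax, km_acn;
  double idh_vmax, km_idh_isocit, km_idh_nad;
  double kgdh_vmax, km_kgdh_akg, km_kgdh_coa, km_kgdh_nad;
  double scs_vmax, km_scs_succoa, km_scs_adp, sdh_vmax, km_sdh;
  double fum_vmax, km_fum, mdh_k, keq_mdh, mal_drain_k, akg_drain_k;
  double km_etc_o2, p_o_ratio, km_syn_adp, km_ant, km_ant_adp,
    km_ims;
  double keq_mas, km_ppp_hkpf, km_ppp_nadp;
  double gr_vmax, km_gr_gssg, km_gr_nadph, ros_k, km_ros_gsh;
  double km_bhb_ut, km_bhb_nad;
  double glysyn_vmax, km_glysyn_hkpf, gly_cap, glyphos_vmax, km_glyphos,
    ki_glyphos_glc, km_hk_atpase;
  double pump_vmax, km_pump_atp, km_pump_glc, km_pump_na, hill_pump_na,
    km_pump_k, hill_pump_atp;
  double gna, gk, gna_leak, gl, el, cm, na_out, k_in, ion_conv, ecs_k_ratio,
    k_bath, k_clear, km_clear, k_clear_thresh, k_resupply;
  double vol_blood, vol_endo, vol_ecsBA, vol_ecsAN;
  CellPar cell[2]; // 0 = neuron, 1 = astrocyte

  // state indices
  int iGlc_b, iLac_b, ibHB_b, iGlc_tt, iLac_tt, ibHB_tt,
    iGlc_BA, iLac_BA, ibHB_BA, iGlc_AN, iLac_AN, ibHB_AN;
  int icyt[2], imit[2], iims[2]; // block offsets
  int iGLY, iV, im, ih, in_, iNa, iK;

  // blood-trace driver (empty => clamped at set points)
  std::vector<double> tr_t, tr_glc, tr_lac, tr_bhb;

  std::vector<std::string> proc_names;
};

// offsets inside the cytosolic block
enum { GLC, HKPF, FBP, GAP, DHAP, PYR, LAC, NAD, NADH, NADP, NADPH, ATP, ADP,
       GSH, GSSG, BHB };
// offsets inside the mitochondrial block
enum { PYRM, ACCOA, COA, CIT, ISOCIT, AKG, SUCCOA, SUC, FUM_, MAL, OXA, NADM,
       NADHM, ATPM, ADPM, O2M, QPOOL };

// saturating terms clamp at zero so transient solver undershoots below zero
// cannot create singularities
static inline double mm(double x, double km) {
  if (x < 0) x = 0;
  return x / (x + km);
}
static inline double hillf(double x, double km, double n) {
  if (x < 0) x = 0;
  double a = std::pow(x, n);
  return a / (a + std::pow(km, n));
}
static inline double carrier(double a, double b, double vmax, double km) {
  return vmax * (mm(a, km) - mm(b, km));
}

static double getp(const NumericVector& p,
                   const std::unordered_map<std::string, int>& idx,
                   const char* name) {
  auto it = idx.find(name);
  if (it == idx.end()) stop("parameter not found: %s", name);
  return p[it->second];
}

// [[Rcpp::export]]
SEXP ngv_make_ctx(NumericVector params, CharacterVector state_names) {
  Ctx* c = new Ctx();
  CharacterVector pn = params.names();
  std::unordered_map<std::string, int> pi;
  for (int i = 0; i < params.size(); ++i) pi[as<std::string>(pn[i])] = i;
  std::unordered_map<std::string, int> si;
  for (int i = 0; i < state_names.size(); ++i)
    si[as<std::string>(state_names[i])] = i;

#define GP(x) c->x = getp(params, pi, #x)
  GP(blood_relax_k); GP(o2_blood); GP(o2_supply_k);
  GP(glc_b_set); GP(lac_b_set); GP(bhb_b_set);
  GP(glut1_be_vmax); GP(glut1_ee_vmax); GP(glut1_ea_vmax); GP(glut1_an_vmax);
  GP(glut3_vmax); GP(km_glut1); GP(km_glut3);
  GP(mct_be_vmax); GP(mct_ee_vmax); GP(mct_ea_vmax); GP(mct_an_vmax);
  GP(mct_n_vmax); GP(km_mct);
  GP(bhbt_be_vmax); GP(bhbt_ee_vmax); GP(bhbt_ea_vmax); GP(bhbt_an_vmax);
  GP(bhbt_n_vmax); GP(km_bhbt);
  GP(km_hk_glc); GP(km_hk_atp); GP(ki_hk_hkpf);
  GP(km_pfk_hkpf); GP(km_pfk_atp); GP(ki_pfk_atp); GP(ka_pfk_adp);
  GP(hill_pfk);
  GP(km_ald); GP(tpi_k); GP(keq_tpi);
  GP(km_lgly_gap); GP(km_lgly_nad); GP(km_lgly_adp); GP(ldh_k); GP(keq_ldh);
  GP(km_mpc); GP(km_pdh_pyr); GP(km_pdh_coa); GP(km_pdh_nad); GP(km_pc);
  GP(cs_vmax); GP(km_cs_accoa); GP(km_cs_oxa); GP(acn_vmax); GP(km_acn);
  GP(idh_vmax); GP(km_idh_isocit); GP(km_idh_nad);
  GP(kgdh_vmax); GP(km_kgdh_akg); GP(km_kgdh_coa); GP(km_kgdh_nad);
  GP(scs_vmax); GP(km_scs_succoa); GP(km_scs_adp); GP(sdh_vmax); GP(km_sdh);
  GP(fum_vmax); GP(km_fum); GP(mdh_k); GP(keq_mdh); GP(mal_drain_k);
  GP(akg_drain_k);
  GP(km_etc_o2); GP(p_o_ratio); GP(km_syn_adp); GP(km_ant);
  GP(km_ant_adp); GP(km_ims);
  GP(keq_mas); GP(km_ppp_hkpf); GP(km_ppp_nadp);
  GP(gr_vmax); GP(km_gr_gssg); GP(km_gr_nadph); GP(ros_k); GP(km_ros_gsh);
  GP(km_bhb_ut); GP(km_bhb_nad);
  GP(glysyn_vmax); GP(km_glysyn_hkpf); GP(gly_cap); GP(glyphos_vmax);
  GP(km_glyphos); GP(ki_glyphos_glc); GP(km_hk_atpase);
  GP(pump_vmax); GP(km_pump_atp); GP(km_pump_glc); GP(km_pump_na);
  GP(hill_pump_na); GP(km_pump_k); GP(hill_pump_atp);
  GP(gna); GP(gk); GP(gna_leak); GP(gl); GP(el); GP(cm); GP(na_out);
  GP(k_in); GP(ion_conv);
  GP(ecs_k_ratio); GP(k_bath); GP(k_clear); GP(km_clear); GP(k_clear_thresh);
  GP(k_resupply);
#undef GP
  c->vol_blood = getp(params, pi, "vol_blood");
  c->vol_endo = getp(params, pi, "vol_endo");
  c->vol_ecsBA = getp(params, pi, "vol_ecsBA");
  c->vol_ecsAN = getp(params, pi, "vol_ecsAN");

  const char* suf[2] = {"n", "a"};
  for (int k = 0; k < 2; ++k) {
    CellPar& cp = c->cell[k];
    std::string s(suf[k]);
#define GC(x) cp.x = getp(params, pi, (std::string(#x "_") + s).c_str())
    GC(hk_vmax); GC(pfk_vmax); GC(ald_vmax); GC(lgly_vmax); GC(mpc_vmax);
    GC(pdh_vmax); GC(pc_vmax); GC(etc_vmax); GC(km_etc_nadh); GC(ant_k);
    GC(ims_exp_k);
    GC(ppp_vmax); GC(bhb_ut_vmax); GC(hk_atpase); GC(mas_k);
#undef GC
    cp.vc = getp(params, pi, (std::string("vol_") + s + "_cyt").c_str());
    cp.vm = getp(params, pi, (std::string("vol_") + s + "_mit").c_str());
    cp.vi = getp(params, pi, (std::string("vol_") + s + "_ims").c_str());
  }

  auto sidx = [&](const char* n2) {
    auto it = si.find(n2);
    if (it == si.end()) stop("state not found: %s", n2);
    return it->second;
  };
  c->iGlc_b = sidx("Glc_b"); c->iLac_b = sidx("Lac_b"); c->ibHB_b = sidx("bHB_b");
  c->iGlc_tt = sidx("Glc_t_t"); c->iLac_tt = sidx("Lac_t_t");
  c->ibHB_tt = sidx("bHB_t_t");
  c->iGlc_BA = sidx("Glc_ecsBA"); c->iLac_BA = sidx("Lac_ecsBA");
  c->ibHB_BA = sidx("bHB_ecsBA");
  c->iGlc_AN = sidx("Glc_ecsAN"); c->iLac_AN = sidx("Lac_ecsAN");
  c->ibHB_AN = sidx("bHB_ecsAN");
  c->icyt[0] = sidx("Glc_n"); c->icyt[1] = sidx("Glc_a");
  c->imit[0] = sidx("PYRmito_n"); c->imit[1] = sidx("PYRmito_a");
  c->iims[0] = sidx("ATPims_n"); c->iims[1] = sidx("ATPims_a");
  c->iGLY = sidx("GLY_a");
  c->iV = sidx("V"); c->im = sidx("gate_m"); c->ih = sidx("gate_h");
  c->in_ = sidx("gate_n"); c->iNa = sidx("Na_in"); c->iK = sidx("K_out");

  // process order must match the R registry
  const char* heads[15] = {"glut1_be", "glut1_ee", "glut1_ea", "glut1_an",
    "glut3_n", "mct_be", "mct_ee", "mct_ea", "mct_an", "mct_n",
    "bhbt_be", "bhbt_ee", "bhbt_ea", "bhbt_an", "bhbt_n"};
  for (int i = 0; i < 15; ++i) c->proc_names.push_back(heads[i]);
  c->proc_names.push_back("glc_b_relax");
  c->proc_names.push_back("lac_b_relax");
  c->proc_names.push_back("bhb_b_relax");
  const char* percell[30] = {"hk", "pfk", "ald", "tpi", "lgly", "ldh", "mpc",
    "pdh", "pc", "cs", "acn", "idh", "kgdh", "scs", "sdh", "fum", "mdh",
    "mal_drain", "akg_drain", "etc", "atpsyn", "ant", "ims_exp", "o2sup",
    "ppp", "gr", "ros", "bhb_ut", "mas", "hk_atpase"};
  for (int k = 0; k < 2; ++k)
    for (int i = 0; i < 30; ++i)
      c->proc_names.push_back(std::string(percell[i]) + "_" + suf[k]);
  c->proc_names.push_back("glysyn_a");
  c->proc_names.push_back("glyphos_a");
  c->proc_names.push_back("nka");

  XPtr<Ctx> ptr(c, true);
  return ptr;
}

// [[Rcpp::export]]
void ngv_set_blood_trace(SEXP ctx, NumericVector t, NumericVector glc,
                         NumericVector lac, NumericVector bhb) {
  XPtr<Ctx> c(ctx);
  c->tr_t.assign(t.begin(), t.end());
  c->tr_glc.assign(glc.begin(), glc.end());
  c->tr_lac.assign(lac.begin(), lac.end());
  c->tr_bhb.assign(bhb.begin(), bhb.end());
}

// [[Rcpp::export]]
void ngv_clear_blood_trace(SEXP ctx) {
  XPtr<Ctx> c(ctx);
  c->tr_t.clear(); c->tr_glc.clear(); c->tr_lac.clear(); c->tr_bhb.clear();
}

static void blood_targets(const Ctx* c, double t, double& glc, double& lac,
                          double& bhb) {
  if (c->tr_t.empty()) {
    glc = c->glc_b_set; lac = c->lac_b_set; bhb = c->bhb_b_set;
    return;
  }
  const std::vector<double>& tt = c->tr_t;
  size_t n = tt.size();
  if (t <= tt.front()) { glc = c->tr_glc.front(); lac = c->tr_lac.front();
    bhb = c->tr_bhb.front(); return; }
  if (t >= tt.back()) { glc = c->tr_glc.back(); lac = c->tr_lac.back();
    bhb = c->tr_bhb.back(); return; }
  size_t lo = std::upper_bound(tt.begin(), tt.end(), t) - tt.begin() - 1;
  double w = (t - tt[lo]) / (tt[lo + 1] - tt[lo]);
  glc = c->tr_glc[lo] + w * (c->tr_glc[lo + 1] - c->tr_glc[lo]);
  lac = c->tr_lac[lo] + w * (c->tr_lac[lo + 1] - c->tr_lac[lo]);
  bhb = c->tr_bhb[lo] + w * (c->tr_bhb[lo + 1] - c->tr_bhb[lo]);
}

// core: compute process rates (length N_PROC) and, if dy != nullptr, the
// full derivative vector including the membrane block
static void ngv_core(const Ctx* c, double t, const double* y, double stim,
                     double* rates, double* dy, int ny) {
  double glc_tgt, lac_tgt, bhb_tgt;
  blood_targets(c, t, glc_tgt, lac_tgt, bhb_tgt);
  if (dy) for (int i = 0; i < ny; ++i) dy[i] = 0.0;
  int ir = 0;
  // helper to add a species contribution: conc-rate in ref volume vref
  auto addc = [&](int idx, double coeff, double rate, double vref,
                  double vsp) {
    if (dy) dy[idx] += coeff * rate * vref / vsp;
  };

  const double vB = c->vol_blood, vE = c->vol_endo, vBA = c->vol_ecsBA,
    vAN = c->vol_ecsAN;

  // ---- transport chains ----
  struct TR { int from, to; double vmax, km, vref, vfrom, vto; bool bound; };
  TR trs[15] = {
    {c->iGlc_b, c->iGlc_tt, c->glut1_be_vmax, c->km_glut1, vE, vB, vE, true},
    {c->iGlc_tt, c->iGlc_BA, c->glut1_ee_vmax, c->km_glut1, vE, vE, vBA, false},
    {c->iGlc_BA, c->icyt[1] + GLC, c->glut1_ea_vmax, c->km_glut1, vBA, vBA,
     c->cell[1].vc, false},
    {c->icyt[1] + GLC, c->iGlc_AN, c->glut1_an_vmax, c->km_glut1,
     c->cell[1].vc, c->cell[1].vc, vAN, false},
    {c->iGlc_AN, c->icyt[0] + GLC, c->glut3_vmax, c->km_glut3, vAN, vAN,
     c->cell[0].vc, false},
    {c->iLac_b, c->iLac_tt, c->mct_be_vmax, c->km_mct, vE, vB, vE, true},
    {c->iLac_tt, c->iLac_BA, c->mct_ee_vmax, c->km_mct, vE, vE, vBA, false},
    {c->iLac_BA, c->icyt[1] + LAC, c->mct_ea_vmax, c->km_mct, vBA, vBA,
     c->cell[1].vc, false},
    {c->icyt[1] + LAC, c->iLac_AN, c->mct_an_vmax, c->km_mct, c->cell[1].vc,
     c->cell[1].vc, vAN, false},
    {c->iLac_AN, c->icyt[0] + LAC, c->mct_n_vmax, c->km_mct, vAN, vAN,
     c->cell[0].vc, false},
    {c->ibHB_b, c->ibHB_tt, c->bhbt_be_vmax, c->km_bhbt, vE, vB, vE, true},
    {c->ibHB_tt, c->ibHB_BA, c->bhbt_ee_vmax, c->km_bhbt, vE, vE, vBA, false},
    {c->ibHB_BA, c->icyt[1] + BHB, c->bhbt_ea_vmax, c->km_bhbt, vBA, vBA,
     c->cell[1].vc, false},
    {c->icyt[1] + BHB, c->ibHB_AN, c->bhbt_an_vmax, c->km_bhbt,
     c->cell[1].vc, c->cell[1].vc, vAN, false},
    {c->ibHB_AN, c->icyt[0] + BHB, c->bhbt_n_vmax, c->km_bhbt, vAN, vAN,
     c->cell[0].vc, false},
  };
  for (int i = 0; i < 15; ++i) {
    double r = carrier(y[trs[i].from], y[trs[i].to], trs[i].vmax, trs[i].km);
    rates[ir++] = r;
    if (!trs[i].bound) addc(trs[i].from, -1, r, trs[i].vref, trs[i].vfrom);
    addc(trs[i].to, 1, r, trs[i].vref, trs[i].vto);
  }

  // ---- blood relaxation ----
  {
    double r1 = c->blood_relax_k * (glc_tgt - y[c->iGlc_b]);
    double r2 = c->blood_relax_k * (lac_tgt - y[c->iLac_b]);
    double r3 = c->blood_relax_k * (bhb_tgt - y[c->ibHB_b]);
    rates[ir++] = r1; rates[ir++] = r2; rates[ir++] = r3;
    if (dy) { dy[c->iGlc_b] += r1; dy[c->iLac_b] += r2; dy[c->ibHB_b] += r3; }
  }

  // ---- per-cell metabolism ----
  for (int k = 0; k < 2; ++k) {
    const CellPar& cp = c->cell[k];
    const int C = c->icyt[k], M = c->imit[k], I = c->iims[k];
    const double vc = cp.vc, vm = cp.vm, vi = cp.vi;
    auto cy = [&](int off) { return y[C + off]; };
    auto mt = [&](int off) { return y[M + off]; };

    double r;
    // hk
    r = cp.hk_vmax * mm(cy(GLC), c->km_hk_glc) * mm(cy(ATP), c->km_hk_atp) *
      c->ki_hk_hkpf / (c->ki_hk_hkpf + cy(HKPF));
    rates[ir++] = r;
    if (dy) { dy[C+GLC] -= r; dy[C+ATP] -= r; dy[C+ADP] += r; dy[C+HKPF] += r; }
    // pfk
    {
      double h = c->hill_pfk;
      r = cp.pfk_vmax * mm(cy(HKPF), c->km_pfk_hkpf) *
        mm(cy(ATP), c->km_pfk_atp) /
        (1 + std::pow(cy(ATP) / c->ki_pfk_atp, h)) *
        hillf(cy(ADP), c->ka_pfk_adp, h);
      rates[ir++] = r;
      if (dy) { dy[C+HKPF] -= r; dy[C+ATP] -= r; dy[C+ADP] += r;
        dy[C+FBP] += r; }
    }
    // ald
    r = cp.ald_vmax * mm(cy(FBP), c->km_ald);
    rates[ir++] = r;
    if (dy) { dy[C+FBP] -= r; dy[C+GAP] += r; dy[C+DHAP] += r; }
    // tpi
    r = c->tpi_k * (cy(DHAP) - cy(GAP) / c->keq_tpi);
    rates[ir++] = r;
    if (dy) { dy[C+DHAP] -= r; dy[C+GAP] += r; }
    // lgly
    r = cp.lgly_vmax * mm(cy(GAP), c->km_lgly_gap) *
      mm(cy(NAD), c->km_lgly_nad) * mm(cy(ADP), c->km_lgly_adp);
    rates[ir++] = r;
    if (dy) { dy[C+GAP] -= r; dy[C+NAD] -= r; dy[C+NADH] += r;
      dy[C+ADP] -= 2*r; dy[C+ATP] += 2*r; dy[C+PYR] += r; }
    // ldh
    r = c->ldh_k * (cy(PYR) * cy(NADH) - cy(LAC) * cy(NAD) / c->keq_ldh);
    rates[ir++] = r;
    if (dy) { dy[C+PYR] -= r; dy[C+NADH] -= r; dy[C+LAC] += r;
      dy[C+NAD] += r; }
    // mpc
    r = carrier(cy(PYR), mt(PYRM), cp.mpc_vmax, c->km_mpc);
    rates[ir++] = r;
    if (dy) { dy[C+PYR] -= r; dy[M+PYRM] += r * vc / vm; }
    // pdh
    r = cp.pdh_vmax * mm(mt(PYRM), c->km_pdh_pyr) *
      mm(mt(COA), c->km_pdh_coa) * mm(mt(NADM), c->km_pdh_nad);
    rates[ir++] = r;
    if (dy) { dy[M+PYRM] -= r; dy[M+COA] -= r; dy[M+NADM] -= r;
      dy[M+ACCOA] += r; dy[M+NADHM] += r; }
    // pc
    r = cp.pc_vmax * mm(mt(PYRM), c->km_pc);
    rates[ir++] = r;
    if (dy) { dy[M+PYRM] -= r; dy[M+OXA] += r; }
    // cs
    r = c->cs_vmax * mm(mt(ACCOA), c->km_cs_accoa) * mm(mt(OXA), c->km_cs_oxa);
    rates[ir++] = r;
    if (dy) { dy[M+ACCOA] -= r; dy[M+OXA] -= r; dy[M+CIT] += r;
      dy[M+COA] += r; }
    // acn
    r = c->acn_vmax * mm(mt(CIT), c->km_acn);
    rates[ir++] = r;
    if (dy) { dy[M+CIT] -= r; dy[M+ISOCIT] += r; }
    // idh
    r = c->idh_vmax * mm(mt(ISOCIT), c->km_idh_isocit) *
      mm(mt(NADM), c->km_idh_nad);
    rates[ir++] = r;
    if (dy) { dy[M+ISOCIT] -= r; dy[M+AKG] += r; dy[M+NADM] -= r;
      dy[M+NADHM] += r; }
    // kgdh
    r = c->kgdh_vmax * mm(mt(AKG), c->km_kgdh_akg) *
      mm(mt(COA), c->km_kgdh_coa) * mm(mt(NADM), c->km_kgdh_nad);
    rates[ir++] = r;
    if (dy) { dy[M+AKG] -= r; dy[M+COA] -= r; dy[M+SUCCOA] += r;
      dy[M+NADM] -= r; dy[M+NADHM] += r; }
    // scs
    r = c->scs_vmax * mm(mt(SUCCOA), c->km_scs_succoa) *
      mm(mt(ADPM), c->km_scs_adp);
    rates[ir++] = r;
    if (dy) { dy[M+SUCCOA] -= r; dy[M+SUC] += r; dy[M+COA] += r;
      dy[M+ADPM] -= r; dy[M+ATPM] += r; }
    // sdh
    r = c->sdh_vmax * mm(mt(SUC), c->km_sdh);
    rates[ir++] = r;
    if (dy) { dy[M+SUC] -= r; dy[M+FUM_] += r; }
    // fum
    r = c->fum_vmax * mm(mt(FUM_), c->km_fum);
    rates[ir++] = r;
    if (dy) { dy[M+FUM_] -= r; dy[M+MAL] += r; }
    // mdh
    r = c->mdh_k * (mt(MAL) * mt(NADM) - mt(OXA) * mt(NADHM) / c->keq_mdh);
    rates[ir++] = r;
    if (dy) { dy[M+MAL] -= r; dy[M+NADM] -= r; dy[M+OXA] += r;
      dy[M+NADHM] += r; }
    // mal_drain
    r = c->mal_drain_k * mt(MAL);
    rates[ir++] = r;
    if (dy) dy[M+MAL] -= r;
    // akg_drain
    r = c->akg_drain_k * mt(AKG);
    rates[ir++] = r;
    if (dy) dy[M+AKG] -= r;
    // etc
    double etc = cp.etc_vmax * mm(mt(NADHM), cp.km_etc_nadh) *
      mm(mt(O2M), c->km_etc_o2);
    rates[ir++] = etc;
    if (dy) { dy[M+NADHM] -= etc; dy[M+NADM] += etc; dy[M+O2M] -= 0.5 * etc; }
    // atpsyn
    r = c->p_o_ratio * etc * mt(QPOOL) * mm(mt(ADPM), c->km_syn_adp);
    rates[ir++] = r;
    if (dy) { dy[M+ADPM] -= r; dy[M+ATPM] += r; }
    // ant
    r = cp.ant_k * (mm(mt(ATPM), c->km_ant) - mm(y[I], c->km_ant)) *
      mm(cy(ADP), c->km_ant_adp);
    if (r < 0) r *= mm(mt(ADPM), c->km_ant_adp);  // reverse needs matrix ADP
    rates[ir++] = r;
    if (dy) { dy[M+ATPM] -= r; dy[M+ADPM] += r; dy[I] += r * vm / vi;
      dy[C+ADP] -= r * vm / vc; }
    // ims_exp
    r = cp.ims_exp_k * (mm(y[I], c->km_ims) - mm(cy(ATP), c->km_ims));
    rates[ir++] = r;
    if (dy) { dy[I] -= r; dy[C+ATP] += r * vi / vc; }
    // o2sup
    r = c->o2_supply_k * (c->o2_blood - mt(O2M));
    rates[ir++] = r;
    if (dy) dy[M+O2M] += r;
    // ppp
    r = cp.ppp_vmax * mm(cy(HKPF), c->km_ppp_hkpf) *
      mm(cy(NADP), c->km_ppp_nadp);
    rates[ir++] = r;
    if (dy) { dy[C+HKPF] -= r; dy[C+NADP] -= 2*r; dy[C+NADPH] += 2*r; }
    // gr
    r = c->gr_vmax * mm(cy(GSSG), c->km_gr_gssg) *
      mm(cy(NADPH), c->km_gr_nadph);
    rates[ir++] = r;
    if (dy) { dy[C+GSSG] -= r; dy[C+NADPH] -= r; dy[C+NADP] += r;
      dy[C+GSH] += 2*r; }
    // ros
    r = c->ros_k * etc * vm / vc * mm(cy(GSH), c->km_ros_gsh);
    rates[ir++] = r;
    if (dy) { dy[C+GSH] -= 2*r; dy[C+GSSG] += r; }
    // bhb_ut
    r = cp.bhb_ut_vmax * mm(cy(BHB), c->km_bhb_ut) *
      mm(mt(NADM), c->km_bhb_nad) * mm(mt(COA), c->km_pdh_coa);
    rates[ir++] = r;
    if (dy) { dy[C+BHB] -= r; dy[M+ACCOA] += 2*r*vc/vm; dy[M+COA] -= 2*r*vc/vm;
      dy[M+NADM] -= r*vc/vm; dy[M+NADHM] += r*vc/vm; }
    // mas
    r = cp.mas_k * (cy(NADH) * mt(NADM) - cy(NAD) * mt(NADHM) / c->keq_mas);
    rates[ir++] = r;
    if (dy) { dy[C+NADH] -= r; dy[C+NAD] += r; dy[M+NADM] -= r*vc/vm;
      dy[M+NADHM] += r*vc/vm; }
    // hk_atpase
    r = cp.hk_atpase * mm(cy(ATP), c->km_hk_atpase);
    rates[ir++] = r;
    if (dy) { dy[C+ATP] -= r; dy[C+ADP] += r; }
  }

  // ---- glycogen (astrocyte) ----
  {
    const int Ca = c->icyt[1];
    double cap = 1 - y[c->iGLY] / c->gly_cap;
    if (cap < 0) cap = 0;
    double r1 = c->glysyn_vmax * mm(y[Ca+HKPF], c->km_glysyn_hkpf) *
      mm(y[Ca+ATP], c->km_hk_atpase) * cap;
    rates[ir++] = r1;
    if (dy) { dy[Ca+HKPF] -= r1; dy[Ca+ATP] -= r1; dy[Ca+ADP] += r1;
      dy[c->iGLY] += r1; }
    double r2 = c->glyphos_vmax * mm(y[c->iGLY], c->km_glyphos) *
      c->ki_glyphos_glc / (c->ki_glyphos_glc + y[Ca+GLC]);
    rates[ir++] = r2;
    if (dy) { dy[c->iGLY] -= r2; dy[Ca+HKPF] += r2; }
  }

  // ---- pump + membrane ----
  {
    const int Cn = c->icyt[0];
    double atp = y[Cn+ATP], glc = y[Cn+GLC];
    double na_in = y[c->iNa], k_out = y[c->iK];
    double jp = c->pump_vmax *
      hillf(atp, c->km_pump_atp, c->hill_pump_atp) *
      mm(glc, c->km_pump_glc) *
      hillf(na_in, c->km_pump_na, c->hill_pump_na) * mm(k_out, c->km_pump_k);
    rates[ir++] = jp;
    if (dy) {
      dy[Cn+ATP] -= jp; dy[Cn+ADP] += jp;
      double v = y[c->iV], m = y[c->im], h = y[c->ih], n = y[c->in_];
      const double rt_f = 26.64;
      double e_na = rt_f * std::log(c->na_out / std::max(na_in, 1e-6));
      double e_k = rt_f * std::log(std::max(k_out, 1e-6) / c->k_in);
      double i_na = (c->gna * m*m*m*h + c->gna_leak) * (v - e_na);
      double i_k = c->gk * n*n*n*n * (v - e_k);
      double i_l = c->gl * (v - c->el);  // untracked (Cl-dominated) leak
      double i_pump = jp / c->ion_conv;
      double am, bm, ah, bh, an, bn, x;
      x = v + 40;
      am = (std::fabs(x) < 1e-7) ? 1.0 : 0.1 * x / (1 - std::exp(-x / 10));
      bm = 4 * std::exp(-(v + 65) / 18);
      ah = 0.07 * std::exp(-(v + 65) / 20);
      bh = 1 / (1 + std::exp(-(v + 35) / 10));
      x = v + 55;
      an = (std::fabs(x) < 1e-7) ? 0.1 : 0.01 * x / (1 - std::exp(-x / 10));
      bn = 0.125 * std::exp(-(v + 65) / 80);
      const double phi = 1000.0;
      dy[c->iV] = 1000.0 * (-(i_na + i_k + i_l + i_pump) + stim) / c->cm;
      dy[c->im] = phi * (am * (1 - m) - bm * m);
      dy[c->ih] = phi * (ah * (1 - h) - bh * h);
      dy[c->in_] = phi * (an * (1 - n) - bn * n);
      dy[c->iNa] = -c->ion_conv * i_na - 3 * jp;
      // astrocytic K+ clearance: dead zone above bath, then saturable
      double kx = k_out - c->k_bath;
      double clear = 0.0;
      if (kx >= c->k_clear_thresh) {
        double e = kx - c->k_clear_thresh;
        clear = c->k_clear * e / (e + c->km_clear);
      } else if (kx <= 0) {
        // weak re-supply from the bath below baseline
        clear = c->k_resupply * kx / (std::fabs(kx) + c->km_clear);
      }
      dy[c->iK] = c->ecs_k_ratio * (c->ion_conv * i_k - 2 * jp) - clear;
    }
  }
  if (ir != N_PROC) stop("internal: process count mismatch");
}

// [[Rcpp::export]]
NumericVector ngv_rhs_cpp(SEXP ctx, double t, NumericVector y, double stim) {
  XPtr<Ctx> c(ctx);
  NumericVector dy(y.size());
  std::vector<double> rates(N_PROC);
  ngv_core(c, t, REAL(y), stim, rates.data(), REAL(dy), y.size());
  return dy;
}

// [[Rcpp::export]]
NumericVector ngv_rates_cpp(SEXP ctx, double t, NumericVector y) {
  XPtr<Ctx> c(ctx);
  NumericVector out(N_PROC);
  ngv_core(c, t, REAL(y), 0.0, REAL(out), nullptr, y.size());
  out.names() = wrap(c->proc_names);
  return out;
}

// flux matrix over a trajectory (rows = times)
// [[Rcpp::export]]
NumericMatrix ngv_flux_matrix(SEXP ctx, NumericVector times, NumericMatrix y) {
  XPtr<Ctx> c(ctx);
  int nt = times.size();
  NumericMatrix out(nt, N_PROC);
  std::vector<double> row(y.ncol()), rates(N_PROC);
  for (int i = 0; i < nt; ++i) {
    for (int j = 0; j < y.ncol(); ++j) row[j] = y(i, j);
    ngv_core(c, times[i], row.data(), 0.0, rates.data(), nullptr, y.ncol());
    for (int j = 0; j < N_PROC; ++j) out(i, j) = rates[j];
  }
  colnames(out) = wrap(c->proc_names);
  return out;
}
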