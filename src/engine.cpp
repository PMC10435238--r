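// Hybrid stochastic simulation core for the synapse model.
//
// Piecewise-deterministic dynamics: continuous variables (compartment
// voltages, soma gates, BaP attenuation resources, spine calcium, buffer/dye,
// enzyme network, readout activations) are integrated with a mix of
// exponential-Euler (voltages, gates, linear resources) and RK4 (calcium +
// enzyme chemistry), while the discrete channel populations (AMPAr, NMDAr
// GluN2A/2B, GABA(A)r, T/R/L VGCC) and the plasticity chain jump with exact
// Gillespie sampling inside each step, with transition rates frozen over the
// step. Time-averaged open-state occupancies over each step drive the
// conductances and calcium fluxes, so brief channel openings are accounted
// for even with coarse steps during quiescent periods.
//
// Units: s, mV, uM (extracellular mM), nS, pA, pF.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>
#include <algorithm>
using namespace Rcpp;

static double P(const List& p, const char* name) {
  if (!p.containsElementNamed(name)) stop("missing parameter: %s", name);
  return as<double>(p[name]);
}

// ---------------------------------------------------------------------------
// population machinery

struct Trans { int from, to; };

struct Pop {
  int n;                        // number of states
  int total;                    // population size
  bool det;                     // mean-field mode
  std::vector<int> cnt;
  std::vector<double> occ;      // deterministic occupancy
  std::vector<Trans> trs;
  std::vector<double> rates;    // per transition (s^-1 per unit)
  std::vector<double> tavg;     // time-averaged occupancy over last step

  void init(int n_states, int size, bool deterministic, int init_state = 0) {
    n = n_states; total = size; det = deterministic;
    cnt.assign(n, 0); occ.assign(n, 0.0); tavg.assign(n, 0.0);
    cnt[init_state] = size; occ[init_state] = size;
    rates.assign(trs.size(), 0.0);
  }
  void set_det(bool d) {
    if (d == det) return;
    if (d) { for (int i = 0; i < n; ++i) occ[i] = cnt[i]; }
    else {
      // round occupancies to counts preserving the total
      int left = total;
      for (int i = 0; i < n; ++i) cnt[i] = 0;
      for (int i = 0; i < n - 1; ++i) {
        int c = (int)std::floor(occ[i] + 0.5);
        c = std::min(c, left); cnt[i] = c; left -= c;
      }
      cnt[n - 1] = left;
    }
    det = d;
  }
  // exact jump sampling over [0, dt] with frozen rates
  void step_jump(double dt) {
    std::fill(tavg.begin(), tavg.end(), 0.0);
    double t0 = 0.0;
    for (;;) {
      double total_a = 0.0;
      for (size_t k = 0; k < trs.size(); ++k)
        total_a += cnt[trs[k].from] * rates[k];
      double tnext;
      if (total_a <= 0.0) tnext = dt;
      else {
        double e = R::exp_rand() / total_a;
        tnext = std::min(dt, t0 + e);
      }
      for (int i = 0; i < n; ++i) tavg[i] += cnt[i] * (tnext - t0);
      t0 = tnext;
      if (t0 >= dt || total_a <= 0.0) break;
      double u = unif_rand() * total_a;
      double acc = 0.0;
      for (size_t k = 0; k < trs.size(); ++k) {
        acc += cnt[trs[k].from] * rates[k];
        if (u < acc) { cnt[trs[k].from]--; cnt[trs[k].to]++; break; }
      }
    }
    if (dt > 0) for (int i = 0; i < n; ++i) tavg[i] /= dt;
  }
  // mean-field occupancy propagation (explicit Euler substeps)
  void step_det(double dt) {
    double maxr = 0.0;
    for (size_t k = 0; k < trs.size(); ++k) maxr = std::max(maxr, rates[k]);
    // at (quasi-)stationarity the net fluxes vanish; skip the substepping
    {
      std::vector<double> d0(n, 0.0);
      for (size_t k = 0; k < trs.size(); ++k) {
        double f = occ[trs[k].from] * rates[k];
        d0[trs[k].from] -= f; d0[trs[k].to] += f;
      }
      double maxd = 0.0;
      for (int i = 0; i < n; ++i) maxd = std::max(maxd, std::fabs(d0[i]));
      if (maxd * dt < 1e-8 * std::max(1, total)) {
        for (int i = 0; i < n; ++i) tavg[i] = occ[i];
        return;
      }
    }
    int nsub = std::max(1, (int)std::ceil(dt * maxr / 0.2));
    nsub = std::min(nsub, 100000);
    double h = dt / nsub;
    std::fill(tavg.begin(), tavg.end(), 0.0);
    std::vector<double> d(n);
    for (int s = 0; s < nsub; ++s) {
      for (int i = 0; i < n; ++i) tavg[i] += occ[i] * h;
      std::fill(d.begin(), d.end(), 0.0);
      for (size_t k = 0; k < trs.size(); ++k) {
        double f = occ[trs[k].from] * rates[k];
        d[trs[k].from] -= f; d[trs[k].to] += f;
      }
      for (int i = 0; i < n; ++i) occ[i] = std::max(0.0, occ[i] + h * d[i]);
    }
    if (dt > 0) for (int i = 0; i < n; ++i) tavg[i] /= dt;
  }
  void step(double dt) { if (det) step_det(dt); else step_jump(dt); }
  double avg(int i) const { return tavg[i]; }
  double count_sum() const {
    if (det) { double s = 0; for (int i = 0; i < n; ++i) s += occ[i]; return s; }
    int s = 0; for (int i = 0; i < n; ++i) s += cnt[i]; return s;
  }
  double now(int i) const { return det ? occ[i] : (double)cnt[i]; }
};

// ---------------------------------------------------------------------------
// scheme construction

struct ChannelConsts {
  // AMPA
  double a_k1, a_km1, a_km2, a_alpha, a_beta, a_d0, a_d1, a_d2, a_g0, a_g1, a_g2;
  double rf_ampa, rb_ampa;
  // NMDA
  double n_fwd[6], n_bwd[6]; double rf_nmda, rb_nmda, b_fwd, b_bwd;
  // GABA
  double g_rb1, g_ru1, g_rb2, g_ru2, g_ro1, g_ro2, g_rc1, g_rc2, rb_gaba;
  // VGCC
  double rf_vgcc, rb_vgcc;
};

static ChannelConsts channel_consts(const List& p) {
  ChannelConsts c;
  c.a_k1 = P(p, "ampa_k1"); c.a_km1 = P(p, "ampa_km1"); c.a_km2 = P(p, "ampa_km2");
  c.a_alpha = P(p, "ampa_alpha"); c.a_beta = P(p, "ampa_beta");
  c.a_d0 = P(p, "ampa_delta0"); c.a_d1 = P(p, "ampa_delta1"); c.a_d2 = P(p, "ampa_delta2");
  c.a_g0 = P(p, "ampa_gamma0"); c.a_g1 = P(p, "ampa_gamma1"); c.a_g2 = P(p, "ampa_gamma2");
  c.rf_ampa = P(p, "rho_f_ampa"); c.rb_ampa = P(p, "rho_b_ampa");
  double fwd[6] = {P(p, "nmda_ka"), P(p, "nmda_kb"), P(p, "nmda_kc"),
                   P(p, "nmda_kd"), P(p, "nmda_ke"), P(p, "nmda_kf")};
  double bwd[6] = {P(p, "nmda_kma"), P(p, "nmda_kmb"), P(p, "nmda_kmc"),
                   P(p, "nmda_kmd"), P(p, "nmda_kme"), P(p, "nmda_kmf")};
  for (int i = 0; i < 6; ++i) { c.n_fwd[i] = fwd[i]; c.n_bwd[i] = bwd[i]; }
  c.rf_nmda = P(p, "rho_f_nmda"); c.rb_nmda = P(p, "rho_b_nmda");
  c.b_fwd = P(p, "glun2b_fwd"); c.b_bwd = P(p, "glun2b_bwd");
  c.g_rb1 = P(p, "gaba_rb1"); c.g_ru1 = P(p, "gaba_ru1");
  c.g_rb2 = P(p, "gaba_rb2"); c.g_ru2 = P(p, "gaba_ru2");
  c.g_ro1 = P(p, "gaba_ro1"); c.g_ro2 = P(p, "gaba_ro2");
  c.g_rc1 = P(p, "gaba_rc1"); c.g_rc2 = P(p, "gaba_rc2");
  c.rb_gaba = P(p, "rho_b_gaba");
  c.rf_vgcc = P(p, "rho_f_vgcc"); c.rb_vgcc = P(p, "rho_b_vgcc");
  return c;
}

// AMPA: states C0..C4 (0-4), O2..O4 (5-7), D0..D4 (8-12), D22..D24 (13-15)
static void ampa_scheme(Pop& pop) {
  std::vector<Trans>& t = pop.trs;
  t.clear();
  for (int i = 0; i < 4; ++i) { t.push_back({i, i + 1}); t.push_back({i + 1, i}); }
  for (int i = 2; i <= 4; ++i) { t.push_back({i, i + 3}); t.push_back({i + 3, i}); }
  t.push_back({0, 8}); t.push_back({8, 0});
  for (int i = 1; i <= 4; ++i) { t.push_back({i, i + 8}); t.push_back({i + 8, i}); }
  for (int i = 8; i < 12; ++i) { t.push_back({i, i + 1}); t.push_back({i + 1, i}); }
  for (int i = 10; i <= 12; ++i) { t.push_back({i, i + 3}); t.push_back({i + 3, i}); }
}
static void ampa_rates_fill(Pop& pop, const ChannelConsts& c, double glu) {
  double kon = c.a_k1 * glu * c.rf_ampa;
  double koff1 = c.a_km1 * c.rb_ampa;
  double koff2 = c.a_km2 * c.rb_ampa;
  int k = 0;
  for (int i = 0; i < 4; ++i) {
    pop.rates[k++] = (4 - i) * kon;
    pop.rates[k++] = (i + 1) * koff1;
  }
  // closing carries the backward temperature factor; opening does not
  for (int i = 0; i < 3; ++i) {
    pop.rates[k++] = c.a_beta; pop.rates[k++] = c.a_alpha * c.rb_ampa;
  }
  pop.rates[k++] = c.a_d0; pop.rates[k++] = c.a_g0;
  for (int i = 0; i < 4; ++i) { pop.rates[k++] = c.a_d1; pop.rates[k++] = c.a_g1; }
  for (int i = 0; i < 4; ++i) {
    pop.rates[k++] = (4 - i) * kon;
    pop.rates[k++] = (i + 1) * koff2;
  }
  for (int i = 0; i < 3; ++i) { pop.rates[k++] = c.a_d2; pop.rates[k++] = c.a_g2; }
}

// NMDA linear chain 0..6, open 5,6
static void nmda_scheme(Pop& pop) {
  pop.trs.clear();
  for (int i = 0; i < 6; ++i) { pop.trs.push_back({i, i + 1}); pop.trs.push_back({i + 1, i}); }
}
static void nmda_rates_fill(Pop& pop, const ChannelConsts& c, double glu, bool glun2b) {
  double sf = glun2b ? c.b_fwd : 1.0, sb = glun2b ? c.b_bwd : 1.0;
  int k = 0;
  for (int i = 0; i < 6; ++i) {
    double f = c.n_fwd[i] * (i < 2 ? glu : 1.0) * sf * c.rf_nmda;
    double b = c.n_bwd[i] * sb * c.rb_nmda;
    pop.rates[k++] = f; pop.rates[k++] = b;
  }
}

// GABA: C0 C1 C2 O1 O2 = 0..4
static void gaba_scheme(Pop& pop) {
  pop.trs = { {0,1},{1,0},{1,2},{2,1},{1,3},{3,1},{2,4},{4,2} };
}
static void gaba_rates_fill(Pop& pop, const ChannelConsts& c, double gaba) {
  pop.rates[0] = c.g_rb1 * gaba; pop.rates[1] = c.g_ru1;
  pop.rates[2] = c.g_rb2 * gaba; pop.rates[3] = c.g_ru2;
  pop.rates[4] = c.g_ro1; pop.rates[5] = c.g_rc1 * c.rb_gaba;
  pop.rates[6] = c.g_ro2; pop.rates[7] = c.g_rc2 * c.rb_gaba;
}

// T/R joint gate states: 0 (m closed, h avail), 1 (m open, h avail = conducting),
// 2 (m closed, h inact), 3 (m open, h inact)
static void tr_scheme(Pop& pop) {
  pop.trs = { {0,1},{1,0},{2,3},{3,2},{0,2},{2,0},{1,3},{3,1} };
}
struct GateRates { double am, bm, ah, bh; };
static GateRates t_gate_rates(double v, const ChannelConsts& c) {
  double minf = 1.0 / (1.0 + std::exp((-32.0 - v) / 7.0));
  double minf_s = 1.0 / (1.0 + std::exp((-32.0 + 20.0) / 7.0));
  double tau_m = 1.0 / (minf_s / (1.0 - minf_s) + 1.0);       // ms
  double hinf = 1.0 / (1.0 + std::exp((v + 70.0) / 6.5));
  double tau_h = 50.0;
  return { 1e3 * minf / tau_m * c.rf_vgcc, 1e3 * (1 - minf) / tau_m * c.rb_vgcc,
           1e3 * hinf / tau_h * c.rf_vgcc, 1e3 * (1 - hinf) / tau_h * c.rb_vgcc };
}
static GateRates r_gate_rates(double v, const ChannelConsts& c) {
  double minf = 1.0 / (1.0 + std::exp((3.0 - v) / 8.0));
  double minf_s = 1.0 / (1.0 + std::exp((3.0 - 10.0) / 8.0));
  double tau_m = 1.0 / (40.0 * minf_s / (1.0 - minf_s) + 40.0);
  double hinf = 1.0 / (1.0 + std::exp((v + 39.0) / 9.2));
  double tau_h = 100.0;
  return { 1e3 * minf / tau_m * c.rf_vgcc, 1e3 * (1 - minf) / tau_m * c.rb_vgcc,
           1e3 * hinf / tau_h * c.rf_vgcc, 1e3 * (1 - hinf) / tau_h * c.rb_vgcc };
}
static void tr_rates_fill(Pop& pop, const GateRates& g) {
  pop.rates[0] = g.am; pop.rates[1] = g.bm;
  pop.rates[2] = g.am; pop.rates[3] = g.bm;
  pop.rates[4] = g.bh; pop.rates[5] = g.ah;
  pop.rates[6] = g.bh; pop.rates[7] = g.ah;
}

// L: C O1 O2 = 0..2
static void l_scheme(Pop& pop) {
  pop.trs = { {0,1},{1,0},{0,2},{2,0} };
}
static void l_rates_fill(Pop& pop, const ChannelConsts& c, double v) {
  double aL = 0.83 / (1.0 + std::exp((13.7 - v) / 6.1));
  double b1 = 0.53 / (1.0 + std::exp((v - 11.5) / 6.4));
  double b2 = 1.86 / (1.0 + std::exp((v - 18.8) / 6.17));
  pop.rates[0] = 1e3 * aL * c.rf_vgcc; pop.rates[1] = 1e3 * b1 * c.rb_vgcc;
  pop.rates[2] = 1e3 * aL * c.rf_vgcc; pop.rates[3] = 1e3 * b2 * c.rb_vgcc;
}

// plasticity chain: NC LTP LTD = 0..2
static void plast_scheme(Pop& pop) {
  pop.trs = { {0,1},{2,0},{1,0},{0,2} };  // toward-LTP: NC->LTP, LTD->NC (p_rate)
}
static void plast_rates_fill(Pop& pop, double p_rate, double d_rate) {
  pop.rates[0] = p_rate; pop.rates[1] = p_rate;
  pop.rates[2] = d_rate; pop.rates[3] = d_rate;
}

// ---------------------------------------------------------------------------
// GHK flux

static double ghk_phi(double v_mv, double temp_c) {
  return 2.0 * (v_mv * 1e-3) * 96485.0 / (8.314 * (temp_c + 273.15));
}
// Cai in uM, Cao in mM; returns flux factor (positive = influx for Cai<Cao,
// v < Nernst), "pA per nS-weight"
static double ghk_flux_c(double v_mv, double cai_um, double cao_mm, double temp_c,
                         double p_ca) {
  double phi = ghk_phi(v_mv, temp_c);
  double ci = cai_um * 1e-3;  // mM
  double pref = p_ca * 1e-6 * 2.0 * 96485.0; // P z F
  if (std::fabs(phi) < 1e-6)
    return -pref * ((ci - cao_mm) + cao_mm * phi * 0.5);
  double em = std::exp(-phi);
  return -pref * phi * (ci - cao_mm * em) / (1.0 - em);
}

// ---------------------------------------------------------------------------
// enzyme network derivatives (17 species + calcium flux)

struct EnzConsts {
  double kon1c, kon2c, kon1n, kon2n, koff1c, koff2c, koff1n, koff2n;
  double konk1c, konk2c, konk1n, konk2n, koffk1c, koffk2c, koffk1n, koffk2n;
  double kf_cam0, kf_cam2c, kf_cam2n, kf_cam4;
  double kb_cam0, kb_cam2c, kb_cam2n, kb_cam4;
  double k1, k2, k3, k4, k5, kf_can, kb_can;
  double rho_b_camkii, rho_f_can, rho_b_can, kcam_total;
};
static EnzConsts enz_consts(const List& p) {
  EnzConsts e;
  e.kon1c = P(p, "kon1c"); e.kon2c = P(p, "kon2c");
  e.kon1n = P(p, "kon1n"); e.kon2n = P(p, "kon2n");
  e.koff1c = P(p, "koff1c"); e.koff2c = P(p, "koff2c");
  e.koff1n = P(p, "koff1n"); e.koff2n = P(p, "koff2n");
  e.konk1c = P(p, "konk1c"); e.konk2c = P(p, "konk2c");
  e.konk1n = P(p, "konk1n"); e.konk2n = P(p, "konk2n");
  e.koffk1c = P(p, "koffk1c"); e.koffk2c = P(p, "koffk2c");
  e.koffk1n = P(p, "koffk1n"); e.koffk2n = P(p, "koffk2n");
  e.kf_cam0 = P(p, "kf_cam0"); e.kf_cam2c = P(p, "kf_cam2c");
  e.kf_cam2n = P(p, "kf_cam2n"); e.kf_cam4 = P(p, "kf_cam4");
  e.kb_cam0 = P(p, "kb_cam0"); e.kb_cam2c = P(p, "kb_cam2c");
  e.kb_cam2n = P(p, "kb_cam2n"); e.kb_cam4 = P(p, "kb_cam4");
  e.k1 = P(p, "k1"); e.k2 = P(p, "k2"); e.k3 = P(p, "k3");
  e.k4 = P(p, "k4"); e.k5 = P(p, "k5");
  e.kf_can = P(p, "kf_can"); e.kb_can = P(p, "kb_can");
  e.rho_b_camkii = P(p, "rho_b_camkii");
  e.rho_f_can = P(p, "rho_f_can"); e.rho_b_can = P(p, "rho_b_can");
  e.kcam_total = P(p, "kcam_total");
  return e;
}

// y: cam0 cam2c cam2n cam4 mcan can4 mkcam kcam0 kcam2c kcam2n kcam4
//    pcam0 pcam2c pcam2n pcam4 p p2   (indices 0..16)
// dy gets the 17 derivatives; returns net calcium flux (uM/s) into free Ca
static double enzyme_deriv(const double* y, double ca, const EnzConsts& e,
                           double* dy) {
  double ca2 = ca * ca;
  // lumped "adapt" rates a*b/(c + d*Ca) of the coarse-grained scheme
  double kf2c = e.kon1c * e.kon2c / (e.koff1c + e.kon2c * ca);
  double kb2c = e.koff1c * e.koff2c / (e.koff1c + e.kon2c * ca);
  double kf2n = e.kon1n * e.kon2n / (e.koff1n + e.kon2n * ca);
  double kb2n = e.koff1n * e.koff2n / (e.koff1n + e.kon2n * ca);
  double kfk2c = e.konk1c * e.konk2c / (e.koffk1c + e.konk2c * ca);
  double kbk2c = e.koffk1c * e.koffk2c / (e.koffk1c + e.konk2c * ca);
  double kfk2n = e.konk1n * e.konk2n / (e.koffk1n + e.konk2n * ca);
  double kbk2n = e.koffk1n * e.koffk2n / (e.koffk1n + e.konk2n * ca);

  const double cam0 = y[0], cam2c = y[1], cam2n = y[2], cam4 = y[3];
  const double mcan = y[4], can4 = y[5], mkcam = y[6];
  const double kcam0 = y[7], kcam2c = y[8], kcam2n = y[9], kcam4 = y[10];
  const double pcam0 = y[11], pcam2c = y[12], pcam2n = y[13], pcam4 = y[14];
  const double pp = y[15], pp2 = y[16];

  double F1 = kf2c * cam0 * ca2, F2 = kf2c * cam2n * ca2;
  double F3 = kb2c * cam2c,      F4 = kb2c * cam4;
  double F5 = kf2n * cam0 * ca2, F6 = kf2n * cam2c * ca2;
  double F7 = kb2n * cam2n,      F8 = kb2n * cam4;
  double G1 = kfk2c * kcam0 * ca2, G2 = kfk2c * kcam2n * ca2;
  double G3 = kbk2c * kcam2c,      G4 = kbk2c * kcam4;
  double G5 = kfk2n * kcam0 * ca2, G6 = kfk2n * kcam2c * ca2;
  double G7 = kbk2n * kcam2n,      G8 = kbk2n * kcam4;
  double B1 = e.kf_cam0 * cam0 * mkcam,  B1b = e.kb_cam0 * kcam0;
  double B2 = e.kf_cam2c * cam2c * mkcam, B2b = e.kb_cam2c * kcam2c;
  double B3 = e.kf_cam2n * cam2n * mkcam, B3b = e.kb_cam2n * kcam2n;
  double B4 = e.kf_cam4 * cam4 * mkcam,  B4b = e.kb_cam4 * kcam4;
  double camkii = kcam0 + kcam2c + kcam2n + kcam4 +
                  pcam0 + pcam2c + pcam2n + pcam4 + pp + pp2;
  double Ffrac = camkii / e.kcam_total;
  double k1f = e.k1 * Ffrac;
  double k2e = e.k2 * e.rho_b_camkii;
  double k3e = e.k3 * e.rho_b_camkii;
  double k5e = e.k5 * e.rho_b_camkii;
  double P10 = k1f * kcam0, P12c = k1f * kcam2c, P12n = k1f * kcam2n, P14 = k1f * kcam4;
  double C1 = e.kf_can * e.rho_f_can * cam4 * mcan;
  double C1b = e.kb_can * e.rho_b_can * can4;

  dy[0] = -F1 - F5 + F3 + F7 - B1 + B1b + k2e * pcam0;
  dy[1] = F1 - F3 - F6 + F8 - B2 + B2b + k2e * pcam2c;
  dy[2] = F5 - F7 - F2 + F4 - B3 + B3b + k2e * pcam2n;
  dy[3] = F2 + F6 - F4 - F8 - B4 + B4b + k2e * pcam4 - C1 + C1b;
  dy[4] = -C1 + C1b;
  dy[5] = C1 - C1b;
  dy[6] = -B1 - B2 - B3 - B4 + B1b + B2b + B3b + B4b + k3e * pp;
  dy[7] = B1 - B1b - G1 - G5 + G3 + G7 - P10;
  dy[8] = B2 - B2b + G1 - G3 - G6 + G8 - P12c;
  dy[9] = B3 - B3b + G5 - G7 - G2 + G4 - P12n;
  dy[10] = B4 - B4b + G2 + G6 - G4 - G8 - P14;
  dy[11] = P10 - k2e * pcam0;
  dy[12] = P12c - k2e * pcam2c;
  dy[13] = P12n - k2e * pcam2n;
  dy[14] = P14 - k2e * pcam4;
  dy[15] = k2e * (pcam0 + pcam2c + pcam2n + pcam4) - k3e * pp - e.k4 * pp + k5e * pp2;
  dy[16] = e.k4 * pp - k5e * pp2;

  double ca_flux = -2.0 * (F1 + F2 + F5 + F6 + G1 + G2 + G5 + G6)
                 + 2.0 * (F3 + F4 + F7 + F8 + G3 + G4 + G7 + G8);
  return ca_flux;
}

// [[Rcpp::export]]
NumericVector cpp_enzyme_deriv(NumericVector y, double ca, List params) {
  if (y.size() != 17) stop("enzyme state must have 17 species");
  EnzConsts e = enz_consts(params);
  NumericVector out(18);
  double dy[17];
  out[17] = enzyme_deriv(REAL(y), ca, e, dy);
  for (int i = 0; i < 17; ++i) out[i] = dy[i];
  return out;
}

// ---------------------------------------------------------------------------
// readout geometry

struct Polygon {
  std::vector<double> x, y;
  bool contains(double px, double py) const {
    int n = x.size();
    bool inside = false;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double xi = x[i], yi = y[i], xj = x[j], yj = y[j];
      // boundary counts as inside
      double cross = (xj - xi) * (py - yi) - (px - xi) * (yj - yi);
      if (std::min(yi, yj) - 1e-12 <= py && py <= std::max(yi, yj) + 1e-12 &&
          std::min(xi, xj) - 1e-12 <= px && px <= std::max(xi, xj) + 1e-12 &&
          std::fabs(cross) < 1e-9) return true;
      bool intersect = ((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi);
      if (intersect) inside = !inside;
    }
    return inside;
  }
};
static Polygon polygon_from(NumericMatrix m) {
  Polygon p;
  for (int i = 0; i < m.nrow(); ++i) { p.x.push_back(m(i, 0)); p.y.push_back(m(i, 1)); }
  return p;
}

// [[Rcpp::export]]
LogicalMatrix cpp_region_indicator(NumericVector can, NumericVector camkii,
                                   NumericMatrix ltp, NumericMatrix ltd) {
  Polygon pp = polygon_from(ltp), pd = polygon_from(ltd);
  int n = can.size();
  LogicalMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = pp.contains(can[i], camkii[i]);
    out(i, 1) = pd.contains(can[i], camkii[i]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// the simulation engine

struct Engine {
  // parameters
  List par;
  ChannelConsts cc;
  EnzConsts ec;
  double temp, ca_o, mg_o;
  double e_leak, g_neck, g_leak_sp, c_sp, g_leak_dend, c_dend, g_diff;
  double g_leak_soma, c_soma, g_na, g_k, e_na, e_k;
  double i_amp, delta_decay, delta_aux, delta_age_step, tau_rec_lambda, tau_rec_age;
  double phi_d, erev_cl, gamma_gaba, gamma_nmda_ns, f_ca;
  double gamma_a2, gamma_a3, gamma_a4;
  double gamma_t, gamma_r, gamma_l, vgcc_scale;
  double gamma_sk, erev_sk, sk_half, sk_hill, tau_sk, rho_f_sk, rho_b_sk;
  double kon_buff, koff_buff, buff_total, ca_inf, tau_ca, tau_ca_diff;
  double kon_dye, koff_dye, dye_total;
  double p_ca, ghk_scale, ca_per_pa;
  double a_d, a_p, b_d, b_p, t_p, t_d, k_p, k_d;
  double n_sk;
  Polygon poly_ltp, poly_ltd;

  // state
  double vsp, vdend, vsoma, m, h, n_gate;
  double lam, lamaux, lamage;
  double ca, buff, dye, msk;
  double enz[17];
  double actd, actp;
  Pop ampa, n2a, n2b, gabar, vgT, vgR, vgL, chain;
  double glu, gaba_conc, ibap;
  int neg_ca_events;

  void setup(const List& p, int n2a_count, int n2b_count,
             const std::vector<std::string>& det_sources) {
    par = p;
    cc = channel_consts(p); ec = enz_consts(p);
    temp = P(p, "temperature_eff"); ca_o = P(p, "ca_o"); mg_o = P(p, "mg_o");
    e_leak = P(p, "e_leak"); g_neck = P(p, "g_neck"); g_leak_sp = P(p, "g_leak_sp");
    c_sp = P(p, "c_sp"); g_leak_dend = P(p, "g_leak_dend"); c_dend = P(p, "c_dend");
    g_diff = P(p, "g_diff"); g_leak_soma = P(p, "g_leak_soma"); c_soma = P(p, "c_soma");
    g_na = P(p, "g_na"); g_k = P(p, "g_k"); e_na = P(p, "e_na"); e_k = P(p, "e_k");
    i_amp = P(p, "i_amp"); delta_decay = P(p, "delta_decay"); delta_aux = P(p, "delta_aux");
    delta_age_step = P(p, "delta_age"); tau_rec_lambda = P(p, "tau_rec_lambda");
    tau_rec_age = P(p, "tau_rec_age");
    phi_d = P(p, "phi_dist"); erev_cl = P(p, "erev_cl");
    gamma_gaba = P(p, "gamma_gaba"); gamma_nmda_ns = P(p, "gamma_nmda_ns");
    f_ca = P(p, "f_ca");
    gamma_a2 = P(p, "gamma_a2"); gamma_a3 = P(p, "gamma_a3"); gamma_a4 = P(p, "gamma_a4");
    gamma_t = P(p, "gamma_t"); gamma_r = P(p, "gamma_r"); gamma_l = P(p, "gamma_l");
    vgcc_scale = P(p, "vgcc_scale");
    gamma_sk = P(p, "gamma_sk"); erev_sk = P(p, "erev_sk"); n_sk = P(p, "n_sk");
    sk_half = P(p, "sk_half"); sk_hill = P(p, "sk_hill"); tau_sk = P(p, "tau_sk");
    rho_f_sk = P(p, "rho_f_sk"); rho_b_sk = P(p, "rho_b_sk");
    kon_buff = P(p, "kon_buff"); koff_buff = P(p, "koff_buff");
    buff_total = P(p, "buff_total"); ca_inf = P(p, "ca_inf"); tau_ca = P(p, "tau_ca");
    tau_ca_diff = P(p, "tau_ca_diff");
    kon_dye = P(p, "kon_dye"); koff_dye = P(p, "koff_dye"); dye_total = P(p, "dye_total");
    p_ca = P(p, "p_ca"); ghk_scale = P(p, "ghk_scale"); ca_per_pa = P(p, "ca_per_pa");
    a_d = P(p, "a_d"); a_p = P(p, "a_p"); b_d = P(p, "b_d"); b_p = P(p, "b_p");
    t_p = P(p, "t_p"); t_d = P(p, "t_d"); k_p = P(p, "k_p"); k_d = P(p, "k_d");
    poly_ltp = polygon_from(as<NumericMatrix>(p["ltp_polygon"]));
    poly_ltd = polygon_from(as<NumericMatrix>(p["ltd_polygon"]));

    auto has = [&](const char* s) {
      for (auto& d : det_sources) if (d == s) return true;
      return false;
    };
    ampa_scheme(ampa); ampa.init(16, (int)P(p, "n_ampa"), has("ampa"));
    nmda_scheme(n2a); n2a.init(7, n2a_count, has("nmda"));
    nmda_scheme(n2b); n2b.init(7, n2b_count, has("nmda"));
    gaba_scheme(gabar); gabar.init(5, (int)P(p, "n_gaba"), has("gaba"));
    tr_scheme(vgT); vgT.init(4, (int)P(p, "n_vgcc"), has("vgcc"));
    tr_scheme(vgR); vgR.init(4, (int)P(p, "n_vgcc"), has("vgcc"));
    l_scheme(vgL); vgL.init(3, (int)P(p, "n_vgcc"), has("vgcc"));
    plast_scheme(chain); chain.init(3, (int)P(p, "n_processes"), has("plasticity"));

    vsp = vdend = vsoma = e_leak;
    soma_gate_init();
    lam = lamaux = lamage = 1.0;
    ca = ca_inf;
    buff = buff_total * ca / (ca + koff_buff / kon_buff);
    dye = dye_total > 0 ? dye_total * ca / (ca + koff_dye / kon_dye) : 0.0;
    msk = 0.0;
    for (int i = 0; i < 17; ++i) enz[i] = 0.0;
    enz[0] = P(p, "cam_total"); enz[4] = P(p, "can_total"); enz[6] = P(p, "kcam_total");
    actd = actp = 0.0;
    glu = 0.0; gaba_conc = 0.0; ibap = 0.0;
    neg_ca_events = 0;
  }

  // soma gate rate functions (input mV, output s^-1); printed in ms^-1
  static double vtrap(double x, double k) {
    // x / (1 - exp(-x/k)) with series branch near 0
    if (std::fabs(x) < 1e-4 * k) return k * (1.0 + x / (2.0 * k));
    return x / (1.0 - std::exp(-x / k));
  }
  double alpha_m(double v) const { return 1e3 * 0.4 * vtrap(v + 30.0, 7.2); }
  double beta_m(double v) const { return 1e3 * 0.124 * vtrap(-(v + 30.0), 7.2); }
  double alpha_h(double v) const { return 1e3 * 0.01 * vtrap(-(v + 45.0), 1.5); }
  double beta_h(double v) const { return 1e3 * 0.03 * vtrap(v + 45.0, 1.5); }
  double n_inf(double v) const { return 1.0 / (1.0 + std::exp(-0.11 * (v - 13.0))); }
  double n_tau(double v) const { // seconds
    double an = std::exp(-0.11 * (v - 13.0)), bn = std::exp(-0.08 * (v - 13.0));
    double t = 50.0 * bn / (1.0 + an);
    return std::max(t, 2.0) * 1e-3;
  }
  void soma_gate_init() {
    double am = alpha_m(vsoma), bm = beta_m(vsoma);
    m = am / (am + bm);
    double ah = alpha_h(vsoma), bh = beta_h(vsoma);
    h = ah / (ah + bh);
    n_gate = n_inf(vsoma);
  }

  void fill_rates() {
    ampa_rates_fill(ampa, cc, glu);
    nmda_rates_fill(n2a, cc, glu, false);
    nmda_rates_fill(n2b, cc, glu, true);
    gaba_rates_fill(gabar, cc, gaba_conc);
    tr_rates_fill(vgT, t_gate_rates(vsp, cc));
    tr_rates_fill(vgR, r_gate_rates(vsp, cc));
    l_rates_fill(vgL, cc, vsp);
    double p_rate = (1.0 / t_p) * actp * actp / (actp * actp + k_p * k_p);
    double d_rate = (1.0 / t_d) * actd * actd / (actd * actd + k_d * k_d);
    plast_rates_fill(chain, p_rate, d_rate);
  }

  // one step of length dt
  void step(double dt) {
    fill_rates();
    ampa.step(dt); n2a.step(dt); n2b.step(dt); gabar.step(dt);
    vgT.step(dt); vgR.step(dt); vgL.step(dt); chain.step(dt);

    // time-averaged conducting occupancies
    double g_ampa = gamma_a2 * ampa.avg(5) + gamma_a3 * ampa.avg(6) + gamma_a4 * ampa.avg(7);
    double nmda_open = n2a.avg(5) + n2a.avg(6) + n2b.avg(5) + n2b.avg(6);
    double B = 1.0 / (1.0 + mg_o / 3.57 * std::exp(-0.062 * vsp));
    double g_nmda = nmda_open * B * gamma_nmda_ns;
    double gaba_open = gabar.avg(3) + gabar.avg(4);
    double oT = vgT.avg(1), oR = vgR.avg(1), oL = vgL.avg(1) + vgL.avg(2);

    // calcium source currents (pA); GHK with frozen V, current Ca inside RK4
    double phi_now = ghk_flux_c(vsp, ca, ca_o, temp, p_ca);
    double i_t = gamma_t * vgcc_scale * phi_now * oT;
    double i_r = gamma_r * vgcc_scale * phi_now * oR;
    double i_l = gamma_l * vgcc_scale * phi_now * oL;

    // --- voltages (exponential Euler, frozen couplings) ---
    double g_sk = gamma_sk * msk * n_sk;
    double g_bap = lam * g_diff * phi_d;
    {
      double Gsp = g_neck + g_leak_sp + g_ampa + g_nmda + g_sk;
      double Asp = g_neck * vdend + g_leak_sp * e_leak + g_sk * erev_sk
                 + i_t + i_r + i_l; // AMPA/NMDA reversal 0 adds nothing
      double Gd = g_bap + g_neck + g_leak_dend + gaba_open * gamma_gaba;
      double Ad = g_bap * vsoma + g_neck * vsp + g_leak_dend * e_leak
                + gaba_open * gamma_gaba * erev_cl;
      double gna_eff = g_na * m * m * m * h * lamage;
      double gk_eff = g_k * n_gate;
      double Gs = g_bap + g_leak_soma + gna_eff + gk_eff;
      double As = g_bap * vdend + g_leak_soma * e_leak + gna_eff * e_na
                + gk_eff * e_k + lamage * ibap;
      double vsp_new = ee_update(vsp, Gsp, Asp, c_sp, dt);
      double vd_new = ee_update(vdend, Gd, Ad, c_dend, dt);
      double vs_new = ee_update(vsoma, Gs, As, c_soma, dt);
      vsp = vsp_new; vdend = vd_new; vsoma = vs_new;
    }

    // --- soma gates (Rush-Larsen) and SK ---
    {
      double am = alpha_m(vsoma), bm = beta_m(vsoma);
      m += (am / (am + bm) - m) * (1.0 - std::exp(-(am + bm) * dt));
      double ah = alpha_h(vsoma), bh = beta_h(vsoma);
      h += (ah / (ah + bh) - h) * (1.0 - std::exp(-(ah + bh) * dt));
      double ni = n_inf(vsoma), nt = n_tau(vsoma);
      n_gate += (ni - n_gate) * (1.0 - std::exp(-dt / nt));
      double r = std::pow(ca, sk_hill) / (std::pow(ca, sk_hill) + std::pow(sk_half, sk_hill));
      double k_off = rho_b_sk / tau_sk;
      double minf_sk = std::min(1.0, r * rho_f_sk);
      msk += (minf_sk - msk) * (1.0 - std::exp(-k_off * dt));
    }

    // --- BaP adaptation resources ---
    lam = resource_update(lam, 1.0 / tau_rec_lambda,
                          delta_decay / std::max(lamaux, 1e-6) * ibap, dt);
    lamaux = resource_update(lamaux, 1.0 / tau_rec_lambda, delta_aux * ibap, dt);
    lamage = resource_update(lamage, 1.0 / tau_rec_age, delta_age_step * ibap, dt);

    // --- chemistry: Ca, buffer, dye, enzymes (RK4 with substeps) ---
    {
      double influx_w = ghk_scale * ca_per_pa;
      double nmda_w = f_ca * g_nmda;  // x phi = CaNMDA (pA)
      double vg_w = vgcc_scale * (gamma_t * oT + gamma_r * oR + gamma_l * oL);
      int nsub = std::max(1, (int)std::ceil(dt / 5e-5));
      double hstep = dt / nsub;
      double y[20], k1v[20], k2v[20], k3v[20], k4v[20], tmp[20];
      for (int s = 0; s < nsub; ++s) {
        pack(y);
        chem_deriv(y, nmda_w, vg_w, influx_w, k1v);
        axpy(y, k1v, hstep * 0.5, tmp); chem_deriv(tmp, nmda_w, vg_w, influx_w, k2v);
        axpy(y, k2v, hstep * 0.5, tmp); chem_deriv(tmp, nmda_w, vg_w, influx_w, k3v);
        axpy(y, k3v, hstep, tmp); chem_deriv(tmp, nmda_w, vg_w, influx_w, k4v);
        for (int i = 0; i < 20; ++i)
          y[i] += hstep / 6.0 * (k1v[i] + 2 * k2v[i] + 2 * k3v[i] + k4v[i]);
        if (y[0] < 0) { y[0] = 0; neg_ca_events++; }
        unpack(y);
      }
    }

    // --- readout activations (exact within the step) ---
    {
      double camkii = 0;
      for (int i = 7; i < 17; ++i) camkii += enz[i];
      double can4 = enz[5];
      bool in_p = poly_ltp.contains(can4, camkii);
      bool in_d = poly_ltd.contains(can4, camkii);
      actp = in_p ? actp + a_p * dt : actp * std::exp(-b_p * dt);
      actd = in_d ? actd + a_d * dt : actd * std::exp(-b_d * dt);
    }
  }

  static double ee_update(double v, double G, double A, double C, double dt) {
    if (G <= 0) return v + A / C * 1e3 * dt;
    double vss = A / G;
    return vss + (v - vss) * std::exp(-G / C * 1e3 * dt);
  }
  // dx/dt = (1 - x)*rec - use*x  (frozen use-coefficient over the step)
  static double resource_update(double x, double rec, double use, double dt) {
    double rate = rec + use;
    double xss = rec / rate;
    return xss + (x - xss) * std::exp(-rate * dt);
  }

  void pack(double* y) {
    y[0] = ca; y[1] = buff; y[2] = dye;
    for (int i = 0; i < 17; ++i) y[3 + i] = enz[i];
  }
  void unpack(const double* y) {
    ca = y[0]; buff = y[1]; dye = y[2];
    for (int i = 0; i < 17; ++i) enz[i] = std::max(0.0, y[3 + i]);
  }
  void chem_deriv(const double* y, double nmda_w, double vg_w, double influx_w,
                  double* dy) {
    double cay = std::max(0.0, y[0]);
    double phi = ghk_flux_c(vsp, cay, ca_o, temp, p_ca);
    double influx = influx_w * phi * (nmda_w + vg_w);
    double dbuff = kon_buff * (buff_total - y[1]) * cay - koff_buff * y[1];
    double ddye = dye_total > 0
      ? kon_dye * (dye_total - y[2]) * cay - koff_dye * y[2] : 0.0;
    double enz_flux = enzyme_deriv(y + 3, cay, ec, dy + 3);
    double diff_src = std::max(ca_inf, cay / 3.0);
    dy[0] = (ca_inf - cay) / tau_ca + influx + (diff_src - cay) / tau_ca_diff
          - dbuff - ddye + enz_flux;
    dy[1] = dbuff;
    dy[2] = ddye;
  }
  static void axpy(const double* y, const double* k, double a, double* out) {
    for (int i = 0; i < 20; ++i) out[i] = y[i] + a * k[i];
  }
};

// ---------------------------------------------------------------------------
// main entry

// events: matrix with columns (time, code, value)
//   code 1: glutamate delta (uM), code 2: GABA delta (uM), code 3: IBaP delta (pA)
// control: list(duration, dt_stim, dt_ap, dt_relax, output_dt,
//               warmup_det, warmup_stoch, post_times, stim_end, record_peaks)
// [[Rcpp::export]]
List engine_run(List params, NumericMatrix events, List control,
                int n_glun2a, int n_glun2b, CharacterVector det_sources) {
  std::vector<std::string> dets;
  for (int i = 0; i < det_sources.size(); ++i)
    dets.push_back(as<std::string>(det_sources[i]));

  Engine E;
  E.setup(params, n_glun2a, n_glun2b, dets);

  double duration = as<double>(control["duration"]);
  double dt_stim = as<double>(control["dt_stim"]);
  double dt_ap = as<double>(control["dt_ap"]);
  double dt_relax = as<double>(control["dt_relax"]);
  double output_dt = as<double>(control["output_dt"]);
  double warm_det = as<double>(control["warmup_det"]);
  double warm_sto = as<double>(control["warmup_stoch"]);
  NumericVector post_times = as<NumericVector>(control["post_times"]);
  double stim_end = as<double>(control["stim_end"]);
  bool record_peaks = as<bool>(control["record_peaks"]);

  // --- warm-up: mean-field relaxation, then stochastic settling ---
  if (warm_det > 0) {
    bool da = E.ampa.det, dn1 = E.n2a.det, dn2 = E.n2b.det, dg = E.gabar.det;
    bool dt_ = E.vgT.det, dr = E.vgR.det, dl = E.vgL.det;
    E.ampa.set_det(true); E.n2a.set_det(true); E.n2b.set_det(true);
    E.gabar.set_det(true); E.vgT.set_det(true); E.vgR.set_det(true); E.vgL.set_det(true);
    double t = 0;
    while (t < warm_det) { E.step(dt_relax); t += dt_relax; }
    E.ampa.set_det(da); E.n2a.set_det(dn1); E.n2b.set_det(dn2); E.gabar.set_det(dg);
    E.vgT.set_det(dt_); E.vgR.set_det(dr); E.vgL.set_det(dl);
  }
  {
    double t = 0;
    while (t < warm_sto) { E.step(dt_relax); t += dt_relax; }
  }
  // fresh readout state per sample
  E.actd = E.actp = 0.0;
  E.chain.init(3, E.chain.total, E.chain.det);

  // --- output buffers ---
  int n_out = (int)std::floor(duration / output_dt) + 1;
  int n_cols = 24;
  NumericMatrix traj(n_out, n_cols);
  CharacterVector col_names = CharacterVector::create(
    "time", "v_sp", "v_dend", "v_soma", "ca", "buff_ca",
    "ampa_open", "glun2a_open", "glun2b_open", "gaba_open",
    "vgcc_t_open", "vgcc_r_open", "vgcc_l_open", "m_sk",
    "cam_ca", "camkii", "can", "act_d", "act_p", "nc", "ltp", "ltd",
    "lambda", "lambda_age");
  colnames(traj) = col_names;

  int n_pulse = post_times.size();
  NumericMatrix peaks(record_peaks ? n_pulse : 0, 4);
  if (record_peaks && n_pulse > 0)
    colnames(peaks) = CharacterVector::create("time", "v_soma_peak", "v_dend_peak", "v_sp_peak");
  for (int i = 0; i < peaks.nrow(); ++i) {
    peaks(i, 0) = post_times[i];
    peaks(i, 1) = peaks(i, 2) = peaks(i, 3) = -1e9;
  }

  double max_ca = E.ca, max_vsp = E.vsp;
  bool conserved = true;

  // --- main loop ---
  double t = 0.0;
  int ev_i = 0, out_i = 0, pulse_lo = 0;
  int n_ev = events.nrow();
  double next_out = 0.0;

  auto record = [&](double tt) {
    if (out_i >= n_out) return;
    traj(out_i, 0) = tt;
    traj(out_i, 1) = E.vsp; traj(out_i, 2) = E.vdend; traj(out_i, 3) = E.vsoma;
    traj(out_i, 4) = E.ca; traj(out_i, 5) = E.buff;
    traj(out_i, 6) = E.ampa.now(5) + E.ampa.now(6) + E.ampa.now(7);
    traj(out_i, 7) = E.n2a.now(5) + E.n2a.now(6);
    traj(out_i, 8) = E.n2b.now(5) + E.n2b.now(6);
    traj(out_i, 9) = E.gabar.now(3) + E.gabar.now(4);
    traj(out_i, 10) = E.vgT.now(1); traj(out_i, 11) = E.vgR.now(1);
    traj(out_i, 12) = E.vgL.now(1) + E.vgL.now(2);
    traj(out_i, 13) = E.msk;
    traj(out_i, 14) = E.enz[1] + E.enz[2] + E.enz[3];
    double camkii = 0; for (int i = 7; i < 17; ++i) camkii += E.enz[i];
    traj(out_i, 15) = camkii;
    traj(out_i, 16) = E.enz[5];
    traj(out_i, 17) = E.actd; traj(out_i, 18) = E.actp;
    traj(out_i, 19) = E.chain.now(0); traj(out_i, 20) = E.chain.now(1);
    traj(out_i, 21) = E.chain.now(2);
    traj(out_i, 22) = E.lam; traj(out_i, 23) = E.lamage;
    out_i++;
  };
  record(0.0); next_out = output_dt;

  while (t < duration - 1e-12) {
    // apply due events
    while (ev_i < n_ev && events(ev_i, 0) <= t + 1e-12) {
      int code = (int)events(ev_i, 1);
      double val = events(ev_i, 2);
      if (code == 1) E.glu = std::max(0.0, E.glu + val);
      else if (code == 2) E.gaba_conc = std::max(0.0, E.gaba_conc + val);
      else if (code == 3) E.ibap = std::max(0.0, E.ibap + val);
      ev_i++;
    }
    // choose step size by regime
    double dt;
    if (t < stim_end + 1.0) {
      dt = dt_stim;
      while (pulse_lo < n_pulse && post_times[pulse_lo] + 0.05 < t) pulse_lo++;
      for (int i = pulse_lo; i < n_pulse; ++i) {
        if (post_times[i] > t) break;
        if (t >= post_times[i] && t < post_times[i] + 0.015) { dt = dt_ap; break; }
      }
    } else dt = dt_relax;
    // do not step across the next event or output time
    double t_stop = duration;
    if (ev_i < n_ev) t_stop = std::min(t_stop, events(ev_i, 0));
    if (next_out <= duration) t_stop = std::min(t_stop, next_out);
    dt = std::min(dt, t_stop - t);
    if (dt <= 0) { // land exactly on the boundary
      t = t_stop;
      if (std::fabs(t - next_out) < 1e-12) { record(t); next_out += output_dt; }
      continue;
    }
    E.step(dt);
    t += dt;
    if (E.ca > max_ca) max_ca = E.ca;
    if (E.vsp > max_vsp) max_vsp = E.vsp;
    if (record_peaks) {
      for (int i = pulse_lo; i < n_pulse; ++i) {
        if (post_times[i] > t) break;
        if (t <= post_times[i] + 0.05) {
          if (E.vsoma > peaks(i, 1)) peaks(i, 1) = E.vsoma;
          if (E.vdend > peaks(i, 2)) peaks(i, 2) = E.vdend;
          if (E.vsp > peaks(i, 3)) peaks(i, 3) = E.vsp;
        }
      }
    }
    while (next_out <= t + 1e-12 && out_i < n_out) {
      record(t); next_out += output_dt;
    }
    // conservation audit (cheap)
    if (std::fabs(E.chain.count_sum() - E.chain.total) > 1e-6 ||
        std::fabs(E.ampa.count_sum() - E.ampa.total) > 1e-6) conserved = false;
  }
  while (out_i < n_out) record(t);

  double weight = E.chain.now(1) - E.chain.now(2);
  return List::create(
    _["trajectory"] = traj,
    _["pulse_peaks"] = peaks,
    _["weight_change"] = weight,
    _["max_ca"] = max_ca,
    _["max_v_sp"] = max_vsp,
    _["neg_ca_events"] = E.neg_ca_events,
    _["counts_conserved"] = conserved,
    _["final_enzymes"] = NumericVector(E.enz, E.enz + 17),
    _["final_act"] = NumericVector::create(E.actd, E.actp),
    _["final_chain"] = NumericVector::create(E.chain.now(0), E.chain.now(1), E.chain.now(2))
  );
}

// ---------------------------------------------------------------------------
// exposed helpers for tests and deterministic analyses

// [[Rcpp::export]]
NumericMatrix cpp_channel_matrix(std::string channel, double glu, double v,
                                 List params) {
  ChannelConsts c = channel_consts(params);
  Pop pop;
  if (channel == "ampa") {
    ampa_scheme(pop); pop.init(16, 1, false);
    ampa_rates_fill(pop, c, glu);
  } else if (channel == "glun2a" || channel == "glun2b") {
    nmda_scheme(pop); pop.init(7, 1, false);
    nmda_rates_fill(pop, c, glu, channel == "glun2b");
  } else if (channel == "gaba") {
    gaba_scheme(pop); pop.init(5, 1, false);
    gaba_rates_fill(pop, c, glu);
  } else if (channel == "vgccL") {
    l_scheme(pop); pop.init(3, 1, false);
    l_rates_fill(pop, c, v);
  } else if (channel == "vgccT" || channel == "vgccR") {
    tr_scheme(pop); pop.init(4, 1, false);
    tr_rates_fill(pop, channel == "vgccT" ? t_gate_rates(v, c) : r_gate_rates(v, c));
  } else stop("unknown channel: %s", channel);
  NumericMatrix Q(pop.n, pop.n);
  for (size_t k = 0; k < pop.trs.size(); ++k)
    Q(pop.trs[k].from, pop.trs[k].to) += pop.rates[k];
  return Q;
}

// Simulate a single unit on an arbitrary rate matrix with the engine's jump
// sampler (frozen-rate steps of length dt); returns (state, dwell) sojourns.
// [[Rcpp::export]]
NumericMatrix cpp_dwell_times(NumericMatrix Q, int init, double t_end, double dt) {
  int n = Q.nrow();
  Pop pop;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && Q(i, j) > 0) pop.trs.push_back({i, j});
  pop.init(n, 1, false, init);
  for (size_t k = 0; k < pop.trs.size(); ++k)
    pop.rates[k] = Q(pop.trs[k].from, pop.trs[k].to);
  std::vector<double> st, dw;
  int cur = init; double dwell = 0.0, t = 0.0;
  while (t < t_end) {
    double step = std::min(dt, t_end - t);
    // replicate step_jump but tracking state changes
    double t0 = 0.0;
    for (;;) {
      double total = 0.0;
      for (size_t k = 0; k < pop.trs.size(); ++k)
        total += pop.cnt[pop.trs[k].from] * pop.rates[k];
      double tnext;
      if (total <= 0) tnext = step;
      else tnext = std::min(step, t0 + R::exp_rand() / total);
      dwell += tnext - t0;
      t0 = tnext;
      if (t0 >= step || total <= 0) break;
      double u = unif_rand() * total, acc = 0.0;
      for (size_t k = 0; k < pop.trs.size(); ++k) {
        acc += pop.cnt[pop.trs[k].from] * pop.rates[k];
        if (u < acc) {
          st.push_back(cur); dw.push_back(dwell);
          pop.cnt[pop.trs[k].from]--; pop.cnt[pop.trs[k].to]++;
          cur = pop.trs[k].to; dwell = 0.0;
          break;
        }
      }
    }
    t += step;
  }
  // append the final (right-censored) sojourn so the terminal state is known
  st.push_back(cur); dw.push_back(dwell);
  NumericMatrix out(st.size(), 2);
  for (size_t i = 0; i < st.size(); ++i) { out(i, 0) = st[i]; out(i, 1) = dw[i]; }
  colnames(out) = CharacterVector::create("state", "dwell");
  return out;
}

// [[Rcpp::export]]
List cpp_soma_rates(double v) {
  Engine E; // only the static rate helpers are used
  return List::create(
    _["alpha_m"] = E.alpha_m(v), _["beta_m"] = E.beta_m(v),
    _["alpha_h"] = E.alpha_h(v), _["beta_h"] = E.beta_h(v),
    _["n_inf"] = E.n_inf(v), _["n_tau"] = E.n_tau(v));
}

// [[Rcpp::export]]
double cpp_ghk_flux(double v, double cai, double cao, double temperature,
                    double p_ca) {
  return ghk_flux_c(v, cai, cao, temperature, p_ca);
}
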