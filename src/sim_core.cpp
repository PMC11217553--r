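// Fixed-step Euler core of the mass-balance plankton ecosystem model.
//
// State layout (concentrations, umol C L-1 unless noted):
//   phyto[P], het_active[H], het_dormant[H], dom[D], pom,
//   no3, nh4, po4, si (umol N/P/Si L-1), exported (cumulative respired C).
//
// Every carbon flux carries nitrogen and phosphorus at fixed quotas
// (biomass: Redfield; DOM species: per-species quotas <= biomass quotas);
// quota mismatches at organic-organic transfers are balanced against
// NH4/PO4, which is what makes heterotrophic remineralization emerge.
// Outflows from any pool are capped per step by proportional scaling so
// no pool can go negative; with that, the explicit Euler bookkeeping is
// exactly conservative and the producer-attribution ledger stays in sync
// with the pools it describes.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline double monod(double s, double k) {
  return (s > 0.0 && s + k > 0.0) ? s / (s + k) : 0.0;
}

inline double cap_factor(double stock, double demand, double dt) {
  if (demand <= 0.0) return 1.0;
  double need = demand * dt;
  return (need > stock) ? (stock > 0.0 ? stock / need : 0.0) : 1.0;
}

struct StepWork {
  // phytoplankton (per taxon)
  std::vector<double> Pfx, Ex, Rp, dd_p, dp_p;
  std::vector<double> fT_p, fI_p, fN_p, fP_p, fSi_p;
  std::vector<double> n_no3, n_nh4, n_po4, n_si;
  // heterotrophs (per taxon)
  std::vector<double> Utot, G, Rh, da, ddorm, dd_h, dp_h, trans;
  std::vector<double> fT_h, fS_h;
  std::vector<double> relN, relP; // net inorganic release (+) / draw (-)
  std::vector<double> U;          // H x D uptake, column-major [h + H*j]
  // pom
  double dis, sink;
  std::vector<double> dis_j;
  double Ptot;

  StepWork(int P, int H, int D)
      : Pfx(P), Ex(P), Rp(P), dd_p(P), dp_p(P), fT_p(P), fI_p(P), fN_p(P),
        fP_p(P), fSi_p(P), n_no3(P), n_nh4(P), n_po4(P), n_si(P), Utot(H),
        G(H), Rh(H), da(H), ddorm(H), dd_h(H), dp_h(H), trans(H), fT_h(H),
        fS_h(H), relN(H), relP(H), U(H * D), dis(0.0), dis_j(D), Ptot(0.0) {}
};

} // namespace

// Dimensions: phyto_par P x 15, phyto_alloc P x D, het_par H x 10,
// het_K H x D (<=0 means unusable), het_alloc H x D, pom_alloc D,
// stoich = (qn_bio, qp_bio, qsi_bio), dom_src0 D x (P+H+1), pom_src0 P+H+1.
// forcing rows are time-sorted with columns time, temp, par, daylength and
// the four loading rates (piecewise constant).
// [[Rcpp::export]]
List sim_core(NumericVector state0, NumericMatrix phyto_par,
              NumericMatrix phyto_alloc, NumericMatrix het_par,
              NumericMatrix het_K, NumericMatrix het_alloc,
              NumericVector pom_par, NumericVector pom_alloc, NumericVector dom_qn,
              NumericVector dom_qp, NumericVector stoich,
              NumericMatrix dom_src0, NumericVector pom_src0,
              NumericMatrix forcing, double t0, double t1, double dt,
              int out_every) {
  const int P = phyto_par.nrow();
  const int H = het_par.nrow();
  const int D = phyto_alloc.ncol();
  const int NPROD = P + H + 1; // producers + "background" for initial stocks
  const double qn = stoich[0], qp = stoich[1], qsi = stoich[2];
  const double pom_kdis = pom_par[0], pom_ksink = pom_par[1];

  // unpack state
  std::vector<double> phy(P), heta(H), hetd(H), dom(D);
  int off = 0;
  for (int i = 0; i < P; ++i) phy[i] = state0[off++];
  for (int h = 0; h < H; ++h) heta[h] = state0[off++];
  for (int h = 0; h < H; ++h) hetd[h] = state0[off++];
  for (int j = 0; j < D; ++j) dom[j] = state0[off++];
  double pom = state0[off++];
  double no3 = state0[off++], nh4 = state0[off++];
  double po4 = state0[off++], si = state0[off++];
  double exported = state0[off++];

  std::vector<double> dsrc(D * NPROD); // [j + D*p]
  for (int j = 0; j < D; ++j)
    for (int p = 0; p < NPROD; ++p) dsrc[j + D * p] = dom_src0(j, p);
  std::vector<double> psrc(NPROD);
  for (int p = 0; p < NPROD; ++p) psrc[p] = pom_src0[p];

  // heterotroph usable-substrate weights
  std::vector<double> w(H * D, 0.0);
  for (int h = 0; h < H; ++h) {
    int n_use = 0;
    for (int j = 0; j < D; ++j)
      if (het_K(h, j) > 0.0) ++n_use;
    if (n_use > 0)
      for (int j = 0; j < D; ++j)
        if (het_K(h, j) > 0.0) w[h + H * j] = 1.0 / n_use;
  }

  const int n_steps = (int)std::lround((t1 - t0) / dt);
  const int n_out = n_steps / out_every + 1;

  // outputs
  NumericVector o_time(n_out);
  NumericMatrix o_phy(n_out, P), o_heta(n_out, H), o_hetd(n_out, H),
      o_dom(n_out, D);
  NumericVector o_pom(n_out), o_no3(n_out), o_nh4(n_out), o_po4(n_out),
      o_si(n_out), o_exported(n_out);
  NumericVector o_dfrac(n_out * D * NPROD); // [t + n_out*(j + D*p)]
  NumericMatrix o_pfrac(n_out, NPROD);
  NumericVector o_uptake(n_out * H * D);    // [t + n_out*(h + H*j)]
  NumericMatrix o_photo(n_out, P), o_exud(n_out, P), o_resp_p(n_out, P),
      o_ddom_p(n_out, P), o_dpom_p(n_out, P);
  NumericMatrix o_upt(n_out, H), o_growth(n_out, H), o_resp_h(n_out, H),
      o_ddom_h(n_out, H), o_dpom_h(n_out, H);
  NumericVector o_dis(n_out), o_sink(n_out), o_remN(n_out), o_remP(n_out);
  NumericVector o_lim_p(n_out * P * 5); // [t + n_out*(i + P*k)]
  NumericVector o_lim_h(n_out * H * 2);
  NumericMatrix o_forc(n_out, 4); // temp, par, daylength, (interp) -- + spare

  StepWork wk(P, H, D);

  int f_idx = 0;
  const int n_forc = forcing.nrow();

  // closure: interpolate forcing at time t
  auto forcing_at = [&](double t, double &T, double &I, double &DL,
                        double &l1, double &l2, double &l3, double &l4) {
    while (f_idx + 1 < n_forc - 1 && forcing(f_idx + 1, 0) <= t) ++f_idx;
    while (f_idx > 0 && forcing(f_idx, 0) > t) --f_idx;
    int k = f_idx;
    double tk = forcing(k, 0);
    if (k + 1 < n_forc) {
      double tk1 = forcing(k + 1, 0);
      double a = (tk1 > tk) ? (t - tk) / (tk1 - tk) : 0.0;
      if (a < 0.0) a = 0.0;
      if (a > 1.0) a = 1.0;
      T = (1 - a) * forcing(k, 1) + a * forcing(k + 1, 1);
      I = (1 - a) * forcing(k, 2) + a * forcing(k + 1, 2);
      DL = (1 - a) * forcing(k, 3) + a * forcing(k + 1, 3);
    } else {
      T = forcing(k, 1); I = forcing(k, 2); DL = forcing(k, 3);
    }
    l1 = forcing(k, 4); l2 = forcing(k, 5); l3 = forcing(k, 6);
    l4 = forcing(k, 7); // loads piecewise-constant on [t_k, t_k+1)
  };

  // closure: compute all (capped, final) rates for the current state at t
  auto compute_rates = [&](double t) {
    double T, I, DL, ld_no3, ld_nh4, ld_po4, ld_si;
    forcing_at(t, T, I, DL, ld_no3, ld_nh4, ld_po4, ld_si);
    wk.Ptot = 0.0;
    double din = no3 + nh4;

    // --- phytoplankton gross photosynthesis (pre nutrient capping) ---
    for (int i = 0; i < P; ++i) {
      double q10 = phyto_par(i, 6), tref = phyto_par(i, 7);
      double fT = std::min(1.0, std::pow(q10, (T - tref) / 10.0));
      double fI = monod(I, phyto_par(i, 1)) * (DL / 24.0);
      double fN = monod(din, phyto_par(i, 2));
      double fP = monod(po4, phyto_par(i, 3));
      bool silic = phyto_par(i, 5) > 0.5;
      double fSi = silic ? monod(si, phyto_par(i, 4)) : 1.0;
      double fnut = std::min(fN, fP);
      if (silic) fnut = std::min(fnut, fSi);
      wk.fT_p[i] = fT; wk.fI_p[i] = fI; wk.fN_p[i] = fN; wk.fP_p[i] = fP;
      wk.fSi_p[i] = fSi;
      wk.Pfx[i] = phyto_par(i, 0) * fT * fI * fnut * phy[i];
    }

    // --- heterotroph uptake, capped by DOM stocks ---
    for (int h = 0; h < H; ++h) {
      double q10 = het_par(h, 2), tref = het_par(h, 3);
      wk.fT_h[h] = std::min(1.0, std::pow(q10, (T - tref) / 10.0));
      double fS = 0.0;
      for (int j = 0; j < D; ++j) {
        double wj = w[h + H * j];
        double m = (wj > 0.0) ? monod(dom[j], het_K(h, j)) : 0.0;
        fS += wj * m;
        wk.U[h + H * j] =
            het_par(h, 0) * wk.fT_h[h] * heta[h] * wj * m;
      }
      wk.fS_h[h] = fS;
    }
    for (int j = 0; j < D; ++j) {
      double dem = 0.0;
      for (int h = 0; h < H; ++h) dem += wk.U[h + H * j];
      double s = cap_factor(dom[j], dem, dt);
      if (s < 1.0)
        for (int h = 0; h < H; ++h) wk.U[h + H * j] *= s;
    }
    for (int h = 0; h < H; ++h) {
      double u = 0.0;
      for (int j = 0; j < D; ++j) u += wk.U[h + H * j];
      wk.Utot[h] = u;
      wk.G[h] = het_par(h, 1) * u;
    }

    // --- nutrient draw capping ---
    double frac_no3 = (din > 0.0) ? no3 / din : 0.0;
    double frac_nh4 = 1.0 - frac_no3;
    double D_no3 = 0.0, D_nh4 = 0.0, D_po4 = 0.0, D_si = 0.0;
    for (int i = 0; i < P; ++i) {
      double nd = qn * wk.Pfx[i];
      D_no3 += frac_no3 * nd;
      D_nh4 += frac_nh4 * nd;
      D_po4 += qp * wk.Pfx[i];
      if (phyto_par(i, 5) > 0.5) D_si += qsi * wk.Pfx[i];
    }
    std::vector<double> drawN(H), drawP(H);
    for (int h = 0; h < H; ++h) {
      double supN = 0.0, supP = 0.0;
      for (int j = 0; j < D; ++j) {
        supN += dom_qn[j] * wk.U[h + H * j];
        supP += dom_qp[j] * wk.U[h + H * j];
      }
      drawN[h] = std::max(0.0, qn * wk.G[h] - supN);
      drawP[h] = std::max(0.0, qp * wk.G[h] - supP);
      D_nh4 += drawN[h];
      D_po4 += drawP[h];
      wk.relN[h] = supN; // stash supplies, finalized below
      wk.relP[h] = supP;
    }
    double s_no3 = cap_factor(no3, D_no3, dt);
    double s_nh4 = cap_factor(nh4, D_nh4, dt);
    double s_po4 = cap_factor(po4, D_po4, dt);
    double s_si = cap_factor(si, D_si, dt);

    for (int i = 0; i < P; ++i) {
      double praw = wk.Pfx[i];
      double aN = frac_no3 * s_no3 + frac_nh4 * s_nh4;
      double s_i = std::min(std::min(aN, s_po4), 1.0);
      if (phyto_par(i, 5) > 0.5) s_i = std::min(s_i, s_si);
      wk.Pfx[i] = praw * s_i;
      double need = qn * wk.Pfx[i];
      double a_nh4 = frac_nh4 * qn * praw * s_nh4;
      wk.n_nh4[i] = std::min(a_nh4, need);
      wk.n_no3[i] = need - wk.n_nh4[i];
      wk.n_po4[i] = qp * wk.Pfx[i];
      wk.n_si[i] = (phyto_par(i, 5) > 0.5) ? qsi * wk.Pfx[i] : 0.0;
      wk.Ptot += wk.Pfx[i];
    }
    for (int h = 0; h < H; ++h) {
      double supN = wk.relN[h], supP = wk.relP[h];
      double g = wk.G[h];
      if (drawN[h] > 0.0)
        g = std::min(g, (supN + drawN[h] * s_nh4) / qn);
      if (drawP[h] > 0.0)
        g = std::min(g, (supP + drawP[h] * s_po4) / qp);
      wk.Rh[h] = wk.Utot[h] - g; // unassimilated carbon is respired
      wk.G[h] = g;
      wk.relN[h] = supN - qn * g; // + release to NH4, - draw from NH4
      wk.relP[h] = supP - qp * g;
    }

    // --- phytoplankton losses from final photosynthesis, pool-capped ---
    for (int i = 0; i < P; ++i) {
      double B = phy[i];
      double E = phyto_par(i, 8) * B + phyto_par(i, 9) * wk.Pfx[i];
      double R = phyto_par(i, 10) * B + phyto_par(i, 11) * wk.Pfx[i];
      double Dd = (phyto_par(i, 12) + phyto_par(i, 14) * B) * B;
      double s = cap_factor(B, E + R + Dd, dt);
      E *= s; R *= s; Dd *= s;
      wk.Ex[i] = E; wk.Rp[i] = R;
      wk.dd_p[i] = phyto_par(i, 13) * Dd;
      wk.dp_p[i] = Dd - wk.dd_p[i];
    }

    // --- heterotroph death and dormancy, pool-capped ---
    for (int h = 0; h < H; ++h) {
      double kd = het_par(h, 4) + het_par(h, 9) * heta[h];
      double mu_net = het_par(h, 1) * het_par(h, 0) * wk.fT_h[h] * wk.fS_h[h] - kd;
      double da = kd * heta[h];
      double dd = het_par(h, 4) * het_par(h, 8) * hetd[h];
      double tr = 0.0;
      if (mu_net < 0.0) tr = het_par(h, 6) * heta[h];       // active -> dormant
      else if (mu_net > 0.0) tr = -het_par(h, 7) * hetd[h]; // dormant -> active
      double s_a = cap_factor(heta[h], da + std::max(tr, 0.0), dt);
      da *= s_a;
      if (tr > 0.0) tr *= s_a;
      double s_d = cap_factor(hetd[h], dd + std::max(-tr, 0.0), dt);
      dd *= s_d;
      if (tr < 0.0) tr *= s_d;
      wk.da[h] = da; wk.ddorm[h] = dd; wk.trans[h] = tr;
      double dtot = da + dd;
      wk.dd_h[h] = het_par(h, 5) * dtot;
      wk.dp_h[h] = dtot - wk.dd_h[h];
    }

    // --- POM dissolution and sinking export ---
    double pout = (pom_kdis + pom_ksink) * pom;
    double s_pom = cap_factor(pom, pout, dt);
    wk.dis = pom_kdis * pom * s_pom;
    wk.sink = pom_ksink * pom * s_pom;
    for (int j = 0; j < D; ++j) wk.dis_j[j] = wk.dis * pom_alloc[j];
  };

  auto record = [&](int r, double t) {
    o_time[r] = t;
    double T, I, DL, l1, l2, l3, l4;
    forcing_at(t, T, I, DL, l1, l2, l3, l4);
    o_forc(r, 0) = T; o_forc(r, 1) = I; o_forc(r, 2) = DL; o_forc(r, 3) = 0.0;
    for (int i = 0; i < P; ++i) {
      o_phy(r, i) = phy[i];
      o_photo(r, i) = wk.Pfx[i]; o_exud(r, i) = wk.Ex[i];
      o_resp_p(r, i) = wk.Rp[i];
      o_ddom_p(r, i) = wk.dd_p[i]; o_dpom_p(r, i) = wk.dp_p[i];
      o_lim_p[r + n_out * (i + P * 0)] = wk.fT_p[i];
      o_lim_p[r + n_out * (i + P * 1)] = wk.fI_p[i];
      o_lim_p[r + n_out * (i + P * 2)] = wk.fN_p[i];
      o_lim_p[r + n_out * (i + P * 3)] = wk.fP_p[i];
      o_lim_p[r + n_out * (i + P * 4)] = wk.fSi_p[i];
    }
    double remN = 0.0, remP = 0.0;
    for (int h = 0; h < H; ++h) {
      o_heta(r, h) = heta[h]; o_hetd(r, h) = hetd[h];
      o_upt(r, h) = wk.Utot[h]; o_growth(r, h) = wk.G[h];
      o_resp_h(r, h) = wk.Rh[h];
      o_ddom_h(r, h) = wk.dd_h[h]; o_dpom_h(r, h) = wk.dp_h[h];
      o_lim_h[r + n_out * (h + H * 0)] = wk.fT_h[h];
      o_lim_h[r + n_out * (h + H * 1)] = wk.fS_h[h];
      remN += wk.relN[h]; remP += wk.relP[h];
      for (int j = 0; j < D; ++j)
        o_uptake[r + n_out * (h + H * j)] = wk.U[h + H * j];
    }
    o_remN[r] = remN; o_remP[r] = remP;
    for (int j = 0; j < D; ++j) {
      o_dom(r, j) = dom[j];
      double tot = 0.0;
      for (int p = 0; p < NPROD; ++p) tot += dsrc[j + D * p];
      for (int p = 0; p < NPROD; ++p)
        o_dfrac[r + n_out * (j + D * p)] =
            (tot > 0.0) ? dsrc[j + D * p] / tot : 0.0;
    }
    double ptot = 0.0;
    for (int p = 0; p < NPROD; ++p) ptot += psrc[p];
    for (int p = 0; p < NPROD; ++p)
      o_pfrac(r, p) = (ptot > 0.0) ? psrc[p] / ptot : 0.0;
    o_pom[r] = pom; o_no3[r] = no3; o_nh4[r] = nh4; o_po4[r] = po4;
    o_si[r] = si; o_exported[r] = exported;
    o_dis[r] = wk.dis; o_sink[r] = wk.sink;
  };

  // conservation diagnostics
  double max_imb_c = 0.0, max_imb_n = 0.0, max_imb_p = 0.0, max_imb_si = 0.0,
         max_ledger = 0.0;
  double exported_n = 0.0, exported_p = 0.0;
  auto total_c = [&]() {
    double s = exported + pom;
    for (int i = 0; i < P; ++i) s += phy[i];
    for (int h = 0; h < H; ++h) s += heta[h] + hetd[h];
    for (int j = 0; j < D; ++j) s += dom[j];
    return s;
  };
  auto total_n = [&]() {
    double b = 0.0;
    for (int i = 0; i < P; ++i) b += phy[i];
    for (int h = 0; h < H; ++h) b += heta[h] + hetd[h];
    double s = no3 + nh4 + qn * (b + pom) + exported_n;
    for (int j = 0; j < D; ++j) s += dom_qn[j] * dom[j];
    return s;
  };
  auto total_p = [&]() {
    double b = 0.0;
    for (int i = 0; i < P; ++i) b += phy[i];
    for (int h = 0; h < H; ++h) b += heta[h] + hetd[h];
    double s = po4 + qp * (b + pom) + exported_p;
    for (int j = 0; j < D; ++j) s += dom_qp[j] * dom[j];
    return s;
  };
  auto total_si = [&]() {
    double s = si;
    for (int i = 0; i < P; ++i)
      if (phyto_par(i, 5) > 0.5) s += qsi * phy[i];
    return s;
  };

  int rec = 0;
  bool bad = false;
  for (int step = 0; step < n_steps; ++step) {
    double t = t0 + step * dt;
    compute_rates(t);
    if (step % out_every == 0) record(rec++, t);

    double T, I, DL, ld_no3, ld_nh4, ld_po4, ld_si;
    forcing_at(t, T, I, DL, ld_no3, ld_nh4, ld_po4, ld_si);

    double c0 = total_c(), n0 = total_n(), p0 = total_p(), si0 = total_si();

    // --- ledger + DOM pools ---
    for (int j = 0; j < D; ++j) {
      double out_j = 0.0;
      for (int h = 0; h < H; ++h) out_j += wk.U[h + H * j];
      double pool_pre = dom[j];
      if (out_j > 0.0 && pool_pre > 0.0) {
        double f = out_j * dt / pool_pre;
        for (int p = 0; p < NPROD; ++p) dsrc[j + D * p] -= f * dsrc[j + D * p];
      }
      double in_j = 0.0;
      for (int i = 0; i < P; ++i) {
        double v = (wk.Ex[i] + wk.dd_p[i]) * phyto_alloc(i, j);
        dsrc[j + D * i] += v * dt;
        in_j += v;
      }
      for (int h = 0; h < H; ++h) {
        double v = wk.dd_h[h] * het_alloc(h, j);
        dsrc[j + D * (P + h)] += v * dt;
        in_j += v;
      }
      in_j += wk.dis_j[j];
      dom[j] += dt * (in_j - out_j);
    }
    // dissolution carries POM source fractions into the DOM ledger
    double ptot_pre = 0.0;
    for (int p = 0; p < NPROD; ++p) ptot_pre += psrc[p];
    if (wk.dis + wk.sink > 0.0 && ptot_pre > 0.0) {
      for (int p = 0; p < NPROD; ++p) {
        double share = psrc[p] / ptot_pre;
        for (int j = 0; j < D; ++j)
          dsrc[j + D * p] += wk.dis_j[j] * share * dt;
        psrc[p] -= (wk.dis + wk.sink) * share * dt;
      }
    }
    double pom_in = 0.0;
    for (int i = 0; i < P; ++i) {
      psrc[i] += wk.dp_p[i] * dt;
      pom_in += wk.dp_p[i];
    }
    for (int h = 0; h < H; ++h) {
      psrc[P + h] += wk.dp_h[h] * dt;
      pom_in += wk.dp_h[h];
    }
    pom += dt * (pom_in - wk.dis - wk.sink);
    exported += dt * wk.sink;
    exported_n += dt * qn * wk.sink;
    exported_p += dt * qp * wk.sink;

    // --- biomass pools ---
    double remN = 0.0, remP = 0.0, siRel = 0.0, resp = 0.0;
    for (int i = 0; i < P; ++i) {
      double loss = wk.Ex[i] + wk.Rp[i] + wk.dd_p[i] + wk.dp_p[i];
      phy[i] += dt * (wk.Pfx[i] - loss);
      resp += wk.Rp[i];
      // N/P released where DOM quota < biomass quota, plus respiration
      double relN_i = qn * wk.Rp[i], relP_i = qp * wk.Rp[i];
      for (int j = 0; j < D; ++j) {
        double v = (wk.Ex[i] + wk.dd_p[i]) * phyto_alloc(i, j);
        relN_i += (qn - dom_qn[j]) * v;
        relP_i += (qp - dom_qp[j]) * v;
      }
      remN += relN_i; remP += relP_i;
      if (phyto_par(i, 5) > 0.5) siRel += qsi * loss;
    }
    for (int h = 0; h < H; ++h) {
      double tr = wk.trans[h];
      heta[h] += dt * (wk.G[h] - wk.da[h] - std::max(tr, 0.0) + std::max(-tr, 0.0));
      hetd[h] += dt * (std::max(tr, 0.0) - std::max(-tr, 0.0) - wk.ddorm[h]);
      resp += wk.Rh[h];
      remN += wk.relN[h]; remP += wk.relP[h];
      for (int j = 0; j < D; ++j) {
        double v = wk.dd_h[h] * het_alloc(h, j);
        remN += (qn - dom_qn[j]) * v;
        remP += (qp - dom_qp[j]) * v;
      }
    }
    for (int j = 0; j < D; ++j) {
      remN += (qn - dom_qn[j]) * wk.dis_j[j];
      remP += (qp - dom_qp[j]) * wk.dis_j[j];
    }
    exported += dt * resp;

    // --- inorganic nutrients ---
    double drawNo3 = 0.0, drawNh4 = 0.0, drawPo4 = 0.0, drawSi = 0.0;
    for (int i = 0; i < P; ++i) {
      drawNo3 += wk.n_no3[i]; drawNh4 += wk.n_nh4[i];
      drawPo4 += wk.n_po4[i]; drawSi += wk.n_si[i];
    }
    no3 += dt * (ld_no3 - drawNo3);
    nh4 += dt * (ld_nh4 - drawNh4 + remN);
    po4 += dt * (ld_po4 - drawPo4 + remP);
    si += dt * (ld_si - drawSi + siRel);

    // --- diagnostics ---
    double scale_c = std::max(c0, 1.0);
    max_imb_c = std::max(max_imb_c,
                         std::fabs(total_c() - c0 - dt * wk.Ptot) / scale_c);
    max_imb_n = std::max(
        max_imb_n,
        std::fabs(total_n() - n0 - dt * (ld_no3 + ld_nh4)) / std::max(n0, 1.0));
    max_imb_p = std::max(max_imb_p, std::fabs(total_p() - p0 - dt * ld_po4) /
                                        std::max(p0, 1.0));
    max_imb_si = std::max(max_imb_si, std::fabs(total_si() - si0 - dt * ld_si) /
                                          std::max(si0, 1.0));
    for (int j = 0; j < D; ++j) {
      double tot = 0.0;
      for (int p = 0; p < NPROD; ++p) tot += dsrc[j + D * p];
      max_ledger = std::max(max_ledger,
                            std::fabs(tot - dom[j]) / std::max(dom[j], 1.0));
    }
    {
      double tot = 0.0;
      for (int p = 0; p < NPROD; ++p) tot += psrc[p];
      max_ledger =
          std::max(max_ledger, std::fabs(tot - pom) / std::max(pom, 1.0));
    }

    for (int i = 0; i < P; ++i)
      if (!(phy[i] >= -1e-12) || !std::isfinite(phy[i])) bad = true;
    for (int h = 0; h < H; ++h)
      if (!(heta[h] >= -1e-12) || !(hetd[h] >= -1e-12)) bad = true;
    for (int j = 0; j < D; ++j)
      if (!(dom[j] >= -1e-12) || !std::isfinite(dom[j])) bad = true;
    if (!(pom >= -1e-12) || !(no3 >= -1e-12) || !(nh4 >= -1e-12) ||
        !(po4 >= -1e-12) || !(si >= -1e-12))
      bad = true;
    if (bad)
      stop("numerical integrity error: negative or non-finite pool at t=%f",
           t + dt);
    // snap tiny negative round-off to zero
    for (int i = 0; i < P; ++i) if (phy[i] < 0) phy[i] = 0;
    for (int h = 0; h < H; ++h) {
      if (heta[h] < 0) heta[h] = 0;
      if (hetd[h] < 0) hetd[h] = 0;
    }
    for (int j = 0; j < D; ++j) if (dom[j] < 0) dom[j] = 0;
    if (pom < 0) pom = 0;
    if (no3 < 0) no3 = 0;
    if (nh4 < 0) nh4 = 0;
    if (po4 < 0) po4 = 0;
    if (si < 0) si = 0;
  }
  compute_rates(t1);
  record(rec, t1);

  // final state vector (same layout as state0)
  NumericVector fin(state0.size());
  off = 0;
  for (int i = 0; i < P; ++i) fin[off++] = phy[i];
  for (int h = 0; h < H; ++h) fin[off++] = heta[h];
  for (int h = 0; h < H; ++h) fin[off++] = hetd[h];
  for (int j = 0; j < D; ++j) fin[off++] = dom[j];
  fin[off++] = pom; fin[off++] = no3; fin[off++] = nh4;
  fin[off++] = po4; fin[off++] = si; fin[off++] = exported;

  NumericMatrix fin_dsrc(D, NPROD);
  for (int j = 0; j < D; ++j)
    for (int p = 0; p < NPROD; ++p) fin_dsrc(j, p) = dsrc[j + D * p];
  NumericVector fin_psrc(NPROD);
  for (int p = 0; p < NPROD; ++p) fin_psrc[p] = psrc[p];

  o_uptake.attr("dim") = IntegerVector::create(n_out, H, D);
  o_dfrac.attr("dim") = IntegerVector::create(n_out, D, NPROD);
  o_lim_p.attr("dim") = IntegerVector::create(n_out, P, 5);
  o_lim_h.attr("dim") = IntegerVector::create(n_out, H, 2);

  return List::create(
      _["time"] = o_time, _["phyto_c"] = o_phy, _["het_active_c"] = o_heta,
      _["het_dormant_c"] = o_hetd, _["dom_c"] = o_dom, _["pom_c"] = o_pom,
      _["no3"] = o_no3, _["nh4"] = o_nh4, _["po4"] = o_po4, _["si"] = o_si,
      _["exported_c"] = o_exported, _["dom_src_frac"] = o_dfrac,
      _["pom_src_frac"] = o_pfrac, _["uptake"] = o_uptake,
      _["photosynthesis"] = o_photo, _["exudation"] = o_exud,
      _["respiration_phyto"] = o_resp_p, _["death_dom_phyto"] = o_ddom_p,
      _["death_pom_phyto"] = o_dpom_p, _["uptake_total"] = o_upt,
      _["growth_het"] = o_growth, _["respiration_het"] = o_resp_h,
      _["death_dom_het"] = o_ddom_h, _["death_pom_het"] = o_dpom_h,
      _["dissolution"] = o_dis, _["sinking"] = o_sink,
      _["remin_nh4"] = o_remN,
      _["remin_po4"] = o_remP, _["lim_phyto"] = o_lim_p,
      _["lim_het"] = o_lim_h, _["forcing"] = o_forc,
      _["final_state"] = fin, _["final_dom_src"] = fin_dsrc,
      _["final_pom_src"] = fin_psrc,
      _["balance"] = NumericVector::create(
          _["carbon"] = max_imb_c, _["nitrogen"] = max_imb_n,
          _["phosphorus"] = max_imb_p, _["silicate"] = max_imb_si,
          _["ledger"] = max_ledger));
}
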