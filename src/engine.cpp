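// Replica-exchange Gibbs Monte Carlo engine over a compiled scoring plan.
// The plan (built in R by compile_plan) lists every restraint as index
// arrays; proposals are scored by local-energy deltas, with cached overlap
// sums for the Gaussian-mixture density term. Uses R's RNG throughout so a
// set.seed() in R makes runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

struct PosSpec {
  std::vector< std::vector<int> > groups; // candidate copies (bead sets)
  int type;                               // 0 = point, 1 = slab
  double tx, ty, tz, zmin, zmax, tol, k;
};

struct ProxPair {
  std::vector<int> A, B;
  double bound;
};

struct Plan {
  int n;
  std::vector<double> radius;
  // connectivity
  std::vector<int> conn_i, conn_j;
  std::vector<double> conn_thr;
  double conn_k, w_conn;
  std::vector< std::vector<int> > conn_by;
  // excluded volume (optionally with a rotation applied to bead j for
  // symmetry-neighbor pairs)
  std::vector<int> ev_i, ev_j;
  std::vector<double> ev_bound, ev_c, ev_s;
  std::vector<char> ev_rot;
  double ev_k, w_ev;
  std::vector< std::vector<int> > ev_by;
  // crosslinks: per link, candidate bead pairs (copy ambiguity)
  std::vector< std::vector< std::pair<int,int> > > xl;
  std::vector<double> xl_mult;
  double xl_cut, xl_k, w_xl;
  std::vector< std::vector<int> > xl_by;
  // positional
  std::vector<PosSpec> pos;
  double w_pos;
  std::vector< std::vector<int> > pos_by;
  // proximity
  std::vector<ProxPair> prox;
  double prox_k, w_prox;
  std::vector< std::vector<int> > prox_by;
  // equivalence
  std::vector<int> eq_i, eq_j;
  std::vector<double> eq_d;
  double eq_k, w_eq;
  std::vector< std::vector<int> > eq_by;
  // EM term
  bool has_em;
  double w_em, S_gg;
  std::vector<int> em_idx;       // bead index of each model component
  std::vector<int> bead2em;      // -1 if bead not in the model GMM
  int n_em, n_map;
  std::vector<double> map_x, map_y, map_z;
  std::vector<double> norm_fg, inv_fg;  // n_em x n_map
  std::vector<double> norm_ff, inv_ff;  // n_em x n_em
  // degrees of freedom
  std::vector<int> move_beads;
  std::vector< std::vector<int> > move_bodies;
  std::vector< std::vector<int> > move_chains;
};

static inline double harm_up(double d, double b, double k) {
  return d > b ? 0.5 * k * (d - b) * (d - b) : 0.0;
}
static inline double harm_lo(double d, double b, double k) {
  return d < b ? 0.5 * k * (b - d) * (b - d) : 0.0;
}
static inline double dist3(const double* x, int i, int j) {
  double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
         dz = x[3*i+2] - x[3*j+2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

static std::vector<int> asIdx0(SEXP v) {
  IntegerVector iv(v);
  std::vector<int> out(iv.size());
  for (int i = 0; i < iv.size(); ++i) out[i] = iv[i] - 1;
  return out;
}

static Plan build_plan(const List& plan) {
  Plan P;
  NumericVector rad = plan["radius"];
  P.n = rad.size();
  P.radius.assign(rad.begin(), rad.end());
  P.conn_by.resize(P.n); P.ev_by.resize(P.n); P.xl_by.resize(P.n);
  P.pos_by.resize(P.n); P.prox_by.resize(P.n); P.eq_by.resize(P.n);

  NumericMatrix conn = plan["conn"];
  P.conn_k = as<double>(plan["conn_k"]); P.w_conn = as<double>(plan["w_conn"]);
  for (int r = 0; r < conn.nrow(); ++r) {
    int i = (int)conn(r,0) - 1, j = (int)conn(r,1) - 1;
    P.conn_i.push_back(i); P.conn_j.push_back(j);
    P.conn_thr.push_back(conn(r,2));
    P.conn_by[i].push_back(r); P.conn_by[j].push_back(r);
  }
  NumericMatrix ev = plan["ev"];
  P.ev_k = as<double>(plan["ev_k"]); P.w_ev = as<double>(plan["w_ev"]);
  bool rot = ev.ncol() >= 5;
  for (int r = 0; r < ev.nrow(); ++r) {
    int i = (int)ev(r,0) - 1, j = (int)ev(r,1) - 1;
    P.ev_i.push_back(i); P.ev_j.push_back(j); P.ev_bound.push_back(ev(r,2));
    P.ev_c.push_back(rot ? ev(r,3) : 1.0);
    P.ev_s.push_back(rot ? ev(r,4) : 0.0);
    P.ev_rot.push_back(rot && (ev(r,3) != 1.0 || ev(r,4) != 0.0));
    P.ev_by[i].push_back(r); P.ev_by[j].push_back(r);
  }
  List xl = plan["xl"];
  NumericVector xm = plan["xl_mult"];
  P.xl_mult.assign(xm.begin(), xm.end());
  P.xl_cut = as<double>(plan["xl_cutoff"]);
  P.xl_k = as<double>(plan["xl_k"]); P.w_xl = as<double>(plan["w_xl"]);
  for (int l = 0; l < xl.size(); ++l) {
    IntegerMatrix pm = xl[l];
    std::vector< std::pair<int,int> > prs;
    std::vector<char> seen(P.n, 0);
    for (int r = 0; r < pm.nrow(); ++r) {
      int a = pm(r,0) - 1, b = pm(r,1) - 1;
      prs.push_back(std::make_pair(a, b));
      if (!seen[a]) { seen[a] = 1; P.xl_by[a].push_back(l); }
      if (!seen[b]) { seen[b] = 1; P.xl_by[b].push_back(l); }
    }
    P.xl.push_back(prs);
  }
  List pos = plan["pos"];
  P.w_pos = as<double>(plan["w_pos"]);
  for (int s = 0; s < pos.size(); ++s) {
    List sp = pos[s];
    PosSpec ps;
    List gr = sp["groups"];
    for (int g = 0; g < gr.size(); ++g) {
      std::vector<int> gi = asIdx0(gr[g]);
      for (size_t t = 0; t < gi.size(); ++t) P.pos_by[gi[t]].push_back(s);
      ps.groups.push_back(gi);
    }
    ps.type = as<int>(sp["type"]);
    NumericVector tg = sp["target"];
    ps.tx = tg[0]; ps.ty = tg[1]; ps.tz = tg[2];
    ps.zmin = as<double>(sp["zmin"]); ps.zmax = as<double>(sp["zmax"]);
    ps.tol = as<double>(sp["tol"]); ps.k = as<double>(sp["k"]);
    P.pos.push_back(ps);
  }
  List prox = plan["prox"];
  P.prox_k = as<double>(plan["prox_k"]); P.w_prox = as<double>(plan["w_prox"]);
  for (int s = 0; s < prox.size(); ++s) {
    List pp = prox[s];
    ProxPair q;
    q.A = asIdx0(pp["A"]); q.B = asIdx0(pp["B"]);
    q.bound = as<double>(pp["bound"]);
    for (size_t t = 0; t < q.A.size(); ++t) P.prox_by[q.A[t]].push_back(s);
    for (size_t t = 0; t < q.B.size(); ++t) P.prox_by[q.B[t]].push_back(s);
    P.prox.push_back(q);
  }
  NumericMatrix eq = plan["equiv"];
  P.eq_k = as<double>(plan["eq_k"]); P.w_eq = as<double>(plan["w_eq"]);
  for (int r = 0; r < eq.nrow(); ++r) {
    int i = (int)eq(r,0) - 1, j = (int)eq(r,1) - 1;
    P.eq_i.push_back(i); P.eq_j.push_back(j); P.eq_d.push_back(eq(r,2));
    P.eq_by[i].push_back(r); P.eq_by[j].push_back(r);
  }
  // EM
  P.has_em = as<bool>(plan["has_em"]);
  P.w_em = as<double>(plan["w_em"]);
  P.bead2em.assign(P.n, -1);
  if (P.has_em) {
    P.em_idx = asIdx0(plan["em_idx"]);
    P.n_em = P.em_idx.size();
    for (int c = 0; c < P.n_em; ++c) P.bead2em[P.em_idx[c]] = c;
    NumericVector mw = plan["em_model_w"], ms2 = plan["em_model_s2"];
    NumericMatrix mp = plan["map_mu"];
    NumericVector pw = plan["map_w"], ps2 = plan["map_s2"];
    P.n_map = pw.size();
    P.map_x.resize(P.n_map); P.map_y.resize(P.n_map); P.map_z.resize(P.n_map);
    for (int k2 = 0; k2 < P.n_map; ++k2) {
      P.map_x[k2] = mp(k2,0); P.map_y[k2] = mp(k2,1); P.map_z[k2] = mp(k2,2);
    }
    const double tau = 2.0 * M_PI;
    P.norm_fg.resize((size_t)P.n_em * P.n_map);
    P.inv_fg.resize((size_t)P.n_em * P.n_map);
    for (int i = 0; i < P.n_em; ++i)
      for (int k2 = 0; k2 < P.n_map; ++k2) {
        double s2 = ms2[i] + ps2[k2];
        P.norm_fg[(size_t)i*P.n_map + k2] =
          mw[i] * pw[k2] * std::pow(tau * s2, -1.5);
        P.inv_fg[(size_t)i*P.n_map + k2] = 1.0 / (2.0 * s2);
      }
    P.norm_ff.resize((size_t)P.n_em * P.n_em);
    P.inv_ff.resize((size_t)P.n_em * P.n_em);
    for (int i = 0; i < P.n_em; ++i)
      for (int j = 0; j < P.n_em; ++j) {
        double s2 = ms2[i] + ms2[j];
        P.norm_ff[(size_t)i*P.n_em + j] =
          mw[i] * mw[j] * std::pow(tau * s2, -1.5);
        P.inv_ff[(size_t)i*P.n_em + j] = 1.0 / (2.0 * s2);
      }
    // S_gg of the map
    double sgg = 0.0;
    for (int a = 0; a < P.n_map; ++a)
      for (int b = 0; b < P.n_map; ++b) {
        double s2 = ps2[a] + ps2[b];
        double dx = P.map_x[a]-P.map_x[b], dy = P.map_y[a]-P.map_y[b],
               dz = P.map_z[a]-P.map_z[b];
        sgg += pw[a] * pw[b] * std::pow(tau * s2, -1.5) *
          std::exp(-(dx*dx+dy*dy+dz*dz) / (2.0 * s2));
      }
    P.S_gg = sgg;
  } else { P.n_em = 0; P.n_map = 0; P.S_gg = 1.0; }
  // DOFs
  P.move_beads = asIdx0(plan["move_beads"]);
  List mb = plan["move_bodies"];
  for (int b = 0; b < mb.size(); ++b) P.move_bodies.push_back(asIdx0(mb[b]));
  if (plan.containsElementNamed("move_chains")) {
    List mc = plan["move_chains"];
    for (int c = 0; c < mc.size(); ++c)
      P.move_chains.push_back(asIdx0(mc[c]));
  }
  return P;
}

// ---- term evaluation -------------------------------------------------------

static double xl_pen(const Plan& P, const double* x, int l) {
  double best = R_PosInf;
  const std::vector< std::pair<int,int> >& prs = P.xl[l];
  for (size_t r = 0; r < prs.size(); ++r) {
    double d = dist3(x, prs[r].first, prs[r].second);
    if (d < best) best = d;
  }
  return harm_up(best, P.xl_cut, P.xl_k) * P.xl_mult[l];
}

static double pos_pen(const Plan& P, const double* x, int s) {
  const PosSpec& ps = P.pos[s];
  double best = R_PosInf;
  for (size_t g = 0; g < ps.groups.size(); ++g) {
    const std::vector<int>& gi = ps.groups[g];
    double cx = 0, cy = 0, cz = 0;
    for (size_t t = 0; t < gi.size(); ++t) {
      cx += x[3*gi[t]]; cy += x[3*gi[t]+1]; cz += x[3*gi[t]+2];
    }
    cx /= gi.size(); cy /= gi.size(); cz /= gi.size();
    double pen;
    if (ps.type == 0) {
      double dx = cx - ps.tx, dy = cy - ps.ty, dz = cz - ps.tz;
      pen = harm_up(std::sqrt(dx*dx+dy*dy+dz*dz), ps.tol, ps.k);
    } else {
      double dz = 0.0;
      if (cz < ps.zmin) dz = ps.zmin - cz;
      else if (cz > ps.zmax) dz = cz - ps.zmax;
      pen = 0.5 * ps.k * dz * dz;
    }
    if (pen < best) best = pen;
  }
  return best;
}

static double prox_pen(const Plan& P, const double* x, int s) {
  const ProxPair& q = P.prox[s];
  double best = R_PosInf;
  for (size_t a = 0; a < q.A.size(); ++a)
    for (size_t b = 0; b < q.B.size(); ++b) {
      double d = dist3(x, q.A[a], q.B[b]);
      if (d < best) best = d;
    }
  return harm_up(best, q.bound, P.prox_k);
}

static double ev_pen_row(const Plan& P, const double* x, int r) {
  int i = P.ev_i[r], j = P.ev_j[r];
  double jx = x[3*j], jy = x[3*j+1], jz = x[3*j+2];
  if (P.ev_rot[r]) {
    double c = P.ev_c[r], s = P.ev_s[r];
    double rx = c * jx - s * jy, ry = s * jx + c * jy;
    jx = rx; jy = ry;
  }
  double dx = x[3*i]-jx, dy = x[3*i+1]-jy, dz = x[3*i+2]-jz;
  return harm_lo(std::sqrt(dx*dx+dy*dy+dz*dz), P.ev_bound[r], P.ev_k);
}

// EM caches for one replica
struct EmCache {
  std::vector<double> ofg;  // n_em: per-component overlap with the map
  std::vector<double> off;  // n_em x n_em ordered-pair overlaps
  double S_fg, S_ff;
};

static void em_full(const Plan& P, const double* x, EmCache& C) {
  C.ofg.assign(P.n_em, 0.0);
  C.off.assign((size_t)P.n_em * P.n_em, 0.0);
  C.S_fg = 0.0; C.S_ff = 0.0;
  for (int i = 0; i < P.n_em; ++i) {
    int bi = P.em_idx[i];
    double xi = x[3*bi], yi = x[3*bi+1], zi = x[3*bi+2];
    double row = 0.0;
    for (int k2 = 0; k2 < P.n_map; ++k2) {
      double dx = xi-P.map_x[k2], dy = yi-P.map_y[k2], dz = zi-P.map_z[k2];
      row += P.norm_fg[(size_t)i*P.n_map+k2] *
        std::exp(-(dx*dx+dy*dy+dz*dz) * P.inv_fg[(size_t)i*P.n_map+k2]);
    }
    C.ofg[i] = row; C.S_fg += row;
  }
  for (int i = 0; i < P.n_em; ++i) {
    int bi = P.em_idx[i];
    for (int j = 0; j < P.n_em; ++j) {
      int bj = P.em_idx[j];
      double dx = x[3*bi]-x[3*bj], dy = x[3*bi+1]-x[3*bj+1],
             dz = x[3*bi+2]-x[3*bj+2];
      double v = P.norm_ff[(size_t)i*P.n_em+j] *
        std::exp(-(dx*dx+dy*dy+dz*dz) * P.inv_ff[(size_t)i*P.n_em+j]);
      C.off[(size_t)i*P.n_em+j] = v; C.S_ff += v;
    }
  }
}

static inline double em_energy(const Plan& P, const EmCache& C) {
  double cc = C.S_fg / std::sqrt(C.S_ff * P.S_gg);
  return P.w_em * (1.0 - cc);
}

// full energy with per-term breakdown (weighted)
static double full_energy(const Plan& P, const double* x, EmCache& C,
                          double* terms /* 7 */) {
  double t_xl = 0, t_pos = 0, t_prox = 0, t_conn = 0, t_ev = 0, t_eq = 0;
  for (size_t l = 0; l < P.xl.size(); ++l) t_xl += xl_pen(P, x, l);
  for (size_t s = 0; s < P.pos.size(); ++s) t_pos += pos_pen(P, x, s);
  for (size_t s = 0; s < P.prox.size(); ++s) t_prox += prox_pen(P, x, s);
  for (size_t r = 0; r < P.conn_i.size(); ++r)
    t_conn += harm_up(dist3(x, P.conn_i[r], P.conn_j[r]), P.conn_thr[r],
                      P.conn_k);
  for (size_t r = 0; r < P.ev_i.size(); ++r) t_ev += ev_pen_row(P, x, r);
  for (size_t r = 0; r < P.eq_i.size(); ++r)
    t_eq += 0.5 * P.eq_k *
      std::pow(dist3(x, P.eq_i[r], P.eq_j[r]) - P.eq_d[r], 2);
  double t_em = 0.0;
  if (P.has_em) { em_full(P, x, C); t_em = em_energy(P, C); }
  terms[0] = P.w_xl * t_xl; terms[1] = t_em; terms[2] = P.w_pos * t_pos;
  terms[3] = P.w_prox * t_prox; terms[4] = P.w_conn * t_conn;
  terms[5] = P.w_ev * t_ev; terms[6] = P.w_eq * t_eq;
  double tot = 0.0;
  for (int t = 0; t < 7; ++t) tot += terms[t];
  return tot;
}

// unique restraint items touched by a set of beads (for group moves)
struct GroupItems {
  std::vector<int> conn, ev, xl, pos, prox, eq;
};

static void collect_group(const Plan& P, const std::vector<int>& set,
                          GroupItems& G,
                          std::vector<char>& fc, std::vector<char>& fe,
                          std::vector<char>& fx, std::vector<char>& fp,
                          std::vector<char>& fr, std::vector<char>& fq) {
  G.conn.clear(); G.ev.clear(); G.xl.clear(); G.pos.clear();
  G.prox.clear(); G.eq.clear();
  for (size_t t = 0; t < set.size(); ++t) {
    int i = set[t];
    for (size_t u = 0; u < P.conn_by[i].size(); ++u) {
      int r = P.conn_by[i][u];
      if (!fc[r]) { fc[r] = 1; G.conn.push_back(r); }
    }
    for (size_t u = 0; u < P.ev_by[i].size(); ++u) {
      int r = P.ev_by[i][u];
      if (!fe[r]) { fe[r] = 1; G.ev.push_back(r); }
    }
    for (size_t u = 0; u < P.xl_by[i].size(); ++u) {
      int r = P.xl_by[i][u];
      if (!fx[r]) { fx[r] = 1; G.xl.push_back(r); }
    }
    for (size_t u = 0; u < P.pos_by[i].size(); ++u) {
      int r = P.pos_by[i][u];
      if (!fp[r]) { fp[r] = 1; G.pos.push_back(r); }
    }
    for (size_t u = 0; u < P.prox_by[i].size(); ++u) {
      int r = P.prox_by[i][u];
      if (!fr[r]) { fr[r] = 1; G.prox.push_back(r); }
    }
    for (size_t u = 0; u < P.eq_by[i].size(); ++u) {
      int r = P.eq_by[i][u];
      if (!fq[r]) { fq[r] = 1; G.eq.push_back(r); }
    }
  }
  for (size_t u = 0; u < G.conn.size(); ++u) fc[G.conn[u]] = 0;
  for (size_t u = 0; u < G.ev.size(); ++u) fe[G.ev[u]] = 0;
  for (size_t u = 0; u < G.xl.size(); ++u) fx[G.xl[u]] = 0;
  for (size_t u = 0; u < G.pos.size(); ++u) fp[G.pos[u]] = 0;
  for (size_t u = 0; u < G.prox.size(); ++u) fr[G.prox[u]] = 0;
  for (size_t u = 0; u < G.eq.size(); ++u) fq[G.eq[u]] = 0;
}

static double group_energy(const Plan& P, const double* x,
                           const GroupItems& G) {
  double e = 0.0;
  for (size_t u = 0; u < G.conn.size(); ++u) {
    int r = G.conn[u];
    e += P.w_conn * harm_up(dist3(x, P.conn_i[r], P.conn_j[r]),
                            P.conn_thr[r], P.conn_k);
  }
  for (size_t u = 0; u < G.ev.size(); ++u)
    e += P.w_ev * ev_pen_row(P, x, G.ev[u]);
  for (size_t u = 0; u < G.xl.size(); ++u)
    e += P.w_xl * xl_pen(P, x, G.xl[u]);
  for (size_t u = 0; u < G.pos.size(); ++u)
    e += P.w_pos * pos_pen(P, x, G.pos[u]);
  for (size_t u = 0; u < G.prox.size(); ++u)
    e += P.w_prox * prox_pen(P, x, G.prox[u]);
  for (size_t u = 0; u < G.eq.size(); ++u) {
    int r = G.eq[u];
    e += P.w_eq * 0.5 * P.eq_k *
      std::pow(dist3(x, P.eq_i[r], P.eq_j[r]) - P.eq_d[r], 2);
  }
  return e;
}

// local (non-EM) energy of every term touching bead i
static double local_energy(const Plan& P, const double* x, int i) {
  double e = 0.0;
  for (size_t t = 0; t < P.conn_by[i].size(); ++t) {
    int r = P.conn_by[i][t];
    e += P.w_conn * harm_up(dist3(x, P.conn_i[r], P.conn_j[r]),
                            P.conn_thr[r], P.conn_k);
  }
  for (size_t t = 0; t < P.ev_by[i].size(); ++t)
    e += P.w_ev * ev_pen_row(P, x, P.ev_by[i][t]);
  for (size_t t = 0; t < P.xl_by[i].size(); ++t)
    e += P.w_xl * xl_pen(P, x, P.xl_by[i][t]);
  for (size_t t = 0; t < P.pos_by[i].size(); ++t)
    e += P.w_pos * pos_pen(P, x, P.pos_by[i][t]);
  for (size_t t = 0; t < P.prox_by[i].size(); ++t)
    e += P.w_prox * prox_pen(P, x, P.prox_by[i][t]);
  for (size_t t = 0; t < P.eq_by[i].size(); ++t) {
    int r = P.eq_by[i][t];
    e += P.w_eq * 0.5 * P.eq_k *
      std::pow(dist3(x, P.eq_i[r], P.eq_j[r]) - P.eq_d[r], 2);
  }
  return e;
}

// [[Rcpp::export]]
List cpp_score(List plan, NumericMatrix coords) {
  Plan P = build_plan(plan);
  std::vector<double> x(3 * P.n);
  for (int i = 0; i < P.n; ++i) {
    x[3*i] = coords(i,0); x[3*i+1] = coords(i,1); x[3*i+2] = coords(i,2);
  }
  EmCache C;
  double terms[7];
  double tot = full_energy(P, x.data(), C, terms);
  NumericVector tv(7);
  for (int t = 0; t < 7; ++t) tv[t] = terms[t];
  tv.names() = CharacterVector::create("crosslink", "em", "positional",
                                       "proximity", "connectivity",
                                       "excluded_volume", "equivalence");
  return List::create(_["total"] = tot, _["terms"] = tv);
}

// one replica's mutable state
struct Rep {
  std::vector<double> x;
  double E;
  EmCache C;
};

// [[Rcpp::export]]
List cpp_run_rex(List plan, List starts, NumericVector temps,
                 int n_steps, int swap_interval, int frame_interval,
                 double bead_max_trans, double rb_max_rot_deg,
                 double rb_max_trans, double chain_max_trans = 0.0,
                 int resync_interval = 1000) {
  RNGScope scope;
  Plan P = build_plan(plan);
  int R = temps.size();
  if ((int)starts.size() != R) stop("one start configuration per replica");
  std::vector<Rep> reps(R);
  double terms[7];
  for (int r = 0; r < R; ++r) {
    NumericMatrix m = starts[r];
    reps[r].x.resize(3 * P.n);
    for (int i = 0; i < P.n; ++i) {
      reps[r].x[3*i] = m(i,0); reps[r].x[3*i+1] = m(i,1);
      reps[r].x[3*i+2] = m(i,2);
    }
    reps[r].E = full_energy(P, reps[r].x.data(), reps[r].C, terms);
    if (!R_finite(reps[r].E)) stop("non-finite starting score");
  }

  long bead_prop = 0, bead_acc = 0, body_prop = 0, body_acc = 0;
  long swap_prop = 0, swap_acc = 0;
  double max_drift = 0.0;
  std::vector<NumericMatrix> frames;
  std::vector<double> fr_scores;
  std::vector<int> fr_steps;
  std::vector< std::array<double,7> > fr_terms;
  std::vector<double> nfg(P.n_map > 0 ? P.n_map : 1);
  std::vector<double> nff(P.n_em > 0 ? P.n_em : 1);
  // group-move scratch
  GroupItems G;
  std::vector<char> fc(P.conn_i.size()), fe(P.ev_i.size()),
    fx(P.xl.size()), fp(P.pos.size()), fr(P.prox.size()),
    fq(P.eq_i.size());
  int max_group = 1;
  for (size_t c = 0; c < P.move_chains.size(); ++c)
    max_group = std::max(max_group, (int)P.move_chains[c].size());
  std::vector<char> moved_em(P.n_em > 0 ? P.n_em : 1, 0);
  std::vector<int> mv_list(max_group);
  std::vector<double> mv_fg(max_group);
  std::vector<double> mv_off((size_t)max_group *
                             (P.n_em > 0 ? P.n_em : 1));

  for (int step = 1; step <= n_steps; ++step) {
    for (int r = 0; r < R; ++r) {
      double T = temps[r];
      double scale = std::sqrt(T);
      double* x = reps[r].x.data();
      // rigid-body sweeps: propose, score by full recompute
      for (size_t b = 0; b < P.move_bodies.size(); ++b) {
        const std::vector<int>& bi = P.move_bodies[b];
        std::vector<double> saved(3 * bi.size());
        double cx = 0, cy = 0, cz = 0;
        for (size_t t = 0; t < bi.size(); ++t) {
          saved[3*t] = x[3*bi[t]]; saved[3*t+1] = x[3*bi[t]+1];
          saved[3*t+2] = x[3*bi[t]+2];
          cx += saved[3*t]; cy += saved[3*t+1]; cz += saved[3*t+2];
        }
        cx /= bi.size(); cy /= bi.size(); cz /= bi.size();
        double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
        double an = std::sqrt(ax*ax+ay*ay+az*az);
        ax /= an; ay /= an; az /= an;
        double th = unif_rand() * 2.0 - 1.0;
        th *= rb_max_rot_deg * M_PI / 180.0 * scale;
        double ct = std::cos(th), st = std::sin(th), omc = 1.0 - ct;
        double tx = (unif_rand()*2-1) * rb_max_trans * scale;
        double ty = (unif_rand()*2-1) * rb_max_trans * scale;
        double tz = (unif_rand()*2-1) * rb_max_trans * scale;
        for (size_t t = 0; t < bi.size(); ++t) {
          double px = saved[3*t]-cx, py = saved[3*t+1]-cy, pz = saved[3*t+2]-cz;
          double rx = px*(ct+ax*ax*omc) + py*(ax*ay*omc-az*st) +
                      pz*(ax*az*omc+ay*st);
          double ry = px*(ay*ax*omc+az*st) + py*(ct+ay*ay*omc) +
                      pz*(ay*az*omc-ax*st);
          double rz = px*(az*ax*omc-ay*st) + py*(az*ay*omc+ax*st) +
                      pz*(ct+az*az*omc);
          x[3*bi[t]] = cx + rx + tx; x[3*bi[t]+1] = cy + ry + ty;
          x[3*bi[t]+2] = cz + rz + tz;
        }
        EmCache Ct;
        double Enew = full_energy(P, x, Ct, terms);
        double dE = Enew - reps[r].E;
        ++body_prop;
        if (dE <= 0 || unif_rand() < std::exp(-dE / T)) {
          reps[r].E = Enew; reps[r].C = Ct; ++body_acc;
        } else {
          for (size_t t = 0; t < bi.size(); ++t) {
            x[3*bi[t]] = saved[3*t]; x[3*bi[t]+1] = saved[3*t+1];
            x[3*bi[t]+2] = saved[3*t+2];
          }
        }
      }
      // whole-chain translation proposals: rare large jumps across
      // ambiguity barriers; scored over the touched restraints only
      // (intra-chain geometry is invariant under the rigid translation)
      if (chain_max_trans > 0) {
        for (size_t c = 0; c < P.move_chains.size(); ++c) {
          const std::vector<int>& ci = P.move_chains[c];
          double tx = (unif_rand()*2-1) * chain_max_trans * scale;
          double ty = (unif_rand()*2-1) * chain_max_trans * scale;
          double tz = (unif_rand()*2-1) * chain_max_trans * scale;
          collect_group(P, ci, G, fc, fe, fx, fp, fr, fq);
          double e0 = group_energy(P, x, G);
          for (size_t t = 0; t < ci.size(); ++t) {
            x[3*ci[t]] += tx; x[3*ci[t]+1] += ty; x[3*ci[t]+2] += tz;
          }
          double e1 = group_energy(P, x, G);
          double dE = e1 - e0;
          double dfg = 0.0, dff = 0.0;
          int nmoved = 0;
          if (P.has_em) {
            EmCache& C = reps[r].C;
            double em0 = em_energy(P, C);
            for (size_t t = 0; t < ci.size(); ++t) {
              int cim = P.bead2em[ci[t]];
              if (cim >= 0) { moved_em[cim] = 1; mv_list[nmoved++] = cim; }
            }
            for (int t = 0; t < nmoved; ++t) {
              int i = mv_list[t];
              int bi = P.em_idx[i];
              double row = 0.0;
              for (int k2 = 0; k2 < P.n_map; ++k2) {
                double dx = x[3*bi]-P.map_x[k2], dy = x[3*bi+1]-P.map_y[k2],
                       dz = x[3*bi+2]-P.map_z[k2];
                double v = P.norm_fg[(size_t)i*P.n_map+k2] *
                  std::exp(-(dx*dx+dy*dy+dz*dz) *
                           P.inv_fg[(size_t)i*P.n_map+k2]);
                row += v;
              }
              mv_fg[t] = row;
              dfg += row - C.ofg[i];
              for (int j = 0; j < P.n_em; ++j) {
                if (moved_em[j]) { mv_off[(size_t)t*P.n_em+j] = NA_REAL;
                                   continue; }
                int bj = P.em_idx[j];
                double dx = x[3*bi]-x[3*bj], dy = x[3*bi+1]-x[3*bj+1],
                       dz = x[3*bi+2]-x[3*bj+2];
                double v = P.norm_ff[(size_t)i*P.n_em+j] *
                  std::exp(-(dx*dx+dy*dy+dz*dz) *
                           P.inv_ff[(size_t)i*P.n_em+j]);
                mv_off[(size_t)t*P.n_em+j] = v;
                dff += 2.0 * (v - C.off[(size_t)i*P.n_em+j]);
              }
            }
            double cc = (C.S_fg + dfg) / std::sqrt((C.S_ff + dff) * P.S_gg);
            dE += P.w_em * (1.0 - cc) - em0;
          }
          ++body_prop;
          if (dE <= 0 || unif_rand() < std::exp(-dE / T)) {
            reps[r].E += dE; ++body_acc;
            if (P.has_em && nmoved) {
              EmCache& C = reps[r].C;
              C.S_fg += dfg; C.S_ff += dff;
              for (int t = 0; t < nmoved; ++t) {
                int i = mv_list[t];
                C.ofg[i] = mv_fg[t];
                for (int j = 0; j < P.n_em; ++j) {
                  if (moved_em[j]) continue;
                  double v = mv_off[(size_t)t*P.n_em+j];
                  C.off[(size_t)i*P.n_em+j] = v;
                  C.off[(size_t)j*P.n_em+i] = v;
                }
              }
            }
          } else {
            for (size_t t = 0; t < ci.size(); ++t) {
              x[3*ci[t]] -= tx; x[3*ci[t]+1] -= ty; x[3*ci[t]+2] -= tz;
            }
          }
          for (int t = 0; t < nmoved; ++t) moved_em[mv_list[t]] = 0;
        }
      }
      // flexible-bead sweeps: local delta scoring
      for (size_t m = 0; m < P.move_beads.size(); ++m) {
        int i = P.move_beads[m];
        double ox = x[3*i], oy = x[3*i+1], oz = x[3*i+2];
        double e0 = local_energy(P, x, i);
        double dfg = 0.0, dff = 0.0;
        int ci = P.bead2em[i];
        x[3*i] = ox + (unif_rand()*2-1) * bead_max_trans * scale;
        x[3*i+1] = oy + (unif_rand()*2-1) * bead_max_trans * scale;
        x[3*i+2] = oz + (unif_rand()*2-1) * bead_max_trans * scale;
        double e1 = local_energy(P, x, i);
        double dE = e1 - e0;
        double em0 = 0.0, em1 = 0.0;
        if (P.has_em && ci >= 0) {
          EmCache& C = reps[r].C;
          em0 = em_energy(P, C);
          double newrow = 0.0;
          for (int k2 = 0; k2 < P.n_map; ++k2) {
            double dx = x[3*i]-P.map_x[k2], dy = x[3*i+1]-P.map_y[k2],
                   dz = x[3*i+2]-P.map_z[k2];
            nfg[k2] = P.norm_fg[(size_t)ci*P.n_map+k2] *
              std::exp(-(dx*dx+dy*dy+dz*dz) * P.inv_fg[(size_t)ci*P.n_map+k2]);
            newrow += nfg[k2];
          }
          dfg = newrow - C.ofg[ci];
          for (int j = 0; j < P.n_em; ++j) {
            if (j == ci) { nff[j] = C.off[(size_t)ci*P.n_em+ci]; continue; }
            int bj = P.em_idx[j];
            double dx = x[3*i]-x[3*bj], dy = x[3*i+1]-x[3*bj+1],
                   dz = x[3*i+2]-x[3*bj+2];
            nff[j] = P.norm_ff[(size_t)ci*P.n_em+j] *
              std::exp(-(dx*dx+dy*dy+dz*dz) * P.inv_ff[(size_t)ci*P.n_em+j]);
            dff += 2.0 * (nff[j] - C.off[(size_t)ci*P.n_em+j]);
          }
          double cc = (C.S_fg + dfg) / std::sqrt((C.S_ff + dff) * P.S_gg);
          em1 = P.w_em * (1.0 - cc);
          dE += em1 - em0;
        }
        ++bead_prop;
        if (dE <= 0 || unif_rand() < std::exp(-dE / T)) {
          reps[r].E += dE; ++bead_acc;
          if (P.has_em && ci >= 0) {
            EmCache& C = reps[r].C;
            C.S_fg += dfg; C.S_ff += dff;
            C.ofg[ci] += dfg;
            for (int j = 0; j < P.n_em; ++j) {
              C.off[(size_t)ci*P.n_em+j] = nff[j];
              C.off[(size_t)j*P.n_em+ci] = nff[j];
            }
          }
        } else {
          x[3*i] = ox; x[3*i+1] = oy; x[3*i+2] = oz;
        }
      }
    }
    // replica exchange between adjacent temperature slots
    if (swap_interval > 0 && step % swap_interval == 0 && R > 1) {
      int parity = (step / swap_interval) % 2;
      for (int a = parity; a + 1 < R; a += 2) {
        ++swap_prop;
        double db = 1.0 / temps[a] - 1.0 / temps[a+1];
        double de = reps[a].E - reps[a+1].E;
        if (db * de >= 0 || unif_rand() < std::exp(db * de)) {
          std::swap(reps[a].x, reps[a+1].x);
          std::swap(reps[a].E, reps[a+1].E);
          std::swap(reps[a].C, reps[a+1].C);
          ++swap_acc;
        }
      }
    }
    if (resync_interval > 0 && step % resync_interval == 0)
      for (int r = 0; r < R; ++r)
        reps[r].E = full_energy(P, reps[r].x.data(), reps[r].C, terms);
    if (frame_interval > 0 &&
        (step % frame_interval == 0 || step == n_steps)) {
      EmCache Ct;
      double tot = full_energy(P, reps[0].x.data(), Ct, terms);
      double drift = std::fabs(tot - reps[0].E) /
        std::max(1.0, std::fabs(tot));
      if (drift > max_drift) max_drift = drift;
      reps[0].E = tot; reps[0].C = Ct;
      NumericMatrix fm(P.n, 3);
      for (int i = 0; i < P.n; ++i) {
        fm(i,0) = reps[0].x[3*i]; fm(i,1) = reps[0].x[3*i+1];
        fm(i,2) = reps[0].x[3*i+2];
      }
      frames.push_back(fm);
      fr_scores.push_back(tot);
      fr_steps.push_back(step);
      std::array<double,7> ta;
      for (int t = 0; t < 7; ++t) ta[t] = terms[t];
      fr_terms.push_back(ta);
      if (!R_finite(tot)) stop("non-finite score during sampling");
    }
  }
  int F = frames.size();
  NumericMatrix tm(F, 7);
  for (int f = 0; f < F; ++f)
    for (int t = 0; t < 7; ++t) tm(f,t) = fr_terms[f][t];
  colnames(tm) = CharacterVector::create("crosslink", "em", "positional",
                                         "proximity", "connectivity",
                                         "excluded_volume", "equivalence");
  return List::create(
    _["frames"] = wrap(frames),
    _["scores"] = wrap(fr_scores),
    _["steps"] = wrap(fr_steps),
    _["terms"] = tm,
    _["accept"] = List::create(
      _["bead"] = bead_prop ? (double)bead_acc / bead_prop : NA_REAL,
      _["body"] = body_prop ? (double)body_acc / body_prop : NA_REAL,
      _["swap"] = swap_prop ? (double)swap_acc / swap_prop : NA_REAL),
    _["max_energy_drift"] = max_drift);
}
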