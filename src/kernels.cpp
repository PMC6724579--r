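#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pairwise nonbonded kernels for the desk energy backend, plus the
// deterministic sphere-sampling SASA integrator.  All distances in
// Angstrom, energies on a Rosetta-energy-unit-like scale.

static const double CUT = 6.0;      // nonbonded cutoff
static const double CUT_IN = 5.0;   // switching starts here
static const double COUL_K = 332.0637;
static const double LK_LAMBDA = 3.5;
static const double REP_CAP = 1.0e4; // per-pair clash cap keeps totals finite

// smooth cubic switch: 1 below CUT_IN, 0 above CUT
static inline double switch_fn(double r) {
  if (r <= CUT_IN) return 1.0;
  if (r >= CUT) return 0.0;
  double t = (CUT - r) / (CUT - CUT_IN);
  return t * t * (3.0 - 2.0 * t);
}

struct PairTerms {
  double atr, rep, sol, elec;
};

// 12-6 split at r_min (attractive branch flattened below the minimum),
// Lazaridis-Karplus-style gaussian exclusion solvation, Coulomb with
// distance-dependent dielectric eps(r) = r.
static inline void pair_terms(double r, double eps_ij, double rmin_ij,
                              double dg_i, double dg_j, double vol_i, double vol_j,
                              double lkr_i, double lkr_j,
                              double q_i, double q_j, PairTerms &out) {
  double s = switch_fn(r);
  double x = rmin_ij / r;
  double x6 = x * x * x;
  x6 = x6 * x6;
  double lj = eps_ij * (x6 * x6 - 2.0 * x6);
  if (r < rmin_ij) {
    out.atr = -eps_ij;
    double rep = lj + eps_ij;
    out.rep = rep > REP_CAP ? REP_CAP : rep;
  } else {
    out.atr = lj * s;
    out.rep = 0.0;
  }
  // solvation: desolvation of i by j and of j by i
  double di = (r - lkr_i) / LK_LAMBDA;
  double dj = (r - lkr_j) / LK_LAMBDA;
  double pre = 1.0 / (2.0 * M_PI * std::sqrt(M_PI) * LK_LAMBDA * r * r);
  double sol = pre * (dg_i * std::exp(-di * di) * vol_j +
                      dg_j * std::exp(-dj * dj) * vol_i);
  out.sol = sol * s;
  out.elec = (q_i != 0.0 && q_j != 0.0)
    ? COUL_K * q_i * q_j / (r * r) * s   // eps(r) = r
    : 0.0;
}

// neighbour sets from precomputed excluded-pair lists (path <= 3 bonds)
static std::vector<std::vector<int> > excl_sets(int n, const IntegerVector &ei,
                                                const IntegerVector &ej) {
  std::vector<std::vector<int> > near(n);
  for (int a = 0; a < n; ++a) near[a].push_back(a);
  for (int k = 0; k < ei.size(); ++k) {
    near[ei[k]].push_back(ej[k]);
    near[ej[k]].push_back(ei[k]);
  }
  for (int a = 0; a < n; ++a) std::sort(near[a].begin(), near[a].end());
  return near;
}

static inline bool excluded(const std::vector<std::vector<int> > &near, int i, int j) {
  const std::vector<int> &v = near[i];
  return std::binary_search(v.begin(), v.end(), j);
}

static inline double dist3(const NumericMatrix &xyz, int i, int j) {
  double dx = xyz(i, 0) - xyz(j, 0);
  double dy = xyz(i, 1) - xyz(j, 1);
  double dz = xyz(i, 2) - xyz(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline double angle_at(const NumericMatrix &xyz, int a, int b, int c) {
  // angle a-b-c in radians
  double v1x = xyz(a,0)-xyz(b,0), v1y = xyz(a,1)-xyz(b,1), v1z = xyz(a,2)-xyz(b,2);
  double v2x = xyz(c,0)-xyz(b,0), v2y = xyz(c,1)-xyz(b,1), v2z = xyz(c,2)-xyz(b,2);
  double n1 = std::sqrt(v1x*v1x+v1y*v1y+v1z*v1z);
  double n2 = std::sqrt(v2x*v2x+v2y*v2y+v2z*v2z);
  double cs = (v1x*v2x+v1y*v2y+v1z*v2z)/(n1*n2);
  if (cs > 1.0) cs = 1.0;
  if (cs < -1.0) cs = -1.0;
  return std::acos(cs);
}

// column order of the per-residue (atomic-level) terms
// 0 fa_atr 1 fa_rep 2 fa_sol 3 fa_intra_rep 4 fa_elec
// 5 hbond_sr_bb 6 hbond_lr_bb 7 hbond_bb_sc 8 hbond_sc

// [[Rcpp::export]]
List score_pairwise_cpp(NumericMatrix xyz,
                        NumericVector eps, NumericVector rmin2,
                        NumericVector dg, NumericVector vol, NumericVector lkr,
                        NumericVector charge,
                        IntegerVector res_of,     // 0-based residue index per atom
                        LogicalVector pep_atom,   // peptide membership per atom
                        IntegerVector excl_i, IntegerVector excl_j,
                        IntegerVector don, IntegerVector don_base, LogicalVector don_bb,
                        IntegerVector acc, IntegerVector acc_base, LogicalVector acc_bb,
                        IntegerVector res_chain,  // per residue
                        IntegerVector res_seq,    // per residue
                        int nres) {
  int n = xyz.nrow();
  std::vector<std::vector<int> > near = excl_sets(n, excl_i, excl_j);

  const char *tn[10] = {"fa_atr", "fa_rep", "fa_sol", "fa_intra_rep", "fa_intra_sol",
                        "fa_elec", "hbond_sr_bb", "hbond_lr_bb", "hbond_bb_sc", "hbond_sc"};
  NumericVector totals(10), pep_totals(10);
  totals.attr("names") = CharacterVector(tn, tn + 10);
  pep_totals.attr("names") = CharacterVector(tn, tn + 10);
  NumericMatrix per_res(nres, 9), per_res_pep(nres, 9);

  PairTerms pt;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double r = dist3(xyz, i, j);
      if (r >= CUT) continue;
      if (r < 0.5) r = 0.5; // guard against coincident atoms
      if (excluded(near, i, j)) continue;
      double eps_ij = std::sqrt(eps[i] * eps[j]);
      double rmin_ij = rmin2[i] + rmin2[j];
      pair_terms(r, eps_ij, rmin_ij, dg[i], dg[j], vol[i], vol[j],
                 lkr[i], lkr[j], charge[i], charge[j], pt);
      int ri = res_of[i], rj = res_of[j];
      bool intra = (ri == rj);
      bool pep_i = pep_atom[i], pep_j = pep_atom[j];
      bool any_pep = pep_i || pep_j;
      if (intra) {
        totals[3] += pt.rep;           // fa_intra_rep
        totals[4] += pt.sol;           // fa_intra_sol
        if (any_pep) { pep_totals[3] += pt.rep; pep_totals[4] += pt.sol; }
        per_res(ri, 3) += pt.rep;
        if (pep_i) per_res_pep(ri, 3) += pt.rep;
      } else {
        totals[0] += pt.atr; totals[1] += pt.rep; totals[2] += pt.sol; totals[5] += pt.elec;
        if (any_pep) {
          pep_totals[0] += pt.atr; pep_totals[1] += pt.rep;
          pep_totals[2] += pt.sol; pep_totals[5] += pt.elec;
        }
        per_res(ri, 0) += 0.5 * pt.atr; per_res(rj, 0) += 0.5 * pt.atr;
        per_res(ri, 1) += 0.5 * pt.rep; per_res(rj, 1) += 0.5 * pt.rep;
        per_res(ri, 2) += 0.5 * pt.sol; per_res(rj, 2) += 0.5 * pt.sol;
        per_res(ri, 4) += 0.5 * pt.elec; per_res(rj, 4) += 0.5 * pt.elec;
        // peptide attribution: cross pairs fully to the peptide residue,
        // intra-peptide pairs split half/half
        if (any_pep) {
          double wi = pep_i ? (pep_j ? 0.5 : 1.0) : 0.0;
          double wj = pep_j ? (pep_i ? 0.5 : 1.0) : 0.0;
          per_res_pep(ri, 0) += wi * pt.atr; per_res_pep(rj, 0) += wj * pt.atr;
          per_res_pep(ri, 1) += wi * pt.rep; per_res_pep(rj, 1) += wj * pt.rep;
          per_res_pep(ri, 2) += wi * pt.sol; per_res_pep(rj, 2) += wj * pt.sol;
          per_res_pep(ri, 4) += wi * pt.elec; per_res_pep(rj, 4) += wj * pt.elec;
        }
      }
    }
  }

  // hydrogen bonds over donor x acceptor heavy-atom lists
  for (int a = 0; a < don.size(); ++a) {
    int D = don[a], DB = don_base[a];
    for (int b = 0; b < acc.size(); ++b) {
      int A = acc[b], AB = acc_base[b];
      if (D == A || res_of[D] == res_of[A]) continue;
      if (excluded(near, D, A)) continue;
      double r = dist3(xyz, D, A);
      if (r < 2.4 || r > 3.6) continue;
      double g = std::exp(-std::pow((r - 2.9) / 0.35, 2.0));
      double fD = -std::cos(angle_at(xyz, DB, D, A));
      double fA = -std::cos(angle_at(xyz, AB, A, D));
      if (fD < 0.0) fD = 0.0;
      if (fA < 0.0) fA = 0.0;
      double e = -1.5 * g * fD * fA;
      if (e == 0.0) continue;
      int ri = res_of[D], rj = res_of[A];
      int cls;
      if (don_bb[a] && acc_bb[b]) {
        bool same_chain = res_chain[ri] == res_chain[rj];
        int sep = std::abs(res_seq[ri] - res_seq[rj]);
        cls = (same_chain && sep <= 4) ? 0 : 1;  // sr_bb : lr_bb
      } else if (!don_bb[a] && !acc_bb[b]) {
        cls = 3;                                  // sc
      } else {
        cls = 2;                                  // bb_sc
      }
      int tcol = 6 + cls;       // totals index
      int rcol = 5 + cls;       // per-res column
      totals[tcol] += e;
      bool pep_i = pep_atom[D], pep_j = pep_atom[A];
      if (pep_i || pep_j) pep_totals[tcol] += e;
      per_res(ri, rcol) += 0.5 * e; per_res(rj, rcol) += 0.5 * e;
      if (pep_i || pep_j) {
        double wi = pep_i ? (pep_j ? 0.5 : 1.0) : 0.0;
        double wj = pep_j ? (pep_i ? 0.5 : 1.0) : 0.0;
        per_res_pep(ri, rcol) += wi * e;
        per_res_pep(rj, rcol) += wj * e;
      }
    }
  }

  return List::create(_["totals"] = totals,
                      _["pep_totals"] = pep_totals,
                      _["per_res"] = per_res,
                      _["per_res_pep"] = per_res_pep);
}

// Interaction energy of pairs touching `sel` (0-based atom indices), for
// delta rescoring during refinement.  Returns the same 10 pairwise-term
// totals restricted to pairs with at least one member in sel, plus the
// hydrogen-bond terms involving sel.
// [[Rcpp::export]]
NumericVector score_subset_cpp(NumericMatrix xyz,
                               NumericVector eps, NumericVector rmin2,
                               NumericVector dg, NumericVector vol, NumericVector lkr,
                               NumericVector charge,
                               IntegerVector res_of, LogicalVector pep_atom,
                               IntegerVector excl_i, IntegerVector excl_j,
                               IntegerVector don, IntegerVector don_base, LogicalVector don_bb,
                               IntegerVector acc, IntegerVector acc_base, LogicalVector acc_bb,
                               IntegerVector res_chain, IntegerVector res_seq,
                               IntegerVector sel) {
  int n = xyz.nrow();
  std::vector<std::vector<int> > near = excl_sets(n, excl_i, excl_j);
  std::vector<bool> in_sel(n, false);
  for (int k = 0; k < sel.size(); ++k) in_sel[sel[k]] = true;

  const char *tn[10] = {"fa_atr", "fa_rep", "fa_sol", "fa_intra_rep", "fa_intra_sol",
                        "fa_elec", "hbond_sr_bb", "hbond_lr_bb", "hbond_bb_sc", "hbond_sc"};
  NumericVector totals(10);
  totals.attr("names") = CharacterVector(tn, tn + 10);

  PairTerms pt;
  for (int k = 0; k < sel.size(); ++k) {
    int i = sel[k];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (in_sel[j] && j < i) continue; // count sel-sel pairs once
      double r = dist3(xyz, i, j);
      if (r >= CUT) continue;
      if (r < 0.5) r = 0.5;
      if (excluded(near, i, j)) continue;
      double eps_ij = std::sqrt(eps[i] * eps[j]);
      double rmin_ij = rmin2[i] + rmin2[j];
      pair_terms(r, eps_ij, rmin_ij, dg[i], dg[j], vol[i], vol[j],
                 lkr[i], lkr[j], charge[i], charge[j], pt);
      if (res_of[i] == res_of[j]) {
        totals[3] += pt.rep; totals[4] += pt.sol;
      } else {
        totals[0] += pt.atr; totals[1] += pt.rep; totals[2] += pt.sol; totals[5] += pt.elec;
      }
    }
  }
  for (int a = 0; a < don.size(); ++a) {
    int D = don[a], DB = don_base[a];
    for (int b = 0; b < acc.size(); ++b) {
      int A = acc[b], AB = acc_base[b];
      if (!(in_sel[D] || in_sel[A])) continue;
      if (D == A || res_of[D] == res_of[A]) continue;
      if (excluded(near, D, A)) continue;
      double r = dist3(xyz, D, A);
      if (r < 2.4 || r > 3.6) continue;
      double g = std::exp(-std::pow((r - 2.9) / 0.35, 2.0));
      double fD = -std::cos(angle_at(xyz, DB, D, A));
      double fA = -std::cos(angle_at(xyz, AB, A, D));
      if (fD < 0.0) fD = 0.0;
      if (fA < 0.0) fA = 0.0;
      double e = -1.5 * g * fD * fA;
      if (e == 0.0) continue;
      int ri = res_of[D], rj = res_of[A];
      int cls;
      if (don_bb[a] && acc_bb[b]) {
        bool same_chain = res_chain[ri] == res_chain[rj];
        int sep = std::abs(res_seq[ri] - res_seq[rj]);
        cls = (same_chain && sep <= 4) ? 0 : 1;
      } else if (!don_bb[a] && !acc_bb[b]) {
        cls = 3;
      } else {
        cls = 2;
      }
      totals[6 + cls] += e;
    }
  }
  return totals;
}

// Deterministic golden-spiral SASA.  Returns per-atom accessible area (A^2).
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radius,
                       double probe, int n_points) {
  int n = xyz.nrow();
  // golden-spiral unit sphere points (fixed layout, no RNG)
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n_points;
    double rr = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    px[k] = rr * std::cos(th);
    py[k] = rr * std::sin(th);
    pz[k] = z;
  }
  NumericVector area(n);
  double maxr = 0.0;
  for (int i = 0; i < n; ++i) maxr = std::max(maxr, radius[i]);
  for (int i = 0; i < n; ++i) {
    double ri = radius[i] + probe;
    // neighbor list
    std::vector<int> nb;
    double cut = ri + maxr + probe;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dist3(xyz, i, j) < cut) nb.push_back(j);
    }
    int acc_pts = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = xyz(i, 0) + ri * px[k];
      double qy = xyz(i, 1) + ri * py[k];
      double qz = xyz(i, 2) + ri * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double rj = radius[j] + probe;
        double dx = qx - xyz(j, 0), dy = qy - xyz(j, 1), dz = qz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc_pts;
    }
    area[i] = 4.0 * M_PI * ri * ri * ((double)acc_pts / n_points);
  }
  return area;
}
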