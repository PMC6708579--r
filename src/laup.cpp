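#include <Rcpp.h>
using namespace Rcpp;

// Sankoff-style dynamic programme for the ancestral position of a single
// landmark on a rooted tree. States are candidate 3D (or 2D) positions per
// internal node; terminal positions are fixed to the observed coordinates.
// Inter-state costs are Euclidean distances, matching the spatial-parsimony
// criterion (displacements, not squared changes).

static double edist(const double *a, const double *b, int k) {
  double s = 0.0;
  for (int d = 0; d < k; ++d) {
    double diff = a[d] - b[d];
    s += diff * diff;
  }
  return std::sqrt(s);
}

// [[Rcpp::export]]
List laup_dp_landmark(NumericMatrix tip_xyz, List children, List cand,
                      IntegerVector postorder, int n_tip, int root) {
  int k = tip_xyz.ncol();
  int n_int = cand.size();
  std::vector<NumericMatrix> C(n_int);
  std::vector<std::vector<double> > cost(n_int);
  for (int i = 0; i < n_int; ++i) C[i] = as<NumericMatrix>(cand[i]);

  // forward pass (children before parents)
  for (int oi = 0; oi < postorder.size(); ++oi) {
    int node = postorder[oi];
    int ii = node - n_tip - 1;          // internal index, 0-based
    NumericMatrix ci = C[ii];
    int S = ci.nrow();
    std::vector<double> acc(S, 0.0);
    std::vector<double> pos_i(k);
    IntegerVector kids = as<IntegerVector>(children[ii]);
    for (int s = 0; s < S; ++s) {
      for (int d = 0; d < k; ++d) pos_i[d] = ci(s, d);
      double tot = 0.0;
      for (int c = 0; c < kids.size(); ++c) {
        int kid = kids[c];
        if (kid <= n_tip) {
          std::vector<double> tp(k);
          for (int d = 0; d < k; ++d) tp[d] = tip_xyz(kid - 1, d);
          tot += edist(&pos_i[0], &tp[0], k);
        } else {
          int jj = kid - n_tip - 1;
          NumericMatrix cj = C[jj];
          int Sj = cj.nrow();
          double best = R_PosInf;
          for (int t = 0; t < Sj; ++t) {
            std::vector<double> pj(k);
            for (int d = 0; d < k; ++d) pj[d] = cj(t, d);
            double v = cost[jj][t] + edist(&pos_i[0], &pj[0], k);
            if (v < best) best = v;
          }
          tot += best;
        }
      }
      acc[s] = tot;
    }
    cost[ii] = acc;
  }

  int ri = root - n_tip - 1;
  int Sr = C[ri].nrow();
  double best = R_PosInf;
  int bests = 0;
  for (int s = 0; s < Sr; ++s) {
    if (cost[ri][s] < best) { best = cost[ri][s]; bests = s; }
  }

  // backtrack (parents before children)
  IntegerVector choice(n_int, NA_INTEGER);
  choice[ri] = bests + 1;
  for (int oi = postorder.size() - 1; oi >= 0; --oi) {
    int node = postorder[oi];
    int ii = node - n_tip - 1;
    int sp = choice[ii] - 1;
    NumericMatrix ci = C[ii];
    std::vector<double> pos_p(k);
    for (int d = 0; d < k; ++d) pos_p[d] = ci(sp, d);
    IntegerVector kids = as<IntegerVector>(children[ii]);
    for (int c = 0; c < kids.size(); ++c) {
      int kid = kids[c];
      if (kid <= n_tip) continue;
      int jj = kid - n_tip - 1;
      NumericMatrix cj = C[jj];
      int Sj = cj.nrow();
      double bv = R_PosInf; int bt = 0;
      for (int t = 0; t < Sj; ++t) {
        std::vector<double> pj(k);
        for (int d = 0; d < k; ++d) pj[d] = cj(t, d);
        double v = cost[jj][t] + edist(&pos_p[0], &pj[0], k);
        if (v < bv) { bv = v; bt = t; }
      }
      choice[jj] = bt + 1;
    }
  }
  return List::create(_["score"] = best, _["choice"] = choice);
}
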