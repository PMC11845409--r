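#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Same-sign 4-connected components of supra-threshold pixels in a 2D map.
// Returns labels (0 = background) plus per-cluster summed statistic and the
// linear index of each cluster's peak (largest |t|).
// [[Rcpp::export]]
List grid_clusters_cpp(NumericMatrix t, double crit) {
  int nr = t.nrow(), nc = t.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<double> mass;
  std::vector<int> peak;
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) != 0 || std::abs(t(i, j)) <= crit) continue;
      ++next;
      int sgn = t(i, j) > 0 ? 1 : -1;
      double m = 0.0;
      int pk = i + j * nr;
      double pkv = 0.0;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        double v = t(ci, cj);
        m += v;
        if (std::abs(v) > pkv) { pkv = std::abs(v); pk = idx; }
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (lab(ni, nj) != 0) continue;
          double nv = t(ni, nj);
          if (std::abs(nv) <= crit) continue;
          if ((nv > 0 ? 1 : -1) != sgn) continue;
          lab(ni, nj) = next;
          stack.push_back(ni + nj * nr);
        }
      }
      mass.push_back(m);
      peak.push_back(pk + 1);  // 1-based for R
    }
  }
  return List::create(_["labels"] = lab, _["mass"] = wrap(mass),
                      _["peak_idx"] = wrap(peak));
}

// Fast path for permutations: maximum |cluster mass| only.
// [[Rcpp::export]]
double grid_max_mass_cpp(NumericMatrix t, double crit) {
  int nr = t.nrow(), nc = t.ncol();
  std::vector<int> lab(nr * nc, 0);
  std::vector<int> stack;
  double best = 0.0;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int idx0 = i + j * nr;
      if (lab[idx0] != 0 || std::abs(t(i, j)) <= crit) continue;
      ++next;
      int sgn = t(i, j) > 0 ? 1 : -1;
      double m = 0.0;
      stack.clear();
      stack.push_back(idx0);
      lab[idx0] = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        m += t(ci, cj);
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          int nidx = ni + nj * nr;
          if (lab[nidx] != 0) continue;
          double nv = t(ni, nj);
          if (std::abs(nv) <= crit) continue;
          if ((nv > 0 ? 1 : -1) != sgn) continue;
          lab[nidx] = next;
          stack.push_back(nidx);
        }
      }
      if (std::abs(m) > best) best = std::abs(m);
    }
  }
  return best;
}

// Same-sign connected components on an arbitrary graph (adjacency given as
// a list of 1-based integer vectors, one per node).
// [[Rcpp::export]]
List graph_clusters_cpp(NumericVector t, double crit, List adj) {
  int n = t.size();
  IntegerVector lab(n, 0);
  std::vector<double> mass;
  std::vector<int> peak;
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (lab[s] != 0 || std::abs(t[s]) <= crit) continue;
    ++next;
    int sgn = t[s] > 0 ? 1 : -1;
    double m = 0.0, pkv = 0.0;
    int pk = s;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      m += t[u];
      if (std::abs(t[u]) > pkv) { pkv = std::abs(t[u]); pk = u; }
      IntegerVector nb = adj[u];
      for (int k = 0; k < nb.size(); ++k) {
        int v = nb[k] - 1;
        if (v < 0 || v >= n || lab[v] != 0) continue;
        if (std::abs(t[v]) <= crit) continue;
        if ((t[v] > 0 ? 1 : -1) != sgn) continue;
        lab[v] = next;
        stack.push_back(v);
      }
    }
    mass.push_back(m);
    peak.push_back(pk + 1);
  }
  return List::create(_["labels"] = lab, _["mass"] = wrap(mass),
                      _["peak_idx"] = wrap(peak));
}

// [[Rcpp::export]]
double graph_max_mass_cpp(NumericVector t, double crit, List adj) {
  List res = graph_clusters_cpp(t, crit, adj);
  NumericVector mass = res["mass"];
  double best = 0.0;
  for (int i = 0; i < mass.size(); ++i)
    if (std::abs(mass[i]) > best) best = std::abs(mass[i]);
  return best;
}
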