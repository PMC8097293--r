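// Counts-only most-parsimonious reconciliation, used in the ABC loop
// where only the event multiset of the unit-cost reconciliation is
// needed. Mirrors the R implementation of reconcile() (same DP, same
// tie-breaks); their agreement is asserted in the test suite.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct DP {
  int E, nTip, nNode;
  const IntegerVector *pendant, *descPtr, *descIdx, *descSteps, *tipHostEdge;
  const IntegerMatrix *daughters, *kids;
  const LogicalMatrix *allowedSwitch;
  double cCo, cDu, cSw, cLo;
  std::vector<double> C, INC;       // nNode x E, row-major
  std::vector<int> kidA, kidB;      // per node, -1 for tips
  double cnt[4];                    // cospec, dup, switch, loss

  double &Cv(int v, int e) { return C[(size_t)v * E + e]; }
  double &Iv(int v, int e) { return INC[(size_t)v * E + e]; }

  void computeInc(int v) {
    for (int e = 0; e < E; ++e) {
      double best = INF;
      for (int k = (*descPtr)[e]; k < (*descPtr)[e + 1]; ++k) {
        double val = Cv(v, (*descIdx)[k]) + cLo * (*descSteps)[k];
        if (val < best) best = val;
      }
      Iv(v, e) = best;
    }
  }

  void fill() {
    for (int r = 0; r < kids->nrow(); ++r) {
      // tips appear implicitly: process any tip children first
      int v = (*kids)(r, 0), a = (*kids)(r, 1), b = (*kids)(r, 2);
      kidA[v] = a; kidB[v] = b;
    }
  }

  std::pair<int, int> resolveInc(int v, int e) {
    // landing edge realising INC[v, e]: fewest losses, lowest edge id
    double best = Iv(v, e);
    int bestEdge = -1, bestSteps = 0;
    for (int k = (*descPtr)[e]; k < (*descPtr)[e + 1]; ++k) {
      double val = Cv(v, (*descIdx)[k]) + cLo * (*descSteps)[k];
      if (val <= best + 1e-9) {
        int st = (*descSteps)[k], ed = (*descIdx)[k];
        if (bestEdge < 0 || st < bestSteps ||
            (st == bestSteps && ed < bestEdge)) {
          bestEdge = ed; bestSteps = st;
        }
      }
    }
    return std::make_pair(bestEdge, bestSteps);
  }

  bool assign(int v, int e) {
    if (v < nTip) return true;
    int a = kidA[v], b = kidB[v];
    double val = Cv(v, e);
    if (!(*pendant)[e] && (*daughters)(e, 0) >= 0) {
      int d1 = (*daughters)(e, 0), d2 = (*daughters)(e, 1);
      int ords[2][2] = {{d1, d2}, {d2, d1}};
      for (int o = 0; o < 2; ++o) {
        if (cCo + Iv(a, ords[o][0]) + Iv(b, ords[o][1]) <= val + 1e-9) {
          cnt[0] += 1;
          auto ra = resolveInc(a, ords[o][0]);
          auto rb = resolveInc(b, ords[o][1]);
          cnt[3] += ra.second + rb.second;
          return assign(a, ra.first) && assign(b, rb.first);
        }
      }
    }
    if (cDu + Iv(a, e) + Iv(b, e) <= val + 1e-9) {
      cnt[1] += 1;
      auto ra = resolveInc(a, e);
      auto rb = resolveInc(b, e);
      cnt[3] += ra.second + rb.second;
      return assign(a, ra.first) && assign(b, rb.first);
    }
    int stay[2] = {a, b}, move[2] = {b, a};
    for (int o = 0; o < 2; ++o) {
      for (int f = 0; f < E; ++f) {
        if (!(*allowedSwitch)(e, f)) continue;
        if (cSw + Iv(stay[o], e) + Iv(move[o], f) <= val + 1e-9) {
          cnt[2] += 1;
          auto rs = resolveInc(stay[o], e);
          auto rm = resolveInc(move[o], f);
          cnt[3] += rs.second + rm.second;
          return assign(stay[o], rs.first) && assign(move[o], rm.first);
        }
      }
    }
    return false;
  }
};

// [[Rcpp::export]]
NumericVector cpp_reconcile_counts(int E, IntegerVector pendant,
                                   IntegerMatrix daughters,
                                   IntegerVector descPtr,
                                   IntegerVector descIdx,
                                   IntegerVector descSteps,
                                   LogicalMatrix allowedSwitch, int nTip,
                                   int nNode, IntegerMatrix kids,
                                   IntegerVector tipHostEdge,
                                   NumericVector costs) {
  DP dp;
  dp.E = E; dp.nTip = nTip; dp.nNode = nNode;
  dp.pendant = &pendant; dp.daughters = &daughters; dp.descPtr = &descPtr;
  dp.descIdx = &descIdx; dp.descSteps = &descSteps;
  dp.allowedSwitch = &allowedSwitch; dp.kids = &kids;
  dp.tipHostEdge = &tipHostEdge;
  dp.cCo = costs[0]; dp.cDu = costs[1]; dp.cLo = costs[3];
  double maxFinite = 0;
  for (int i = 0; i < 4; ++i)
    if (std::isfinite(costs[i]) && costs[i] > maxFinite)
      maxFinite = costs[i];
  dp.cSw = costs[2] + 1e-9 * (1 + maxFinite);   // fewer-switches tie-break
  dp.C.assign((size_t)nNode * E, INF);
  dp.INC.assign((size_t)nNode * E, INF);
  dp.kidA.assign(nNode, -1); dp.kidB.assign(nNode, -1);
  dp.cnt[0] = dp.cnt[1] = dp.cnt[2] = dp.cnt[3] = 0;
  dp.fill();

  // tips
  for (int t = 0; t < nTip; ++t) {
    dp.Cv(t, tipHostEdge[t]) = 0;
    dp.computeInc(t);
  }
  // internal nodes in postorder (kids rows are postorder)
  std::vector<double> swA(E), swB(E);
  for (int r = 0; r < kids.nrow(); ++r) {
    int v = kids(r, 0), a = kids(r, 1), b = kids(r, 2);
    for (int e = 0; e < E; ++e) {
      double bestA = INF, bestB = INF;
      for (int f = 0; f < E; ++f) {
        if (!allowedSwitch(e, f)) continue;
        if (dp.Iv(a, f) < bestA) bestA = dp.Iv(a, f);
        if (dp.Iv(b, f) < bestB) bestB = dp.Iv(b, f);
      }
      swA[e] = bestA; swB[e] = bestB;
    }
    for (int e = 0; e < E; ++e) {
      double cand = INF;
      if (!pendant[e] && daughters(e, 0) >= 0) {
        int d1 = daughters(e, 0), d2 = daughters(e, 1);
        double co = dp.cCo + std::min(dp.Iv(a, d1) + dp.Iv(b, d2),
                                      dp.Iv(a, d2) + dp.Iv(b, d1));
        if (co < cand) cand = co;
      }
      double du = dp.cDu + dp.Iv(a, e) + dp.Iv(b, e);
      if (du < cand) cand = du;
      double sw = dp.cSw + std::min(dp.Iv(a, e) + swB[e],
                                    dp.Iv(b, e) + swA[e]);
      if (sw < cand) cand = sw;
      dp.Cv(v, e) = cand;
    }
    dp.computeInc(v);
  }
  int root = nTip;   // ape convention: first internal node
  double total = INF;
  int rootEdge = -1;
  for (int e = 0; e < E; ++e)
    if (dp.Cv(root, e) < total) { total = dp.Cv(root, e); rootEdge = e; }
  NumericVector out(6);
  if (!std::isfinite(total)) {
    out[0] = NA_REAL;
    return out;
  }
  // lowest edge id among optima
  for (int e = 0; e < E; ++e)
    if (dp.Cv(root, e) <= total + 1e-9) { rootEdge = e; break; }
  if (!dp.assign(root, rootEdge)) {
    out[0] = NA_REAL;
    return out;
  }
  double totalTrue = 0;
  for (int i = 0; i < 4; ++i)
    if (dp.cnt[i] > 0) totalTrue += dp.cnt[i] * costs[i];
  out[0] = totalTrue;
  out[1] = dp.cnt[0]; out[2] = dp.cnt[1]; out[3] = dp.cnt[2];
  out[4] = dp.cnt[3];
  out[5] = total;
  return out;
}
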