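#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Minimum-free-energy RNA secondary structure under a reduced
// nearest-neighbour model: Watson-Crick + G:U pairs, stacking energies,
// size-dependent hairpin/bulge/internal-loop penalties with a capped
// asymmetry term, and an affine multiloop cost. No pseudoknots, no
// dangles, no coaxial stacking. All arithmetic in integer tenths of a
// kcal/mol so that equality against the enumeration oracle is exact.

static const int INF = 100000000;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': case 'T': return 3;
    default: return -1;
  }
}

// pair order must match fold_params(): AU, CG, GC, UA, GU, UG
static inline int pair_idx(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 3 && b == 0) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct FoldParams {
  int stack[6][6];
  std::vector<int> hairpin, bulge, internal_;
  int asym_coef, asym_max, ml_close, ml_branch, ml_unpaired;
  int max_interior, min_loop;
};

static inline int to_tenth(double x) {
  return (int)std::lround(x * 10.0);
}

static int interior_energy(const FoldParams &P, int pij, int pkl,
                           int n1, int n2) {
  if (n1 == 0 && n2 == 0) return P.stack[pij][pkl];
  int n = n1 + n2;
  if (n1 == 0 || n2 == 0) {
    if (n >= (int)P.bulge.size()) return INF;
    return P.bulge[n];
  }
  if (n >= (int)P.internal_.size()) return INF;
  int asym = P.asym_coef * std::abs(n1 - n2);
  if (asym > P.asym_max) asym = P.asym_max;
  return P.internal_[n] + asym;
}

// [[Rcpp::export(name = ".fold_engine")]]
List fold_engine(std::string seq, List params) {
  int n = seq.size();
  if (n == 0) stop("empty sequence");
  std::vector<int> s(n);
  for (int i = 0; i < n; i++) {
    s[i] = base_code(seq[i]);
    if (s[i] < 0)
      stop("non-ACGU symbol '%s' at position %d", std::string(1, seq[i]), i + 1);
  }

  FoldParams P;
  NumericMatrix st = params["stack"];
  for (int a = 0; a < 6; a++)
    for (int b = 0; b < 6; b++) P.stack[a][b] = to_tenth(st(a, b));
  NumericVector hp = params["hairpin"], bu = params["bulge"],
                il = params["internal"];
  P.hairpin.assign(hp.size() + 1, INF);
  for (int k = 0; k < hp.size(); k++)
    P.hairpin[k + 1] = R_finite(hp[k]) ? to_tenth(hp[k]) : INF;
  P.bulge.assign(bu.size() + 1, INF);
  for (int k = 0; k < bu.size(); k++)
    P.bulge[k + 1] = R_finite(bu[k]) ? to_tenth(bu[k]) : INF;
  P.internal_.assign(il.size() + 1, INF);
  for (int k = 0; k < il.size(); k++)
    P.internal_[k + 1] = R_finite(il[k]) ? to_tenth(il[k]) : INF;
  P.asym_coef = to_tenth(as<double>(params["asym_coef"]));
  P.asym_max = to_tenth(as<double>(params["asym_max"]));
  P.ml_close = to_tenth(as<double>(params["ml_close"]));
  P.ml_branch = to_tenth(as<double>(params["ml_branch"]));
  P.ml_unpaired = to_tenth(as<double>(params["ml_unpaired"]));
  P.max_interior = as<int>(params["max_interior"]);
  P.min_loop = as<int>(params["min_loop"]);
  if ((int)P.hairpin.size() <= n) P.hairpin.resize(n + 1, INF);

  std::vector<std::vector<int>> V(n, std::vector<int>(n, INF));
  std::vector<std::vector<int>> WM(n, std::vector<int>(n, INF));

  for (int span = P.min_loop + 1; span < n; span++) {
    for (int i = 0; i + span < n; i++) {
      int j = i + span;
      int pij = pair_idx(s[i], s[j]);
      if (pij >= 0) {
        int best = INF;
        // hairpin closure
        int hsize = j - i - 1;
        if (hsize >= P.min_loop && hsize < (int)P.hairpin.size() &&
            P.hairpin[hsize] < INF)
          best = P.hairpin[hsize];
        // stack / bulge / internal
        int kmax = std::min(j - 1, i + 1 + P.max_interior);
        for (int k = i + 1; k <= kmax; k++) {
          int n1 = k - i - 1;
          int lmin = k + P.min_loop + 1;
          int lmin2 = j - 1 - (P.max_interior - n1);
          if (lmin2 > lmin) lmin = lmin2;
          for (int l = lmin; l <= j - 1; l++) {
            if (l <= k) continue;
            int pkl = pair_idx(s[k], s[l]);
            if (pkl < 0 || V[k][l] >= INF) continue;
            int e = interior_energy(P, pij, pkl, n1, j - l - 1);
            if (e >= INF) continue;
            int tot = V[k][l] + e;
            if (tot < best) best = tot;
          }
        }
        // multiloop closure: >= 2 enclosed branches
        for (int k = i + 2; k <= j - 2; k++) {
          if (WM[i + 1][k] >= INF || WM[k + 1][j - 1] >= INF) continue;
          int tot = P.ml_close + P.ml_branch + WM[i + 1][k] + WM[k + 1][j - 1];
          if (tot < best) best = tot;
        }
        V[i][j] = best;
      }
      // WM: segment [i, j] holding >= 1 branch inside a multiloop
      int w = INF;
      if (WM[i + 1][j] < INF) w = std::min(w, WM[i + 1][j] + P.ml_unpaired);
      if (WM[i][j - 1] < INF) w = std::min(w, WM[i][j - 1] + P.ml_unpaired);
      if (V[i][j] < INF) w = std::min(w, V[i][j] + P.ml_branch);
      for (int k = i + 1; k <= j - 1; k++) {
        if (WM[i][k] < INF && WM[k + 1][j] < INF)
          w = std::min(w, WM[i][k] + WM[k + 1][j]);
      }
      WM[i][j] = w;
    }
  }

  // external loop
  std::vector<int> W(n, 0);
  for (int j = 0; j < n; j++) {
    int best = (j > 0) ? W[j - 1] : 0;
    for (int k = 0; k <= j; k++) {
      if (V[k][j] >= INF) continue;
      int e = ((k > 0) ? W[k - 1] : 0) + V[k][j];
      if (e < best) best = e;
    }
    W[j] = best;
  }

  // traceback
  std::vector<int> pairv(n, 0);  // 1-based partner, 0 = unpaired
  struct Frame { int type, i, j; };  // 0=W, 1=V, 2=WM
  std::vector<Frame> stk;
  stk.push_back({0, 0, n - 1});
  while (!stk.empty()) {
    Frame f = stk.back();
    stk.pop_back();
    if (f.type == 0) {
      int j = f.j;
      if (j < 0) continue;
      if (j == 0 && W[0] == 0) continue;
      if (j > 0 && W[j] == W[j - 1]) { stk.push_back({0, 0, j - 1}); continue; }
      bool done = false;
      for (int k = 0; k <= j && !done; k++) {
        if (V[k][j] < INF && ((k > 0) ? W[k - 1] : 0) + V[k][j] == W[j]) {
          stk.push_back({1, k, j});
          if (k > 0) stk.push_back({0, 0, k - 1});
          done = true;
        }
      }
      if (!done) stop("traceback failure in W");
    } else if (f.type == 1) {
      int i = f.i, j = f.j;
      pairv[i] = j + 1;
      pairv[j] = i + 1;
      int v = V[i][j];
      int pij = pair_idx(s[i], s[j]);
      int hsize = j - i - 1;
      if (hsize >= P.min_loop && hsize < (int)P.hairpin.size() &&
          P.hairpin[hsize] == v)
        continue;
      bool done = false;
      int kmax = std::min(j - 1, i + 1 + P.max_interior);
      for (int k = i + 1; k <= kmax && !done; k++) {
        int n1 = k - i - 1;
        for (int l = j - 1; l > k && !done; l--) {
          int n2 = j - l - 1;
          if (n1 + n2 > P.max_interior) continue;
          int pkl = pair_idx(s[k], s[l]);
          if (pkl < 0 || V[k][l] >= INF) continue;
          int e = interior_energy(P, pij, pkl, n1, n2);
          if (e < INF && V[k][l] + e == v) {
            stk.push_back({1, k, l});
            done = true;
          }
        }
      }
      if (done) continue;
      for (int k = i + 2; k <= j - 2 && !done; k++) {
        if (WM[i + 1][k] < INF && WM[k + 1][j - 1] < INF &&
            P.ml_close + P.ml_branch + WM[i + 1][k] + WM[k + 1][j - 1] == v) {
          stk.push_back({2, i + 1, k});
          stk.push_back({2, k + 1, j - 1});
          done = true;
        }
      }
      if (!done) stop("traceback failure in V");
    } else {
      int i = f.i, j = f.j;
      int w = WM[i][j];
      if (i + 1 <= j && WM[i + 1][j] < INF && WM[i + 1][j] + P.ml_unpaired == w) {
        stk.push_back({2, i + 1, j});
        continue;
      }
      if (i <= j - 1 && WM[i][j - 1] < INF && WM[i][j - 1] + P.ml_unpaired == w) {
        stk.push_back({2, i, j - 1});
        continue;
      }
      if (V[i][j] < INF && V[i][j] + P.ml_branch == w) {
        stk.push_back({1, i, j});
        continue;
      }
      bool done = false;
      for (int k = i + 1; k <= j - 1 && !done; k++) {
        if (WM[i][k] < INF && WM[k + 1][j] < INF &&
            WM[i][k] + WM[k + 1][j] == w) {
          stk.push_back({2, i, k});
          stk.push_back({2, k + 1, j});
          done = true;
        }
      }
      if (!done) stop("traceback failure in WM");
    }
  }

  std::string db(n, '.');
  for (int i = 0; i < n; i++) {
    if (pairv[i] > i + 1) db[i] = '(';
    else if (pairv[i] > 0 && pairv[i] <= i) db[i] = ')';
  }

  IntegerVector pr(n);
  for (int i = 0; i < n; i++) pr[i] = pairv[i] == 0 ? NA_INTEGER : pairv[i];

  double mfe = (n > 0 ? W[n - 1] : 0) / 10.0;
  return List::create(_["mfe"] = mfe, _["structure"] = db, _["pairs"] = pr);
}

// Leftmost 3'-adapter occurrence per read: the adapter (or a >= min_overlap
// prefix of it when the read ends first) must match with at most max_mm
// substitutions; everything from the match start is trimmed. Returns the
// 0-based match start, i.e. the insert length, or -1 when absent.
// [[Rcpp::export(name = ".adapter_scan")]]
IntegerVector adapter_scan(CharacterVector reads, std::string adapter,
                           int max_mm, int min_overlap) {
  int nr = reads.size(), alen = adapter.size();
  IntegerVector out(nr);
  for (int r = 0; r < nr; r++) {
    std::string rd = as<std::string>(reads[r]);
    int len = rd.size(), hit = -1;
    for (int s0 = 0; s0 < len && hit < 0; s0++) {
      int ov = std::min(alen, len - s0);
      if (ov < min_overlap) break;
      int mm = 0;
      for (int k = 0; k < ov; k++) {
        if (rd[s0 + k] != adapter[k] && ++mm > max_mm) break;
      }
      if (mm <= max_mm) hit = s0;
    }
    out[r] = hit;
  }
  return out;
}
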