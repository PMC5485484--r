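#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Plant miRNA target scoring: the miRNA is slid antisense along the
// transcript; per miRNA position (1-based from the 5' end) a perfect
// Watson-Crick pair scores 0, a G:U wobble 0.5 and a mismatch 1, doubled
// within the seed-proximal core (positions core_start..core_end).
// Ungapped; windows with score <= max_score are reported.

static inline char norm_base(char c) {
  if (c == 'U') return 'T';
  return c;
}

static inline double pos_score(char mi, char tb) {
  // mi: miRNA base (T for U), tb: transcript base; both DNA alphabet
  switch (mi) {
    case 'A': return tb == 'T' ? 0.0 : 1.0;
    case 'C': return tb == 'G' ? 0.0 : 1.0;
    case 'G': return tb == 'C' ? 0.0 : (tb == 'T' ? 0.5 : 1.0);
    case 'T': return tb == 'A' ? 0.0 : (tb == 'G' ? 0.5 : 1.0);
    default: return 1.0;
  }
}

// [[Rcpp::export(name = ".target_scan")]]
DataFrame target_scan(CharacterVector mirnas, CharacterVector transcripts,
                      double max_score, int core_start, int core_end) {
  std::vector<int> out_mir, out_tx, out_pos;
  std::vector<double> out_score;
  for (int m = 0; m < mirnas.size(); m++) {
    std::string mi = as<std::string>(mirnas[m]);
    int L = mi.size();
    for (int k = 0; k < L; k++) mi[k] = norm_base(mi[k]);
    for (int t = 0; t < transcripts.size(); t++) {
      std::string tx = as<std::string>(transcripts[t]);
      int n = tx.size();
      for (int s = 0; s + L <= n; s++) {
        double sc = 0.0;
        for (int i = 1; i <= L; i++) {
          double ps = pos_score(mi[i - 1], tx[s + L - i]);
          if (i >= core_start && i <= core_end) ps *= 2.0;
          sc += ps;
          if (sc > max_score) break;
        }
        if (sc <= max_score) {
          out_mir.push_back(m + 1);
          out_tx.push_back(t + 1);
          out_pos.push_back(s);
          out_score.push_back(sc);
        }
      }
    }
  }
  return DataFrame::create(_["mirna"] = out_mir, _["transcript"] = out_tx,
                           _["pos"] = out_pos, _["score"] = out_score);
}
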