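#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Uniform pair-energy ("pair count") nested secondary-structure model:
// every admissible pair (Watson-Crick or G:U wobble) contributes energy
// -eps (kT units), structures are nested, hairpin loops have at least
// min_loop unpaired bases. Exact inside/outside over this ensemble.

static bool g_allow_gu = true;

static inline bool admissible(char a, char b) {
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
      (a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return true;
  return g_allow_gu &&
         ((a == 'G' && b == 'U') || (a == 'U' && b == 'G'));
}

// inside partition function over [1..n], 1-based; Z(i,j)=1 for j<i.
// Z stored as (n+2)x(n+2).
static void inside_pf(const std::string &s, double w, int min_loop,
                      std::vector<std::vector<double> > &Z) {
  int n = (int)s.size();
  Z.assign(n + 2, std::vector<double>(n + 2, 1.0));
  for (int span = 1; span <= n; ++span) {
    for (int i = 1; i + span - 1 <= n; ++i) {
      int j = i + span - 1;
      double z = Z[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (admissible(s[i - 1], s[k - 1]))
          z += w * Z[i + 1][k - 1] * Z[k + 1][j];
      }
      Z[i][j] = z;
    }
  }
}

// [[Rcpp::export(name = ".pu_pair_count_cpp")]]
List pu_pair_count_cpp(std::string seq, double eps, int min_loop,
                       bool allow_gu) {
  g_allow_gu = allow_gu;
  int n = (int)seq.size();
  if (n < 1) stop("empty sequence");
  double w = std::exp(eps);
  std::vector<std::vector<double> > Z;
  inside_pf(seq, w, min_loop, Z);
  double Ztot = Z[1][n];

  // outside: Ob(i,j) = PF of everything outside [i..j] given (i,j) paired.
  // Ob(i,j) = Z(1,i-1) Z(j+1,n)
  //         + sum over directly enclosing admissible pairs (p,q):
  //           Ob(p,q) * w * Z(p+1,i-1) * Z(j+1,q-1)
  // evaluated in order of decreasing span so enclosing pairs come first.
  NumericMatrix P(n, n);
  std::vector<std::vector<double> > Ob(n + 2, std::vector<double>(n + 2, 0.0));
  for (int span = n; span >= min_loop + 2; --span) {
    for (int i = 1; i + span - 1 <= n; ++i) {
      int j = i + span - 1;
      if (!admissible(seq[i - 1], seq[j - 1])) continue;
      double o = Z[1][i - 1] * Z[j + 1][n];
      for (int p = 1; p < i; ++p) {
        for (int q = j + 1; q <= n; ++q) {
          if (q - p <= min_loop) continue;
          if (!admissible(seq[p - 1], seq[q - 1])) continue;
          if (Ob[p][q] == 0.0) continue;
          o += Ob[p][q] * w * Z[p + 1][i - 1] * Z[j + 1][q - 1];
        }
      }
      Ob[i][j] = o;
      double Zb = w * Z[i + 1][j - 1];
      P(i - 1, j - 1) = o * Zb / Ztot;
      P(j - 1, i - 1) = P(i - 1, j - 1);
    }
  }

  // PU by an independent constrained-inside recursion: recompute the inside
  // partition function with position u forbidden to pair; PU(u) = Zno/Z.
  NumericVector pu(n);
  std::vector<std::vector<double> > Zn;
  for (int u = 1; u <= n; ++u) {
    Zn.assign(n + 2, std::vector<double>(n + 2, 1.0));
    for (int span = 1; span <= n; ++span) {
      for (int i = 1; i + span - 1 <= n; ++i) {
        int j = i + span - 1;
        double z = Zn[i + 1][j];
        if (i != u) {
          for (int k = i + min_loop + 1; k <= j; ++k) {
            if (k == u) continue;
            if (admissible(seq[i - 1], seq[k - 1]))
              z += w * Zn[i + 1][k - 1] * Zn[k + 1][j];
          }
        }
        Zn[i][j] = z;
      }
    }
    pu[u - 1] = Zn[1][n] / Ztot;
  }

  return List::create(_["pu"] = pu, _["pair_prob"] = P, _["Z"] = Ztot);
}

// Nussinov maximum-pairing DP with deterministic traceback: at each
// subproblem the 5'-most position is paired with the smallest admissible
// partner achieving the optimum, otherwise left unpaired (yields the
// 5'-most outermost pair among co-optimal structures).
// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop, bool allow_gu) {
  g_allow_gu = allow_gu;
  int n = (int)seq.size();
  std::vector<std::vector<int> > N(n + 2, std::vector<int>(n + 2, 0));
  for (int span = min_loop + 2; span <= n; ++span) {
    for (int i = 1; i + span - 1 <= n; ++i) {
      int j = i + span - 1;
      int best = N[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (admissible(seq[i - 1], seq[k - 1])) {
          int v = 1 + N[i + 1][k - 1] + N[k + 1][j];
          if (v > best) best = v;
        }
      }
      N[i][j] = best;
    }
  }
  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(1, n));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || N[i][j] == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j && !paired; ++k) {
      if (admissible(seq[i - 1], seq[k - 1]) &&
          N[i][j] == 1 + N[i + 1][k - 1] + N[k + 1][j]) {
        db[i - 1] = '(';
        db[k - 1] = ')';
        stack.push_back(std::make_pair(k + 1, j));
        stack.push_back(std::make_pair(i + 1, k - 1));
        paired = true;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  return List::create(_["n_pairs"] = N[1][n], _["structure"] = db);
}

// Mismatch-tolerant k-mer scan: for every read, every offset whose Hamming
// distance to the k-mer is <= max_mm. Returns 1-based read indices/offsets.
// [[Rcpp::export(name = ".hamming_scan_cpp")]]
DataFrame hamming_scan_cpp(CharacterVector reads, std::string kmer, int max_mm) {
  int k = (int)kmer.size();
  std::vector<int> ridx, off, mm;
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    int n = (int)s.size();
    for (int o = 0; o + k <= n; ++o) {
      int d = 0;
      for (int t = 0; t < k && d <= max_mm; ++t) {
        if (s[o + t] != kmer[t]) ++d;
      }
      if (d <= max_mm) {
        ridx.push_back(r + 1);
        off.push_back(o + 1);
        mm.push_back(d);
      }
    }
  }
  return DataFrame::create(_["read"] = ridx, _["offset"] = off,
                           _["mismatches"] = mm);
}
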