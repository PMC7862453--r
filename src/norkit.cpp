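#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Alignment op codes shared with the R side:
//   0 '=' match, 1 'X' mismatch, 2 'I' insertion (base in b, gap in a),
//   3 'D' deletion (base in a, gap in b).  a is the reference.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export(name = ".align_banded_cpp")]]
List align_banded_cpp(std::string a, std::string b,
                      int match, int mismatch,
                      int gap_open, int gap_ext, int band) {
  const long long n = (long long)a.size();
  const long long m = (long long)b.size();
  if (band < 1) stop("band must be >= 1");
  if (llabs(n - m) > band)
    stop("band (%d) smaller than length difference (%d)", band, (int)llabs(n - m));
  const long long w = 2LL * band + 1;
  // memory guard: three byte matrices of (n+1) x w
  double bytes = 3.0 * (double)(n + 1) * (double)w;
  if (bytes > 1.5e9)
    stop("banded DP would need >1.5 GB; sequences too long or band too wide");

  // rolling score rows, full traceback byte matrices
  std::vector<int> Mp(w, NEG), Dp(w, NEG), Ip(w, NEG);
  std::vector<int> Mc(w, NEG), Dc(w, NEG), Ic(w, NEG);
  std::vector<unsigned char> tM((n + 1) * w, 255), tD((n + 1) * w, 255),
      tI((n + 1) * w, 255);

  // i = 0 row: j = 0..min(m, band); offset c = j + band - i
  {
    long long jhi = std::min(m, (long long)band);
    Mp[band] = 0;  // (0,0)
    for (long long j = 1; j <= jhi; ++j) {
      long long c = j + band;
      if (c >= w) break;
      Ip[c] = gap_open + (int)j * gap_ext;
      tI[0 * w + c] = (j == 1) ? 0 : 2;  // came from M at (0,0) else I
    }
  }

  for (long long i = 1; i <= n; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Dc.begin(), Dc.end(), NEG);
    std::fill(Ic.begin(), Ic.end(), NEG);
    long long jlo = std::max(0LL, i - band);
    long long jhi = std::min(m, i + band);
    for (long long j = jlo; j <= jhi; ++j) {
      long long c = j - i + band;  // 0..w-1
      if (j == 0) {
        // leading deletion chain
        Dc[c] = gap_open + (int)i * gap_ext;
        tD[i * w + c] = (i == 1) ? 0 : 1;
        continue;
      }
      // M: from (i-1, j-1) -> same offset c in previous row
      {
        int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
        int best = Mp[c];
        unsigned char who = 0;
        if (Dp[c] > best) { best = Dp[c]; who = 1; }
        if (Ip[c] > best) { best = Ip[c]; who = 2; }
        if (best > NEG) {
          Mc[c] = best + s;
          tM[i * w + c] = who;
        }
      }
      // D: from (i-1, j) -> offset c+1 in previous row
      if (c + 1 < w) {
        int v1 = (Mp[c + 1] > NEG) ? Mp[c + 1] + gap_open + gap_ext : NEG;
        int v2 = (Dp[c + 1] > NEG) ? Dp[c + 1] + gap_ext : NEG;
        int v3 = (Ip[c + 1] > NEG) ? Ip[c + 1] + gap_open + gap_ext : NEG;
        int best = v1; unsigned char who = 0;
        if (v2 > best) { best = v2; who = 1; }
        if (v3 > best) { best = v3; who = 2; }
        if (best > NEG) { Dc[c] = best; tD[i * w + c] = who; }
      }
      // I: from (i, j-1) -> offset c-1 in current row
      if (c - 1 >= 0) {
        int v1 = (Mc[c - 1] > NEG) ? Mc[c - 1] + gap_open + gap_ext : NEG;
        int v2 = (Ic[c - 1] > NEG) ? Ic[c - 1] + gap_ext : NEG;
        int v3 = (Dc[c - 1] > NEG) ? Dc[c - 1] + gap_open + gap_ext : NEG;
        int best = v1; unsigned char who = 0;
        if (v2 > best) { best = v2; who = 2; }
        if (v3 > best) { best = v3; who = 1; }
        if (best > NEG) { Ic[c] = best; tI[i * w + c] = who; }
      }
    }
    Mp.swap(Mc); Dp.swap(Dc); Ip.swap(Ic);
  }

  long long cend = m - n + band;
  if (cend < 0 || cend >= w) stop("internal: end cell outside band");
  int sM = Mp[cend], sD = Dp[cend], sI = Ip[cend];
  int score = sM; int state = 0;  // 0 M, 1 D, 2 I
  if (sD > score) { score = sD; state = 1; }
  if (sI > score) { score = sI; state = 2; }
  if (score <= NEG / 2) stop("no alignment within band");

  // traceback
  std::vector<int> ops;
  ops.reserve(n + m);
  long long i = n, j = m;
  while (i > 0 || j > 0) {
    long long c = j - i + band;
    if (state == 0) {
      ops.push_back((a[i - 1] == b[j - 1]) ? 0 : 1);
      state = tM[i * w + c];
      --i; --j;
    } else if (state == 1) {
      ops.push_back(3);
      state = tD[i * w + c];
      --i;
    } else {
      ops.push_back(2);
      state = tI[i * w + c];
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}

// ---------------------------------------------------------------------------
// Nussinov-style folding with two scoring models and optional forced-unpaired
// positions.  model 0: +1 per canonical pair (AU, GC, GU).  model 1: weighted
// pairs (GC=3, AU=2, GU=1) plus stack_bonus for each pair stacked directly on
// another pair.

static inline double pair_score(char x, char y, int model,
                                double gc, double au, double gu) {
  if ((x == 'G' && y == 'C') || (x == 'C' && y == 'G'))
    return model == 0 ? 1.0 : gc;
  if ((x == 'A' && y == 'U') || (x == 'U' && y == 'A'))
    return model == 0 ? 1.0 : au;
  if ((x == 'G' && y == 'U') || (x == 'U' && y == 'G'))
    return model == 0 ? 1.0 : gu;
  return -1.0;  // not pairable
}

// [[Rcpp::export(name = ".fold_cpp")]]
List fold_cpp(std::string seq, int model, int min_loop,
              LogicalVector unpaired,
              double gc, double au, double gu, double stack_bonus) {
  const int n = (int)seq.size();
  IntegerVector partner(n, 0);
  if (n == 0)
    return List::create(_["partner"] = partner, _["score"] = 0.0);
  if ((int)unpaired.size() != n) stop("constraint mask length mismatch");
  const double NEGD = -1e18;
  double bonus = (model == 0) ? 0.0 : stack_bonus;

  std::vector<double> E((size_t)n * n, 0.0), P((size_t)n * n, NEGD);
  std::vector<double> S((size_t)n * n, -1.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (!unpaired[i] && !unpaired[j] && (j - i) > min_loop)
        S[(size_t)i * n + j] = pair_score(seq[i], seq[j], model, gc, au, gu);

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      size_t ij = (size_t)i * n + j;
      // P(i,j): (i,j) paired
      double s = S[ij];
      if (s > 0) {
        double innerE = (j - 1 >= i + 1) ? E[(size_t)(i + 1) * n + (j - 1)] : 0.0;
        double best = innerE;
        if (j - 1 >= i + 1) {
          double ip = P[(size_t)(i + 1) * n + (j - 1)];
          if (ip > NEGD / 2 && ip + bonus > best) best = ip + bonus;
        }
        P[ij] = s + best;
      }
      // E(i,j): j unpaired, or j pairs with k in [i, j-min_loop-1]
      double best = E[(size_t)i * n + (j - 1)];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double pk = P[(size_t)k * n + j];
        if (pk <= NEGD / 2) continue;
        double left = (k - 1 >= i) ? E[(size_t)i * n + (k - 1)] : 0.0;
        if (left + pk > best) best = left + pk;
      }
      E[ij] = best;
    }
  }

  // traceback (iterative)
  std::vector<std::pair<std::pair<int, int>, int> > stack;  // ((i,j), which) which 0=E 1=P
  if (n >= 2) stack.push_back(std::make_pair(std::make_pair(0, n - 1), 0));
  const double eps = 1e-9;
  while (!stack.empty()) {
    std::pair<std::pair<int, int>, int> top = stack.back();
    stack.pop_back();
    int i = top.first.first, j = top.first.second, which = top.second;
    if (j - i < min_loop + 1) continue;
    size_t ij = (size_t)i * n + j;
    if (which == 1) {
      partner[i] = j + 1;
      partner[j] = i + 1;
      if (j - 1 < i + 1) continue;
      double s = S[ij];
      double ip = P[(size_t)(i + 1) * n + (j - 1)];
      if (ip > NEGD / 2 && std::abs(P[ij] - (s + ip + bonus)) < eps)
        stack.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 1));
      else
        stack.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 0));
      continue;
    }
    double v = E[ij];
    if (std::abs(v - E[(size_t)i * n + (j - 1)]) < eps) {
      stack.push_back(std::make_pair(std::make_pair(i, j - 1), 0));
      continue;
    }
    bool found = false;
    for (int k = i; k <= j - min_loop - 1 && !found; ++k) {
      double pk = P[(size_t)k * n + j];
      if (pk <= NEGD / 2) continue;
      double left = (k - 1 >= i) ? E[(size_t)i * n + (k - 1)] : 0.0;
      if (std::abs(v - (left + pk)) < eps) {
        if (k - 1 >= i)
          stack.push_back(std::make_pair(std::make_pair(i, k - 1), 0));
        stack.push_back(std::make_pair(std::make_pair(k, j), 1));
        found = true;
      }
    }
    if (!found) stop("internal: fold traceback failed");
  }

  double score = (n >= 2) ? E[(size_t)0 * n + (n - 1)] : 0.0;
  return List::create(_["partner"] = partner, _["score"] = score);
}

// Hamming mismatch count between equal-length strings (helper for overlap
// verification on long sequences).
// [[Rcpp::export(name = ".hamming_cpp")]]
int hamming_cpp(std::string x, std::string y) {
  if (x.size() != y.size()) stop("hamming: length mismatch");
  int d = 0;
  for (size_t i = 0; i < x.size(); ++i)
    if (x[i] != y[i]) ++d;
  return d;
}
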