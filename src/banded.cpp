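#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Banded global alignment with linear gap costs.
// Cells (i,j), 0..la x 0..lb, restricted to |i - j - delta| <= band with
// delta = floor((la - lb) / 2) centering the band so both corners fit.
// Transcript characters: 'M' match, 'R' mismatch, 'D' gap in b (a char
// consumed alone), 'I' gap in a (b char consumed alone).
// [[Rcpp::export]]
List banded_align_cpp(IntegerVector a, IntegerVector b,
                      int match, int mismatch, int gap, int band) {
  const int la = a.size(), lb = b.size();
  const int delta = (la - lb) >= 0 ? (la - lb) / 2 : -((lb - la) / 2);
  const long NEG = -1000000000L;
  if (std::abs(0 - 0 - delta) > band || std::abs(la - lb - delta) > band)
    stop("band too small to connect the alignment corners");

  std::vector<long> S((size_t)(la + 1) * (lb + 1), NEG);
  std::vector<char> T((size_t)(la + 1) * (lb + 1), 0);
  auto id = [&](int i, int j) { return (size_t)i * (lb + 1) + j; };
  auto inband = [&](int i, int j) { return std::abs(i - j - delta) <= band; };

  S[id(0, 0)] = 0;
  for (int i = 0; i <= la; ++i) {
    int jlo = std::max(0, i - delta - band);
    int jhi = std::min(lb, i - delta + band);
    for (int j = jlo; j <= jhi; ++j) {
      if (i == 0 && j == 0) continue;
      long best = NEG; char op = 0;
      if (i > 0 && j > 0 && inband(i - 1, j - 1) && S[id(i-1, j-1)] > NEG) {
        bool eq = a[i - 1] == b[j - 1];
        long v = S[id(i-1, j-1)] + (eq ? match : mismatch);
        if (v > best) { best = v; op = eq ? 'M' : 'R'; }
      }
      if (i > 0 && inband(i - 1, j) && S[id(i-1, j)] > NEG) {
        long v = S[id(i-1, j)] + gap;
        if (v > best) { best = v; op = 'D'; }
      }
      if (j > 0 && inband(i, j - 1) && S[id(i, j-1)] > NEG) {
        long v = S[id(i, j-1)] + gap;
        if (v > best) { best = v; op = 'I'; }
      }
      S[id(i, j)] = best; T[id(i, j)] = op;
    }
  }
  if (S[id(la, lb)] <= NEG) stop("band too small to connect the alignment corners");

  std::string tr;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    char op = T[id(i, j)];
    tr.push_back(op);
    if (op == 'M' || op == 'R') { --i; --j; }
    else if (op == 'D') { --i; }
    else { --j; }
  }
  std::reverse(tr.begin(), tr.end());
  return List::create(_["score"] = (double)S[id(la, lb)],
                      _["transcript"] = tr);
}

// Metropolis-Hastings chain over fixed-length DNA sequences for the
// synthetic exponential-tail score family:
//   hash h = (off + sum_i c_i * base^i) mod p, u = (h + 0.5)/p,
//   score = floor(-log(u) / lam_true).
// Moves: substitution, or insertion/deletion balanced by dropping/adding a
// terminal base, keeping |x| = n (edit distance <= 2); proposals equal to
// the current sequence are redrawn. Acceptance min{1, exp(lambda0 (sy-sx))}.
// Sampling: if sample_interval > 0, the current state is recorded every
// sample_interval proposals (time-uniform, the estimator-consistent
// default); otherwise the state is recorded at every accepts_per_sample-th
// acceptance (the jump-chain variant).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List mh_chain_exp_cpp(int n, double lam_true, double off, int base, double p,
                      double lambda0, int num_samples, int accepts_per_sample,
                      int burn_in, int sample_interval) {
  // modular reduction without fmod; operands stay well below 2^53
  auto pmod = [&](double v) {
    v -= std::floor(v / p) * p;
    if (v >= p) v -= p;
    if (v < 0) v += p;
    return v;
  };
  std::vector<double> pw(n);
  pw[0] = 1.0;
  for (int i = 1; i < n; ++i) pw[i] = pmod(pw[i - 1] * base);

  auto score_of = [&](const std::vector<int>& c) {
    double h = off;
    for (int i = 0; i < n; ++i) h += c[i] * pw[i];
    h = pmod(h);
    double u = (h + 0.5) / p;
    return (int)std::floor(-std::log(u) / lam_true);
  };
  auto runi = [&](int k) {  // uniform integer in 0..k-1
    int v = (int)(unif_rand() * k);
    return v >= k ? k - 1 : v;
  };

  GetRNGstate();
  std::vector<int> x(n), y(n);
  for (int i = 0; i < n; ++i) x[i] = runi(4) + 1;
  int sx = score_of(x);

  long long proposals = 0, accepts = 0;
  int kept = 0;
  IntegerVector samples(std::max(num_samples - burn_in, 0));
  int acc_since = 0, drawn = 0;

  while (kept < samples.size()) {
    // propose y != x
    for (;;) {
      y = x;
      int mv = runi(3);
      if (mv == 0) {
        int i = runi(n);
        int nb = runi(3);
        int cur = y[i] - 1;
        y[i] = ((cur + nb + 1) % 4) + 1;
      } else if (mv == 1) {
        // insert a uniform base at a uniform position, drop a terminal base
        int i = runi(n);      // insertion index in the shortened sequence
        int nb = runi(4) + 1;
        int side = runi(2);   // 0: drop left terminal, 1: drop right terminal
        if (side == 0) {
          for (int t2 = 0; t2 < n - 1; ++t2) y[t2] = x[t2 + 1];
        } else {
          for (int t2 = 0; t2 < n - 1; ++t2) y[t2] = x[t2];
        }
        for (int t2 = n - 1; t2 > i; --t2) y[t2] = y[t2 - 1];
        y[i] = nb;
      } else {
        // delete at a uniform position, add a uniform base at a terminal
        int i = runi(n);
        int nb = runi(4) + 1;
        int side = runi(2);   // 0: prepend at left end, 1: append at right
        if (side == 0) {
          for (int t2 = i; t2 > 0; --t2) y[t2] = x[t2 - 1];
          y[0] = nb;
        } else {
          for (int t2 = i; t2 < n - 1; ++t2) y[t2] = x[t2 + 1];
          y[n - 1] = nb;
        }
      }
      if (y != x) break;
    }
    ++proposals;
    int sy = score_of(y);
    bool accept = sy >= sx || unif_rand() < std::exp(lambda0 * (sy - sx));
    if (accept) {
      x = y; sx = sy; ++accepts;
      if (sample_interval <= 0 && ++acc_since >= accepts_per_sample) {
        acc_since = 0;
        ++drawn;
        if (drawn > burn_in) samples[kept++] = sx;
      }
    }
    if (sample_interval > 0 && proposals % sample_interval == 0) {
      ++drawn;
      if (drawn > burn_in) samples[kept++] = sx;
    }
  }
  PutRNGstate();
  return List::create(_["samples"] = samples,
                      _["proposals"] = (double)proposals,
                      _["accepts"] = (double)accepts);
}
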