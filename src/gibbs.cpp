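// Simulated-annealing Gibbs sampler for peptide motif deconvolution.
//
// State: per-peptide (cluster, alignment) where an alignment picks which
// residues of a 9-11-mer form the length-9 core (terminal residues always
// kept).  One sweep visits every peptide in a seeded-random order, removes
// it from its cluster's counts, scores every (cluster, alignment) candidate
// by the peptide's leave-one-out log2-odds fit with background pseudocounts,
// and samples a candidate with probability proportional to exp(score / T).
// The annealing schedule ends with zero-temperature (greedy) polish sweeps
// run to convergence.
//
// Draws uniforms directly from std::mt19937 words (53-bit mantissa) rather
// than through std::*_distribution, so results are bit-reproducible for a
// given seed independent of standard-library internals.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  // uniform double in [0, 1), 53 random bits
  double unif() {
    double a = static_cast<double>(gen() >> 5);   // 27 bits
    double b = static_cast<double>(gen() >> 6);   // 26 bits
    return (a * 67108864.0 + b) / 9007199254740992.0;
  }
  // uniform integer in [0, n)
  int below(int n) {
    int v = static_cast<int>(unif() * n);
    return v >= n ? n - 1 : v;
  }
};

}  // namespace

class GibbsState {
 public:
  int N, K, m;              // peptides, clusters, motif length
  double omega;
  std::vector<int> pep;     // N x maxL residue indices (0..19), row-major
  std::vector<int> len;     // peptide lengths
  int maxL;
  std::vector<std::vector<std::vector<int>>> aligns_by_pep;
  // aligns_by_pep[i][r] = kept positions (size m) for candidate alignment r
  std::vector<double> bg;   // 20 background frequencies
  std::vector<int> counts;  // K x m x 20
  std::vector<int> nc;      // cluster sizes
  std::vector<int> assign;  // cluster of each peptide
  std::vector<int> ach;     // alignment choice of each peptide

  GibbsState(const IntegerMatrix& pepmat, const IntegerVector& lens,
             const List& align_list, const IntegerVector& pep_align_idx,
             int K_, int m_, const NumericVector& bg_, double omega_)
      : N(pepmat.nrow()), K(K_), m(m_), omega(omega_),
        maxL(pepmat.ncol()) {
    pep.resize(N * maxL);
    len.resize(N);
    for (int i = 0; i < N; ++i) {
      len[i] = lens[i];
      for (int j = 0; j < maxL; ++j) pep[i * maxL + j] = pepmat(i, j);
    }
    bg.assign(bg_.begin(), bg_.end());
    aligns_by_pep.resize(N);
    for (int i = 0; i < N; ++i) {
      IntegerMatrix A = align_list[pep_align_idx[i]];
      aligns_by_pep[i].resize(A.nrow());
      for (int r = 0; r < A.nrow(); ++r) {
        aligns_by_pep[i][r].resize(m);
        for (int p = 0; p < m; ++p) aligns_by_pep[i][r][p] = A(r, p);
      }
    }
    counts.assign(K * m * 20, 0);
    nc.assign(K, 0);
    assign.assign(N, -1);
    ach.assign(N, 0);
  }

  inline int residue(int i, int pos) const { return pep[i * maxL + pos]; }

  void add(int i, int c, int r) {
    const std::vector<int>& keep = aligns_by_pep[i][r];
    for (int p = 0; p < m; ++p)
      counts[(c * m + p) * 20 + residue(i, keep[p])]++;
    nc[c]++;
    assign[i] = c;
    ach[i] = r;
  }

  void remove(int i) {
    int c = assign[i];
    const std::vector<int>& keep = aligns_by_pep[i][ach[i]];
    for (int p = 0; p < m; ++p)
      counts[(c * m + p) * 20 + residue(i, keep[p])]--;
    nc[c]--;
    assign[i] = -1;
  }

  // log2-odds fit of peptide i under cluster c with alignment r, using the
  // current (leave-one-out if i was removed) smoothed frequency model.
  double score(int i, int c, int r) const {
    const std::vector<int>& keep = aligns_by_pep[i][r];
    double s = 0.0;
    double n = static_cast<double>(nc[c]);
    for (int p = 0; p < m; ++p) {
      int a = residue(i, keep[p]);
      double F = n > 0 ? counts[(c * m + p) * 20 + a] / n : bg[a];
      double f = (F + omega * bg[a]) / (1.0 + omega);
      s += std::log2(f / bg[a]);
    }
    return s;
  }

  // One sweep at temperature T (T <= 0: greedy argmax, lowest index wins
  // ties).  Returns the number of peptides that changed state.
  int sweep(double T, Rng& rng, std::vector<int>& order,
            std::vector<double>& cand) {
    // seeded-random visiting order (Fisher-Yates)
    for (int i = N - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(order[i], order[j]);
    }
    int moved = 0;
    for (int oi = 0; oi < N; ++oi) {
      int i = order[oi];
      int old_c = assign[i], old_r = ach[i];
      remove(i);
      int nr = static_cast<int>(aligns_by_pep[i].size());
      int ncand = K * nr;
      cand.resize(ncand);
      double smax = -1e300;
      int argmax = 0;
      for (int c = 0; c < K; ++c)
        for (int r = 0; r < nr; ++r) {
          double s = score(i, c, r);
          int idx = c * nr + r;
          cand[idx] = s;
          if (s > smax + 1e-12) { smax = s; argmax = idx; }
        }
      int pick;
      if (T <= 0.0) {
        pick = argmax;
      } else {
        double tot = 0.0;
        for (int idx = 0; idx < ncand; ++idx) {
          cand[idx] = std::exp((cand[idx] - smax) / T);
          tot += cand[idx];
        }
        double u = rng.unif() * tot, acc = 0.0;
        pick = ncand - 1;
        for (int idx = 0; idx < ncand; ++idx) {
          acc += cand[idx];
          if (u < acc) { pick = idx; break; }
        }
      }
      int c = pick / nr, r = pick % nr;
      add(i, c, r);
      if (c != old_c || r != old_r) ++moved;
    }
    return moved;
  }

  // Total leave-one-out objective: sum over peptides of their current fit.
  double total_objective() {
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      int c = assign[i], r = ach[i];
      remove(i);
      tot += score(i, c, r);
      add(i, c, r);
    }
    return tot;
  }
};

// [[Rcpp::export(name = ".gibbs_run")]]
List gibbs_run(IntegerMatrix pepmat, IntegerVector lens, List align_list,
               IntegerVector pep_align_idx, int K, int motif_len,
               NumericVector bg, double omega, NumericVector temps,
               int iters_per_temp, int seed) {
  GibbsState st(pepmat, lens, align_list, pep_align_idx, K, motif_len,
                bg, omega);
  Rng rng(static_cast<uint32_t>(seed));

  // random initialization
  for (int i = 0; i < st.N; ++i) {
    int c = rng.below(K);
    int r = rng.below(static_cast<int>(st.aligns_by_pep[i].size()));
    st.add(i, c, r);
  }

  std::vector<int> order(st.N);
  for (int i = 0; i < st.N; ++i) order[i] = i;
  std::vector<double> cand;

  for (int t = 0; t < temps.size(); ++t)
    for (int it = 0; it < iters_per_temp; ++it)
      st.sweep(temps[t], rng, order, cand);

  // zero-temperature polish to convergence (max 25 sweeps)
  std::vector<double> polish_trace;
  polish_trace.push_back(st.total_objective());
  for (int s = 0; s < 25; ++s) {
    int moved = st.sweep(0.0, rng, order, cand);
    polish_trace.push_back(st.total_objective());
    if (moved == 0) break;
  }

  return List::create(
      _["assignment"] = IntegerVector(st.assign.begin(), st.assign.end()),
      _["align_choice"] = IntegerVector(st.ach.begin(), st.ach.end()),
      _["polish_trace"] = NumericVector(polish_trace.begin(),
                                        polish_trace.end()));
}
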