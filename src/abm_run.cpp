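// Individual-based Wright-Fisher simulation of bit-string prophages.
//
// Each bacterial genome carries (at most) one prophage locus laid out as
// [B genes | E genes | R genes | N genes]; per gene we track presence
// (deleted = absent) and the number of sustained TE disruptions. A gene is
// functional iff present and undisrupted. Per bacterial generation, in
// order: gene deletion -> TE disruption -> induction -> reproduction pool
// (baseline copy + selection copy + re-infection copy) -> carrying-capacity
// regulation. All event probabilities are rate * dt, valid for small r*dt.
//
// Uses R's RNG so runs are reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Genome {
  std::vector<uint8_t> present;
  std::vector<uint16_t> te;
};

inline bool all_functional(const Genome& g, int from, int to) {
  for (int j = from; j < to; ++j)
    if (!g.present[j] || g.te[j] > 0) return false;
  return true;
}

} // namespace

// [[Rcpp::export]]
List abm_run_cpp(int n_B, int n_E, int n_R, int n_N,
                 double r_D, double r_I, double r_L, double r_S, double r_T,
                 int K, double dt, int n_steps, int record_every,
                 bool halt_on_extinction) {
  const int G = n_B + n_E + n_R + n_N;
  const int e0 = n_B, e1 = n_B + n_E;        // excision block [e0, e1)
  const int r1 = n_B + n_E + n_R;            // re-infection block [e1, r1)
  const double pD = r_D * dt, pT = r_T * dt, pI = r_I * dt;
  const double pS = r_S * dt, pL = r_L * dt;

  Genome full;
  full.present.assign(G, 1);
  full.te.assign(G, 0);
  std::vector<Genome> pop(K, full), pool;
  pool.reserve(2 * K + 16);

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix rec(n_rec, 11);
  colnames(rec) = CharacterVector::create(
    "generation", "pop_size", "func_B", "func_E", "func_R", "func_N",
    "te_B", "te_E", "te_R", "te_N", "frac_er_intact");

  int row = 0;
  bool extinct_halt = false;

  auto record = [&](int gen) {
    const double N = static_cast<double>(pop.size());
    double fb = 0, fe = 0, fr = 0, fn = 0;
    double tb = 0, teE = 0, tr = 0, tn = 0;
    double er = 0;
    for (const Genome& g : pop) {
      for (int j = 0; j < G; ++j) {
        if (!g.present[j]) continue;
        const bool func = g.te[j] == 0;
        if (j < e0)      { tb += g.te[j]; if (func) fb += 1; }
        else if (j < e1) { teE += g.te[j]; if (func) fe += 1; }
        else if (j < r1) { tr += g.te[j]; if (func) fr += 1; }
        else             { tn += g.te[j]; if (func) fn += 1; }
      }
      if (all_functional(g, e0, r1)) er += 1;
    }
    rec(row, 0) = gen;
    rec(row, 1) = N;
    if (N > 0) {
      rec(row, 2) = fb / N;  rec(row, 3) = fe / N;
      rec(row, 4) = fr / N;  rec(row, 5) = fn / N;
      rec(row, 6) = tb / N;  rec(row, 7) = teE / N;
      rec(row, 8) = tr / N;  rec(row, 9) = tn / N;
      rec(row, 10) = er / N;
    }
    ++row;
  };

  record(0);

  for (int gen = 1; gen <= n_steps; ++gen) {
    if (!pop.empty()) {
      // deletion then TE disruption, one pass (TE only strikes survivors)
      for (Genome& g : pop) {
        for (int j = 0; j < G; ++j) {
          if (!g.present[j]) continue;
          if (pD > 0 && unif_rand() < pD) {
            g.present[j] = 0;
            g.te[j] = 0;            // deletion removes any embedded IS
          } else if (pT > 0 && unif_rand() < pT) {
            ++g.te[j];
          }
        }
      }

      // induction kills hosts whose excision genes are all functional,
      // then survivors seed the reproduction pool
      pool.clear();
      for (Genome& g : pop) {
        const bool e_func = all_functional(g, e0, e1);
        if (e_func && pI > 0 && unif_rand() < pI) continue;  // host lysed
        pool.push_back(g);
        if (pS > 0 && n_B > 0) {
          int nb = 0;
          for (int j = 0; j < e0; ++j)
            if (g.present[j] && g.te[j] == 0) ++nb;
          if (nb > 0 &&
              unif_rand() < pS * static_cast<double>(nb) / n_B)
            pool.push_back(g);
        }
        if (pL > 0 && e_func && all_functional(g, e1, r1) &&
            unif_rand() < pL)
          pool.push_back(g);
      }

      // carrying-capacity regulation
      if (static_cast<int>(pool.size()) > K) {
        const double keep = static_cast<double>(K) / pool.size();
        pop.clear();
        for (Genome& g : pool)
          if (unif_rand() < keep) pop.push_back(std::move(g));
      } else {
        pop.swap(pool);
      }
    }

    if (gen % record_every == 0) record(gen);

    if (pop.empty() && halt_on_extinction) {
      extinct_halt = true;
      // emit the remaining scheduled records as zero-size rows
      for (int g2 = (gen / record_every + 1) * record_every;
           g2 <= n_steps; g2 += record_every)
        record(g2);
      break;
    }
  }

  const int N = static_cast<int>(pop.size());
  IntegerMatrix present(N, G), te(N, G);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < G; ++j) {
      present(i, j) = pop[i].present[j];
      te(i, j) = pop[i].te[j];
    }

  return List::create(_["summary"] = rec,
                      _["present"] = present,
                      _["te"] = te,
                      _["halted"] = extinct_halt);
}
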