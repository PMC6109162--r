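// Structured coalescent for a fixed population tree with piecewise-constant
// diploid effective sizes and no migration.
//
// Populations are indexed 0..P-1.  Sampled lineages start in the first
// G populations (G = length of n_samp); "merge" events move all lineages of
// one population into another at a fixed time (backwards in time), which is
// how population splits are encoded.  Within a population holding k
// lineages coalescence occurs at rate k(k-1)/2 * 1/(2 Ne(t)) per
// generation.  Each replicate yields one genealogy; a single mutation is
// placed on a branch chosen proportionally to branch length
// (infinite-sites, one segregating site per replicate) and the
// derived-allele count per sampled population is returned.
//
// Uses R's RNG so results are reproducible via set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Branch {
  double len;
  std::vector<int> cnt; // descendant leaves per sampled population
};

struct SimState {
  double tmrca;
  double total_len;
  std::vector<Branch> branches;
};

double pop_ne(const NumericMatrix& ep, double t) {
  // rows: (start_generation, diploid Ne), starts ascending, first start 0
  int row = 0;
  for (int r = 0; r < ep.nrow(); ++r) {
    if (ep(r, 0) <= t) row = r; else break;
  }
  return ep(row, 1);
}

double next_boundary(const std::vector<NumericMatrix>& epochs,
                     const NumericMatrix& merges, double t) {
  double nb = R_PosInf;
  for (const auto& ep : epochs)
    for (int r = 0; r < ep.nrow(); ++r)
      if (ep(r, 0) > t && ep(r, 0) < nb) nb = ep(r, 0);
  for (int r = 0; r < merges.nrow(); ++r)
    if (merges(r, 0) > t && merges(r, 0) < nb) nb = merges(r, 0);
  return nb;
}

// one genealogy; returns branches with leaf-count vectors
SimState simulate_tree(const IntegerVector& n_samp,
                       const std::vector<NumericMatrix>& epochs,
                       const NumericMatrix& merges) {
  const int P = (int)epochs.size();
  const int G = n_samp.size();
  int total = 0;
  for (int g = 0; g < G; ++g) total += n_samp[g];

  // lineage pool: leaf counts and birth times
  std::vector< std::vector<int> > cnt;
  std::vector<double> birth;
  std::vector< std::vector<int> > pop(P); // lineage ids per population
  cnt.reserve(2 * total);
  birth.reserve(2 * total);
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < n_samp[g]; ++i) {
      std::vector<int> c(G, 0);
      c[g] = 1;
      pop[g].push_back((int)cnt.size());
      cnt.push_back(c);
      birth.push_back(0.0);
    }
  }

  SimState st;
  st.total_len = 0.0;
  st.branches.reserve(2 * total);

  double t = 0.0;
  int active = total;
  int merge_done = 0;

  while (active > 1) {
    // apply any merges due at (or before) the current time, including t = 0
    while (merge_done < merges.nrow() && merges(merge_done, 0) <= t) {
      int from = (int)merges(merge_done, 1);
      int to = (int)merges(merge_done, 2);
      for (int id : pop[from]) pop[to].push_back(id);
      pop[from].clear();
      ++merge_done;
    }
    // total coalescence rate at current time
    double lambda = 0.0;
    std::vector<double> rate(P, 0.0);
    for (int p = 0; p < P; ++p) {
      double k = (double)pop[p].size();
      if (k >= 2.0) {
        rate[p] = k * (k - 1.0) / 2.0 / (2.0 * pop_ne(epochs[p], t));
        lambda += rate[p];
      }
    }
    double nb = next_boundary(epochs, merges, t);
    double dt = (lambda > 0.0) ? R::rexp(1.0 / lambda) : R_PosInf;
    if (t + dt >= nb) {
      if (!R_FINITE(nb))
        stop("coalescent cannot finish: no events possible (check merges)");
      t = nb;
      continue;  // merges/epoch changes take effect at the top of the loop
    }
    t += dt;
    // choose population proportional to rate
    double u = R::runif(0.0, lambda);
    int p = 0;
    double acc = 0.0;
    for (; p < P; ++p) {
      acc += rate[p];
      if (u <= acc || p == P - 1) break;
    }
    while (rate[p] <= 0.0) --p; // numerical guard
    // choose an unordered pair uniformly
    int k = (int)pop[p].size();
    int i = (int)(R::unif_rand() * k);
    if (i >= k) i = k - 1;
    int j = (int)(R::unif_rand() * (k - 1));
    if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    int li = pop[p][i], lj = pop[p][j];
    // close both child branches
    for (int id : {li, lj}) {
      Branch b;
      b.len = t - birth[id];
      b.cnt = cnt[id];
      st.total_len += b.len;
      st.branches.push_back(std::move(b));
    }
    // parent lineage replaces slot i; remove slot j (swap with back)
    std::vector<int> merged(G);
    for (int g = 0; g < G; ++g) merged[g] = cnt[li][g] + cnt[lj][g];
    int parent = (int)cnt.size();
    cnt.push_back(merged);
    birth.push_back(t);
    pop[p][i] = parent;
    pop[p][j] = pop[p].back();
    pop[p].pop_back();
    --active;
  }
  st.tmrca = t;
  return st;
}

} // namespace

// [[Rcpp::export]]
List coal_sim_cpp(IntegerVector n_samp, List epochs_list, NumericMatrix merges,
                  int n_reps, bool require_poly2, int max_tries) {
  const int G = n_samp.size();
  std::vector<NumericMatrix> epochs;
  for (int i = 0; i < epochs_list.size(); ++i)
    epochs.push_back(as<NumericMatrix>(epochs_list[i]));

  IntegerMatrix derived(n_reps, G);
  NumericVector tmrca(n_reps), tlen(n_reps);
  long redraws = 0;

  for (int rep = 0; rep < n_reps; ++rep) {
    bool accepted = false;
    for (int attempt = 0; attempt < max_tries; ++attempt) {
      SimState st = simulate_tree(n_samp, epochs, merges);
      // place one mutation proportional to branch length
      double x = R::unif_rand() * st.total_len;
      const Branch* hit = &st.branches.back();
      double acc = 0.0;
      for (const Branch& b : st.branches) {
        acc += b.len;
        if (x <= acc) { hit = &b; break; }
      }
      if (require_poly2) {
        int npoly = 0;
        for (int g = 0; g < G; ++g)
          if (hit->cnt[g] > 0 && hit->cnt[g] < n_samp[g]) ++npoly;
        if (npoly < 2) { ++redraws; continue; }
      }
      for (int g = 0; g < G; ++g) derived(rep, g) = hit->cnt[g];
      tmrca[rep] = st.tmrca;
      tlen[rep] = st.total_len;
      accepted = true;
      break;
    }
    if (!accepted)
      stop("coalescent null: acceptance rate too low under the polymorphism "
           "filter (no accepted replicate in %d tries)", max_tries);
  }
  return List::create(_["derived"] = derived, _["tmrca"] = tmrca,
                      _["total_length"] = tlen,
                      _["redraws"] = (double)redraws);
}
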