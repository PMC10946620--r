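#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Structured-coalescent simulator for K demes with backward migration and a
// schedule of deme-merge events (looking backward in time, the 'source' deme
// is absorbed into 'dest' at the event time and dest may change size).
//
// Time is measured in generations; deme sizes are diploid Ne, so k lineages
// in a deme coalesce at rate k(k-1)/(4 Ne) and each lineage migrates from
// deme i to deme j at the backward rate migration(i, j).
//
// For every branch segment the simulator records the per-deme counts of
// present-day samples subtended by the carrying lineage ("configuration"),
// accumulating segment lengths into a dense array indexed by configuration.
// Branch-length accumulation gives a Rao-Blackwellized estimate of the
// expected SFS under infinite sites; when mu > 0 and want_sites is true,
// Poisson mutations are also dropped on segments to produce realized site
// data per locus.
//
// Returns: tmrca (per locus), config_lengths (flattened array over
// prod(sample_sizes + 1) cells, summed over loci), and optionally a site
// matrix with columns (locus, count_deme1, ..., count_demeK).
// [[Rcpp::export]]
List coalescent_sim_cpp(IntegerVector sample_sizes,
                        NumericVector deme_ne,
                        NumericMatrix migration,
                        NumericMatrix events,
                        int n_loci,
                        double mu,
                        double locus_length,
                        int seed,
                        bool want_sites,
                        int max_events_per_locus = 3000) {
  const int K = sample_sizes.size();
  if (deme_ne.size() != K || migration.nrow() != K || migration.ncol() != K)
    stop("inconsistent deme dimensions");
  const int n_events = events.nrow();
  for (int e = 1; e < n_events; ++e)
    if (events(e, 0) < events(e - 1, 0)) stop("events must be sorted by time");

  // configuration index strides
  std::vector<std::int64_t> stride(K);
  std::int64_t ncell = 1;
  for (int d = 0; d < K; ++d) {
    stride[d] = ncell;
    ncell *= (std::int64_t)sample_sizes[d] + 1;
  }
  if (ncell > 50000000) stop("configuration space too large");
  std::vector<double> acc((size_t)ncell, 0.0);

  std::mt19937_64 rng((std::uint64_t)seed + 0x9e3779b97f4a7c15ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  NumericVector tmrca(n_loci);
  std::vector<int> site_rows; // locus, cfg[0..K-1]
  std::vector<int> members;
  members.reserve(64);

  const int n_total = sum(sample_sizes);
  // a lineage's configuration changes only at coalescences, so branch
  // lengths are accumulated lazily: each lineage remembers its birth time
  // and is flushed into the configuration table when it coalesces
  struct Lineage { int deme; double birth; std::vector<int> cfg; };

  for (int locus = 0; locus < n_loci; ++locus) {
    std::vector<Lineage> lin;
    lin.reserve(n_total);
    for (int d = 0; d < K; ++d)
      for (int s = 0; s < sample_sizes[d]; ++s) {
        Lineage L; L.deme = d; L.birth = 0.0; L.cfg.assign(K, 0);
        L.cfg[d] = 1;
        lin.push_back(L);
      }
    auto flush = [&](const Lineage &L, double now) {
      double len = now - L.birth;
      if (len <= 0.0) return;
      std::int64_t idx = 0;
      for (int d = 0; d < K; ++d) idx += stride[d] * L.cfg[d];
      acc[(size_t)idx] += len;
      if (want_sites && mu > 0.0) {
        std::poisson_distribution<int> pois(mu * locus_length * len);
        int nm = pois(rng);
        for (int m = 0; m < nm; ++m) {
          site_rows.push_back(locus + 1);
          for (int d = 0; d < K; ++d) site_rows.push_back(L.cfg[d]);
        }
      }
    };
    std::vector<double> ne(deme_ne.begin(), deme_ne.end());
    std::vector<bool> alive(K, true);
    double t = 0.0;
    int ev = 0;
    int n_steps = 0;
    bool collapsed = false;

    while ((int)lin.size() > 1) {
      // strong-migration limit: when migration events dominate the locus
      // (event budget exhausted), the demes are effectively well mixed;
      // collapse the alive demes into one panmictic deme with the
      // harmonic-mean effective size K^2 / sum(1/Ne_d)
      if (!collapsed && ++n_steps > max_events_per_locus) {
        int surv = -1, n_alive = 0;
        double invsum = 0.0;
        for (int d = 0; d < K; ++d)
          if (alive[d]) { if (surv < 0) surv = d; n_alive++; invsum += 1.0 / ne[d]; }
        if (n_alive > 1) {
          for (auto &L : lin) L.deme = surv;
          for (int d = 0; d < K; ++d) if (d != surv) alive[d] = false;
          ne[surv] = (double)n_alive * n_alive / invsum;
        }
        collapsed = true;
      }
      // per-deme lineage counts
      std::vector<int> k(K, 0);
      for (const auto &L : lin) k[L.deme]++;
      double rate = 0.0;
      std::vector<double> coal_rate(K, 0.0), mig_rate(K, 0.0);
      for (int d = 0; d < K; ++d) {
        if (k[d] >= 2)
          coal_rate[d] = (double)k[d] * (k[d] - 1) / (4.0 * ne[d]);
        double mrow = 0.0;
        if (k[d] >= 1 && alive[d])
          for (int j = 0; j < K; ++j)
            if (j != d && alive[j]) mrow += migration(d, j);
        mig_rate[d] = k[d] * mrow;
        rate += coal_rate[d] + mig_rate[d];
      }
      double dt;
      bool at_event = false;
      if (rate > 0.0) {
        dt = -std::log(unif(rng)) / rate;
      } else {
        if (ev >= n_events) stop("lineages cannot coalesce: no events left and zero rate");
        dt = events(ev, 0) - t;
        at_event = true;  // forced: nothing can happen before the next merge
      }
      if (!at_event && ev < n_events && t + dt >= events(ev, 0)) {
        dt = events(ev, 0) - t;
        at_event = true;
      }
      if (dt < 0.0) dt = 0.0;
      t += dt;
      if (at_event) {
        t = events(ev, 0);  // snap: avoids ulp drift past the merge time
        int src = (int)events(ev, 1), dst = (int)events(ev, 2);
        for (auto &L : lin) if (L.deme == src) L.deme = dst;
        alive[src] = false;
        ne[dst] = events(ev, 3);
        ev++;
        continue;
      }
      // pick an event among the positive-rate channels (2d = coalescence
      // in deme d, 2d+1 = migration out of deme d); on numerical round-off
      // fall back to the last positive channel
      double u = unif(rng) * rate;
      int chosen_deme = -1;
      bool is_coal = false;
      for (int d = 0; d < K; ++d) {
        if (coal_rate[d] > 0.0) {
          if (u < coal_rate[d]) { chosen_deme = d; is_coal = true; break; }
          u -= coal_rate[d];
        }
        if (mig_rate[d] > 0.0) {
          if (u < mig_rate[d]) { chosen_deme = d; is_coal = false; break; }
          u -= mig_rate[d];
        }
      }
      if (chosen_deme < 0) {
        for (int d = K - 1; d >= 0; --d) {
          if (mig_rate[d] > 0.0) { chosen_deme = d; is_coal = false; break; }
          if (coal_rate[d] > 0.0) { chosen_deme = d; is_coal = true; break; }
        }
      }
      if (chosen_deme < 0) stop("internal error: no event channel available");
      // indices of lineages in chosen deme (reused buffer)
      members.clear();
      for (int i = 0; i < (int)lin.size(); ++i)
        if (lin[i].deme == chosen_deme) members.push_back(i);
      if (is_coal) {
        int a = (int)(unif(rng) * members.size());
        int b = (int)(unif(rng) * (members.size() - 1));
        if (b >= a) b++;
        int ia = members[a], ib = members[b];
        flush(lin[ia], t);
        flush(lin[ib], t);
        for (int d = 0; d < K; ++d) lin[ia].cfg[d] += lin[ib].cfg[d];
        lin[ia].birth = t;
        lin.erase(lin.begin() + ib);
      } else {
        // migration: destination proportional to row rates among alive demes
        double mrow = 0.0;
        for (int j = 0; j < K; ++j)
          if (j != chosen_deme && alive[j]) mrow += migration(chosen_deme, j);
        double v = unif(rng) * mrow;
        int dest = -1;
        for (int j = 0; j < K; ++j) {
          if (j == chosen_deme || !alive[j]) continue;
          if (v < migration(chosen_deme, j)) { dest = j; break; }
          v -= migration(chosen_deme, j);
        }
        if (dest < 0) { for (int j = K - 1; j >= 0; --j) if (j != chosen_deme && alive[j]) { dest = j; break; } }
        int i = members[(int)(unif(rng) * members.size())];
        lin[i].deme = dest;
      }
    }
    tmrca[locus] = t;
  }

  List out = List::create(_["tmrca"] = tmrca,
                          _["config_lengths"] = NumericVector(acc.begin(), acc.end()));
  if (want_sites) {
    int nr = (int)(site_rows.size() / (K + 1));
    IntegerMatrix sites(nr, K + 1);
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c <= K; ++c) sites(r, c) = site_rows[(size_t)r * (K + 1) + c];
    out["sites"] = sites;
  }
  return out;
}
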