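#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fixed-step Monte Carlo on a 1D lattice pore with two particle species
// entering at either end.  With exclusion on, a site holds at most one
// particle and hops/entries into occupied sites are rejected; with exclusion
// off particles are independent random walkers.  A traversal (entered one
// end, exited the other) is the countable "crossing".
//
// Uses R's RNG (unif_rand) so results follow set.seed() on the R side.
// [[Rcpp::export]]
List cpp_lattice(int n_sites,
                 double pA_left, double pA_right,
                 double pB_left, double pB_right,
                 double p_hop, bool exclusion,
                 int n_steps, int record_every) {
  std::vector<int> species;  // 0 = A, 1 = B
  std::vector<int> origin;   // 0 = entered left, 1 = entered right
  std::vector<int> pos;      // 1..n_sites
  std::vector<int> site_n(n_sites + 2, 0);  // occupancy count per site (1-based)

  int a_lr = 0, a_rl = 0, b_lr = 0, b_rl = 0;
  int max_site_occ = 0;
  std::vector<double> occ_trace;
  occ_trace.reserve(n_steps / record_every + 1);

  auto try_enter = [&](int sp, int end, double p) {
    if (p <= 0.0 || unif_rand() >= p) return;
    const int s = (end == 0) ? 1 : n_sites;
    if (exclusion && site_n[s] > 0) return;
    species.push_back(sp);
    origin.push_back(end);
    pos.push_back(s);
    if (++site_n[s] > max_site_occ) max_site_occ = site_n[s];
  };

  for (int step = 0; step < n_steps; ++step) {
    try_enter(0, 0, pA_left);
    try_enter(0, 1, pA_right);
    try_enter(1, 0, pB_left);
    try_enter(1, 1, pB_right);

    // hop particles in random order (Fisher-Yates over indices)
    const int np = (int)pos.size();
    std::vector<int> order(np);
    for (int i = 0; i < np; ++i) order[i] = i;
    for (int i = np - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }

    std::vector<int> gone;
    for (int oi = 0; oi < np; ++oi) {
      const int i = order[oi];
      if (pos[i] < 0) continue;
      if (unif_rand() >= p_hop) continue;
      const int dir = (unif_rand() < 0.5) ? -1 : 1;
      const int dest = pos[i] + dir;
      if (dest < 1 || dest > n_sites) {
        // exit; a traversal if the exit side differs from the entry side
        const int exit_side = (dest < 1) ? 0 : 1;
        if (exit_side != origin[i]) {
          const bool lr = (origin[i] == 0);
          if (species[i] == 0) { if (lr) ++a_lr; else ++a_rl; }
          else                 { if (lr) ++b_lr; else ++b_rl; }
        }
        --site_n[pos[i]];
        pos[i] = -1;
        gone.push_back(i);
        continue;
      }
      if (exclusion && site_n[dest] > 0) continue;
      --site_n[pos[i]];
      pos[i] = dest;
      if (++site_n[dest] > max_site_occ) max_site_occ = site_n[dest];
    }

    // compact out exited particles
    if (!gone.empty()) {
      std::vector<int> s2, o2, p2;
      s2.reserve(pos.size()); o2.reserve(pos.size()); p2.reserve(pos.size());
      for (size_t i = 0; i < pos.size(); ++i) {
        if (pos[i] >= 0) { s2.push_back(species[i]); o2.push_back(origin[i]); p2.push_back(pos[i]); }
      }
      species.swap(s2); origin.swap(o2); pos.swap(p2);
    }

    if ((step + 1) % record_every == 0) {
      int occupied = 0;
      for (int s = 1; s <= n_sites; ++s) if (site_n[s] > 0) ++occupied;
      occ_trace.push_back((double)occupied / n_sites);
    }
  }

  return List::create(
    _["a_lr"] = a_lr, _["a_rl"] = a_rl,
    _["b_lr"] = b_lr, _["b_rl"] = b_rl,
    _["occupancy"] = NumericVector(occ_trace.begin(), occ_trace.end()),
    _["max_site_occupancy"] = max_site_occ,
    _["n_in_pore"] = (int)pos.size());
}
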