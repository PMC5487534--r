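#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Deterministic 1D-lattice engine for one starvation-induced expression
// episode: RNA polymerases on the DNA, ribosomes and one RNase per nascent
// transcript.  Agents hop velo*dt nucleotides per tick; minimum spacings
// and per-gene translation quotas gate movement.  With the default
// dt = 1/velo every hop is exactly one nucleotide.

namespace {

const double TOL = 1e-9;

struct Strand {
  double x;                  // RNAP position; == op_length once complete
  bool complete;             // RNAP reached the terminator and detached
  std::vector<double> y;     // ribosome positions, descending (leader first)
  std::vector<int> gene;     // gene index per ribosome, parallel to y
  std::vector<int> init_cnt; // translation initiations per gene (Iverson sum)
  std::vector<int> comp_cnt; // completed translations per gene
  double z;                  // RNase position, 0 = start of transcript
  bool degraded;             // z swept the full transcript
  double len() const { return complete ? x : x; }
};

} // namespace

// [[Rcpp::export(name = ".sim_episode_cpp")]]
List sim_episode_cpp(double op_length,
                     NumericVector c_start,
                     NumericVector c_end,
                     IntegerVector quota,
                     double velo_rnap,
                     double velo_ribosome,
                     double velo_rnase,
                     double delta_x,
                     double delta_y,
                     double delta_z,
                     double t_start,
                     double t_end,
                     double dt,
                     double horizon) {
  const int G = c_start.size();
  const double step_x = velo_rnap * dt;
  const double step_y = velo_ribosome * dt;
  const double step_z = velo_rnase * dt;

  const long k_start = (long)std::ceil(t_start / dt - TOL);
  const long k_end = (long)std::floor(t_end / dt + TOL);
  const long k_max = (long)std::floor(horizon / dt + TOL);

  std::vector<Strand> strands;
  strands.reserve(64);
  std::vector<long> protein(G, 0);
  long n_initiated = 0, n_complete = 0;
  double last_degraded_at = 0.0;
  bool truncated = false;

  // sampled trace, tick 0 included
  std::vector<double> times;
  times.reserve(k_max + 1);
  std::vector<std::vector<int>> mrna_tr(G), prot_tr(G);
  for (int g = 0; g < G; ++g) {
    mrna_tr[g].reserve(k_max + 1);
    prot_tr[g].reserve(k_max + 1);
  }
  times.push_back(0.0);
  for (int g = 0; g < G; ++g) {
    mrna_tr[g].push_back(0);
    prot_tr[g].push_back(0);
  }

  // the induction window is a closed interval; if it opens at (or before)
  // time zero the first initiation happens at t = 0, before any tick
  if (k_start <= 0 && 0 <= k_end) {
    Strand s;
    s.x = 0.0;
    s.complete = false;
    s.init_cnt.assign(G, 0);
    s.comp_cnt.assign(G, 0);
    s.z = 0.0;
    s.degraded = false;
    strands.push_back(s);
    ++n_initiated;
  }

  long k = 0;
  while (true) {
    if (k >= k_max) {
      // horizon reached before the episode closed
      bool all_gone = true;
      for (const Strand& s : strands)
        if (!s.degraded) { all_gone = false; break; }
      truncated = !(k > k_end && all_gone);
      break;
    }
    ++k;
    const double t = k * dt;

    // --- RNAP movement, most-downstream (oldest) strand first -------------
    bool have_prev = false;
    double prev_x = 0.0;
    for (size_t i = 0; i < strands.size(); ++i) {
      Strand& s = strands[i];
      if (s.complete) { have_prev = false; continue; }
      if (!have_prev || prev_x - s.x >= delta_x - TOL) {
        s.x += step_x;
        if (s.x >= op_length - TOL) {
          s.x = op_length;
          s.complete = true;
          ++n_complete;
        }
      }
      if (s.complete) {
        have_prev = false;
      } else {
        have_prev = true;
        prev_x = s.x;
      }
    }

    // --- ribosome movement, leader first; then per-gene initiation --------
    for (size_t i = 0; i < strands.size(); ++i) {
      Strand& s = strands[i];
      if (s.degraded) continue;
      const double L = s.complete ? op_length : s.x;
      if (!s.y.empty()) {
        std::vector<double> ny;
        std::vector<int> ng;
        ny.reserve(s.y.size());
        ng.reserve(s.y.size());
        bool have_lead = false;
        double lead_y = 0.0;
        for (size_t j = 0; j < s.y.size(); ++j) {
          double yj = s.y[j];
          const int gj = s.gene[j];
          const bool template_halt = !s.complete && (L - yj <= delta_y + TOL);
          const bool lead_halt = have_lead && (lead_y - yj < delta_y - TOL);
          if (!template_halt && !lead_halt) yj += step_y;
          if (yj > c_end[gj] + TOL) {
            // translation completed: ribosome detaches, one protein
            ++s.comp_cnt[gj];
            ++protein[gj];
          } else {
            ny.push_back(yj);
            ng.push_back(gj);
            have_lead = true;
            lead_y = yj;
          }
        }
        s.y.swap(ny);
        s.gene.swap(ng);
      }
      // initiation: at most one new ribosome per gene per tick
      for (int g = 0; g < G; ++g) {
        if (s.init_cnt[g] >= quota[g]) continue;
        const bool lookahead_ok =
            s.complete || (L - c_start[g] >= delta_y - TOL);
        if (!lookahead_ok) continue;
        // nearest ribosome at or downstream of the start codon
        bool blocked = false;
        size_t ins = s.y.size();
        for (size_t j = s.y.size(); j-- > 0;) {
          if (s.y[j] >= c_start[g] - TOL) {
            blocked = s.y[j] - c_start[g] < delta_y - TOL;
            ins = j + 1;
            break;
          }
          ins = j;
        }
        if (blocked) continue;
        s.y.insert(s.y.begin() + ins, c_start[g]);
        s.gene.insert(s.gene.begin() + ins, g);
        ++s.init_cnt[g];
      }
    }

    // --- RNase movement ----------------------------------------------------
    for (size_t i = 0; i < strands.size(); ++i) {
      Strand& s = strands[i];
      if (s.degraded) continue;
      const double L = s.complete ? op_length : s.x;
      if (!s.y.empty() && s.y.back() - s.z <= delta_z + TOL) continue;
      double cap = L;
      for (int g = 0; g < G; ++g) {
        if (s.init_cnt[g] < quota[g]) {
          if (c_start[g] - 1.0 < cap) cap = c_start[g] - 1.0;
          break; // genes are ordered 5'->3'; first open quota caps first
        }
      }
      double zn = s.z + step_z;
      if (zn > cap) zn = cap;
      if (zn > s.z) s.z = zn;
      if (s.complete && s.z >= op_length - TOL) {
        s.z = op_length;
        s.degraded = true;
        last_degraded_at = t;
      }
    }

    // --- RNAP initiation (the first elongation step) -----------------------
    if (k >= k_start && k <= k_end) {
      bool clear = true;
      if (!strands.empty()) {
        const Strand& tail = strands.back();
        if (!tail.complete && tail.x < delta_x - TOL) clear = false;
      }
      if (clear) {
        // appended at the reserved position 0; the first elongation step
        // (= the initiation step proper) is taken on the next tick, so the
        // leader sits exactly delta_x ahead and the initiation cadence is
        // delta_x / velo_rnap, matching the closed-form strand count
        Strand s;
        s.x = 0.0;
        s.complete = false;
        s.init_cnt.assign(G, 0);
        s.comp_cnt.assign(G, 0);
        s.z = 0.0;
        s.degraded = false;
        strands.push_back(s);
        ++n_initiated;
      }
    }

    // --- census: synthesized minus degraded, per gene ----------------------
    // a strand carries gene g while transcription has reached the gene's
    // first nucleotide and the RNase has not yet passed it
    times.push_back(t);
    for (int g = 0; g < G; ++g) {
      int m = 0;
      for (const Strand& s : strands) {
        const double L = s.complete ? op_length : s.x;
        const int syn = (L >= c_start[g] - TOL) ? 1 : 0;
        const int deg = (s.z >= c_start[g] - TOL) ? 1 : 0;
        const int c = syn - deg;
        if (c > 0) m += c;
      }
      mrna_tr[g].push_back(m);
      prot_tr[g].push_back((int)protein[g]);
    }

    if (k > k_end) {
      bool all_gone = true;
      for (const Strand& s : strands)
        if (!s.degraded) { all_gone = false; break; }
      if (all_gone) break;
    }
  }

  const R_xlen_t n = (R_xlen_t)times.size();
  NumericVector times_out(times.begin(), times.end());
  IntegerMatrix mrna_out(n, G), prot_out(n, G);
  for (int g = 0; g < G; ++g) {
    for (R_xlen_t s = 0; s < n; ++s) {
      mrna_out(s, g) = mrna_tr[g][s];
      prot_out(s, g) = prot_tr[g][s];
    }
  }
  IntegerVector final_protein(G);
  for (int g = 0; g < G; ++g) final_protein[g] = (int)protein[g];

  return List::create(
      _["times"] = times_out,
      _["mrna"] = mrna_out,
      _["protein"] = prot_out,
      _["episode_length"] = last_degraded_at,
      _["n_initiated"] = (int)n_initiated,
      _["n_complete"] = (int)n_complete,
      _["truncated"] = truncated,
      _["final_protein"] = final_protein);
}
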