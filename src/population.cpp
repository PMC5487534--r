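#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Stochastic cell-distribution engine for the STR-PFR loop.  Three
// first-order events drive the STR population -- PFR entry, washout and
// division (the division propensity uses the constant reference cell
// number, which is what makes the population self-stabilising) -- solved
// with Gillespie's direct method.  PFR transit is a deterministic delay:
// scheduled returns are interleaved with the SSA draws and, because the
// exponential clock is memoryless, the draw simply restarts after each
// executed return.  Uses R's RNG so set.seed() governs reproducibility.

// event codes: 1 = pfr_entry, 2 = washout, 3 = division, 4 = pfr_return

// [[Rcpp::export(name = ".sim_population_cpp")]]
List sim_population_cpp(int n0,
                        double entry_coef,    // per-STR-cell hazard, 1/s
                        double washout_coef,  // per-STR-cell hazard, 1/s
                        double division_rate, // constant propensity, 1/s
                        double tau_pfr,       // deterministic transit, s
                        double duration) {    // simulated span, s
  std::vector<double> born_at(n0, 0.0);
  std::vector<double> removed_at(n0, R_PosInf);

  std::vector<int> str_ids(n0);
  std::vector<int> pos(n0);
  for (int i = 0; i < n0; ++i) { str_ids[i] = i; pos[i] = i; }

  std::vector<double> pfr_time; // scheduled return times, FIFO
  std::vector<int> pfr_id;
  size_t pfr_head = 0;

  std::vector<double> ev_time;
  std::vector<int> ev_type, ev_cell;
  const size_t guess = (size_t)std::min(
      5e7, 16.0 + duration * (n0 * (entry_coef + washout_coef) * 2.2 +
                              division_rate));
  ev_time.reserve(guess);
  ev_type.reserve(guess);
  ev_cell.reserve(guess);

  double t = 0.0;
  while (true) {
    const int n_str = (int)str_ids.size();
    const double a1 = n_str * entry_coef;
    const double a2 = n_str * washout_coef;
    const double A = a1 + a2 + division_rate;

    double r1 = unif_rand();
    if (r1 <= 0.0) r1 = DBL_MIN;
    const double tau = -std::log(r1) / A;
    const double t_next = t + tau;

    const bool have_return = pfr_head < pfr_time.size();
    if (have_return && pfr_time[pfr_head] <= t_next) {
      const double tr = pfr_time[pfr_head];
      if (tr > duration) break;
      const int id = pfr_id[pfr_head];
      ++pfr_head;
      t = tr;
      pos[id] = (int)str_ids.size();
      str_ids.push_back(id);
      ev_time.push_back(t);
      ev_type.push_back(4);
      ev_cell.push_back(id + 1);
      continue; // memoryless: redraw from the return time
    }
    if (t_next > duration) break;
    t = t_next;

    const double r2 = unif_rand() * A;
    if (r2 < a1 && n_str > 0) {
      // uniformly chosen STR cell enters the PFR
      int j = (int)(unif_rand() * n_str);
      if (j >= n_str) j = n_str - 1;
      const int id = str_ids[j];
      const int last = str_ids.back();
      str_ids[j] = last;
      pos[last] = j;
      str_ids.pop_back();
      pos[id] = -1;
      pfr_time.push_back(t + tau_pfr);
      pfr_id.push_back(id);
      ev_time.push_back(t);
      ev_type.push_back(1);
      ev_cell.push_back(id + 1);
    } else if (r2 < a1 + a2 && n_str > 0) {
      // washout: uniformly chosen STR cell leaves the system
      int j = (int)(unif_rand() * n_str);
      if (j >= n_str) j = n_str - 1;
      const int id = str_ids[j];
      const int last = str_ids.back();
      str_ids[j] = last;
      pos[last] = j;
      str_ids.pop_back();
      pos[id] = -1;
      removed_at[id] = t;
      ev_time.push_back(t);
      ev_type.push_back(2);
      ev_cell.push_back(id + 1);
    } else {
      // division: default daughter cell appended to the STR
      const int id = (int)born_at.size();
      born_at.push_back(t);
      removed_at.push_back(R_PosInf);
      pos.push_back((int)str_ids.size());
      str_ids.push_back(id);
      ev_time.push_back(t);
      ev_type.push_back(3);
      ev_cell.push_back(id + 1);
    }
  }

  const int n_cells = (int)born_at.size();
  IntegerVector location(n_cells, 0); // 0 STR, 1 PFR, 2 removed
  NumericVector exit_due(n_cells, NA_REAL);
  for (int i = 0; i < n_cells; ++i)
    if (!std::isinf(removed_at[i])) location[i] = 2;
  for (size_t q = pfr_head; q < pfr_id.size(); ++q) {
    location[pfr_id[q]] = 1;
    exit_due[pfr_id[q]] = pfr_time[q];
  }

  return List::create(
      _["ev_time"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["ev_type"] = IntegerVector(ev_type.begin(), ev_type.end()),
      _["ev_cell"] = IntegerVector(ev_cell.begin(), ev_cell.end()),
      _["born_at"] = NumericVector(born_at.begin(), born_at.end()),
      _["removed_at"] = NumericVector(removed_at.begin(), removed_at.end()),
      _["location"] = location,
      _["pfr_exit_due"] = exit_due,
      _["t_end"] = t);
}
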