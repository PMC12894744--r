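#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Distance-dependent edge sampling on a 2D lattice.
//
// Units are indexed row-major (1-based on the R side): unit u sits at
// (row, col) = (u %/% n_cols, u %% n_cols), position (col * spacing,
// row * spacing) in micrometres. Each ordered pair (i, j), i != j, receives
// a directed edge independently with probability
//   p(r) = amp_g * exp(-r^2 / (2 * sd_g^2)) + amp_e * exp(-r / scale_e)
// evaluated at the (minimal-image, if periodic) Euclidean distance r, and
// truncated to zero beyond `cutoff` (pass R_PosInf for no cutoff).
//
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_sample_lattice_edges(int n_rows, int n_cols, double spacing,
                              bool periodic, double cutoff,
                              double amp_g, double sd_g,
                              double amp_e, double scale_e) {
  const int n = n_rows * n_cols;
  std::vector<int> from;
  std::vector<int> to;
  from.reserve(n * 8);
  to.reserve(n * 8);

  if (periodic) {
    // Enumerate torus offsets once; each ordered pair corresponds to a
    // unique offset (ox, oy) != (0, 0).
    std::vector<int> ox_keep, oy_keep;
    std::vector<double> p_keep;
    for (int ox = 0; ox < n_rows; ++ox) {
      for (int oy = 0; oy < n_cols; ++oy) {
        if (ox == 0 && oy == 0) continue;
        const int mx = std::min(ox, n_rows - ox);
        const int my = std::min(oy, n_cols - oy);
        const double r = spacing * std::sqrt((double)mx * mx + (double)my * my);
        if (r > cutoff) continue;
        const double p = amp_g * std::exp(-(r * r) / (2.0 * sd_g * sd_g)) +
                         amp_e * std::exp(-r / scale_e);
        if (p <= 0.0) continue;
        ox_keep.push_back(ox);
        oy_keep.push_back(oy);
        p_keep.push_back(p > 1.0 ? 1.0 : p);
      }
    }
    const int n_off = (int)p_keep.size();
    for (int ri = 0; ri < n_rows; ++ri) {
      for (int ci = 0; ci < n_cols; ++ci) {
        const int i = ri * n_cols + ci;
        for (int o = 0; o < n_off; ++o) {
          if (unif_rand() < p_keep[o]) {
            int rj = ri + ox_keep[o]; if (rj >= n_rows) rj -= n_rows;
            int cj = ci + oy_keep[o]; if (cj >= n_cols) cj -= n_cols;
            from.push_back(i + 1);
            to.push_back(rj * n_cols + cj + 1);
          }
        }
      }
      Rcpp::checkUserInterrupt();
    }
  } else {
    for (int i = 0; i < n; ++i) {
      const int ri = i / n_cols, ci = i % n_cols;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const int rj = j / n_cols, cj = j % n_cols;
        const double dx = spacing * (rj - ri);
        const double dy = spacing * (cj - ci);
        const double r = std::sqrt(dx * dx + dy * dy);
        if (r > cutoff) continue;
        const double p = amp_g * std::exp(-(r * r) / (2.0 * sd_g * sd_g)) +
                         amp_e * std::exp(-r / scale_e);
        if (unif_rand() < p) {
          from.push_back(i + 1);
          to.push_back(j + 1);
        }
      }
      if (i % 256 == 0) Rcpp::checkUserInterrupt();
    }
  }

  return List::create(_["from"] = wrap(from), _["to"] = wrap(to));
}

// Three-state excitable dynamics on a directed network (CSR out-edges).
//
// States: 0 = resting, 1 = active, 2 = refractory; active and refractory
// phases each last one step. At every step, a resting unit activates with
// probability 1 - (1 - p_poiss) * (1 - p_stim * [stimulated]) *
// (1 - p_trans)^a, where a counts its currently active presynaptic inputs
// (independent Bernoulli per active input). Units listed in `init_active`
// spike at step 0. Spikes are attributed to the step on which the unit is
// active. `stim_unit` gives, per step, the 0-based index of the unit under
// extra drive, or -1.
//
// Returns whole-lattice population counts per step, frame-binned counts for
// the recorded units, their per-step population count, and (optionally) the
// full step-resolution raster of the recorded units.
// [[Rcpp::export]]
List cpp_simulate(IntegerVector row_ptr, IntegerVector col_idx, int n_units,
                  double p_trans, double p_poiss, int n_steps,
                  IntegerVector stim_unit, double p_stim,
                  IntegerVector init_active, IntegerVector record_ids,
                  int steps_per_frame, bool record_steps) {
  const int n_rec = record_ids.size();
  const int n_frames = n_steps / steps_per_frame;

  std::vector<int> state(n_units, 0);
  std::vector<char> pending(n_units, 0);
  std::vector<int> rec_index(n_units, -1);
  for (int k = 0; k < n_rec; ++k) rec_index[record_ids[k]] = k;

  IntegerVector pop_steps(n_steps);
  IntegerVector rec_pop_steps(n_steps);
  IntegerMatrix frame_counts(n_rec, std::max(n_frames, 0));
  IntegerMatrix step_raster(record_steps ? n_rec : 0,
                            record_steps ? n_steps : 0);

  std::vector<int> cur_active, next_active, refr;
  for (int k = 0; k < init_active.size(); ++k) {
    const int u = init_active[k];
    if (state[u] == 0) { state[u] = 1; cur_active.push_back(u); }
  }
  long n_rest = (long)n_units - (long)cur_active.size();

  for (int t = 0; t < n_steps; ++t) {
    // record spikes of step t
    pop_steps[t] = (int)cur_active.size();
    int rec_pop = 0;
    const int f = (steps_per_frame > 0) ? t / steps_per_frame : -1;
    for (size_t a = 0; a < cur_active.size(); ++a) {
      const int k = rec_index[cur_active[a]];
      if (k >= 0) {
        ++rec_pop;
        if (f >= 0 && f < n_frames) frame_counts(k, f) += 1;
        if (record_steps) step_raster(k, t) = 1;
      }
    }
    rec_pop_steps[t] = rec_pop;

    next_active.clear();
    // synaptic transmission from active units
    if (p_trans > 0.0) {
      for (size_t a = 0; a < cur_active.size(); ++a) {
        const int u = cur_active[a];
        for (int e = row_ptr[u]; e < row_ptr[u + 1]; ++e) {
          const int v = col_idx[e];
          if (state[v] == 0 && !pending[v] && unif_rand() < p_trans) {
            pending[v] = 1;
            next_active.push_back(v);
          }
        }
      }
    }
    // external Poisson drive on units resting at step start
    if (p_poiss > 0.0 && n_rest > 0) {
      const int k_drive = (int)R::rbinom((double)n_rest, p_poiss);
      int placed = 0;
      std::vector<int> chosen;
      chosen.reserve(k_drive);
      while (placed < k_drive) {
        const int v = (int)(unif_rand() * n_units);
        if (v >= n_units || state[v] != 0) continue;
        bool dup = false;
        for (size_t c = 0; c < chosen.size(); ++c)
          if (chosen[c] == v) { dup = true; break; }
        if (dup) continue;
        chosen.push_back(v);
        ++placed;
        if (!pending[v]) { pending[v] = 1; next_active.push_back(v); }
      }
    }
    // targeted stimulation
    if (t < stim_unit.size() && stim_unit[t] >= 0 && p_stim > 0.0) {
      const int v = stim_unit[t];
      if (state[v] == 0 && !pending[v] && unif_rand() < p_stim) {
        pending[v] = 1;
        next_active.push_back(v);
      }
    }
    // transitions: refractory -> resting, active -> refractory,
    // pending -> active
    for (size_t a = 0; a < refr.size(); ++a) { state[refr[a]] = 0; ++n_rest; }
    refr = cur_active;
    for (size_t a = 0; a < cur_active.size(); ++a) state[cur_active[a]] = 2;
    for (size_t a = 0; a < next_active.size(); ++a) {
      const int v = next_active[a];
      state[v] = 1;
      pending[v] = 0;
      --n_rest;
    }
    cur_active.swap(next_active);
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["pop_steps"] = pop_steps,
                          _["rec_pop_steps"] = rec_pop_steps,
                          _["frame_counts"] = frame_counts);
  if (record_steps) out["step_raster"] = step_raster;
  return out;
}

// Pooled descendant ratio from sparsely seeded cascades.
//
// Runs `n_reps` independent cascades, each seeded with `n_seeds` random
// resting units in an otherwise quiet network (no external drive), and
// accumulates parents n(t) and children n(t+1) over steps t >= burn_in
// until the cascade dies or `max_steps` is reached. The ratio
// sum(children) / sum(parents) estimates the effective branching ratio.
// Per-rep sums are returned so the caller can attach an uncertainty.
// A cascade is also stopped once it has accumulated `max_spikes` spikes
// (supercritical cascades otherwise grow to lattice scale and dominate
// the cost; the growth steps already counted carry the ratio signal).
// [[Rcpp::export]]
List cpp_descendant_ratio(IntegerVector row_ptr, IntegerVector col_idx,
                          int n_units, double p_trans, int n_seeds,
                          int n_reps, int max_steps, int burn_in,
                          int max_spikes) {
  NumericVector parents(n_reps), children(n_reps);
  std::vector<int> state(n_units, 0);
  std::vector<char> pending(n_units, 0);
  std::vector<int> cur_active, next_active, refr, touched;

  for (int rep = 0; rep < n_reps; ++rep) {
    // reset only the units touched by the previous cascade
    for (size_t k = 0; k < touched.size(); ++k) state[touched[k]] = 0;
    touched.clear();
    cur_active.clear(); next_active.clear(); refr.clear();

    for (int s = 0; s < n_seeds; ++s) {
      const int v = (int)(unif_rand() * n_units);
      if (v < n_units && state[v] == 0) {
        state[v] = 1;
        cur_active.push_back(v);
        touched.push_back(v);
      }
    }

    double par = 0.0, chi = 0.0;
    long total = (long)cur_active.size();
    for (int t = 0; t < max_steps && !cur_active.empty() &&
                    total < max_spikes; ++t) {
      next_active.clear();
      for (size_t a = 0; a < cur_active.size(); ++a) {
        const int u = cur_active[a];
        for (int e = row_ptr[u]; e < row_ptr[u + 1]; ++e) {
          const int v = col_idx[e];
          if (state[v] == 0 && !pending[v] && unif_rand() < p_trans) {
            pending[v] = 1;
            next_active.push_back(v);
            touched.push_back(v);
          }
        }
      }
      for (size_t a = 0; a < refr.size(); ++a) state[refr[a]] = 0;
      refr = cur_active;
      for (size_t a = 0; a < cur_active.size(); ++a) state[cur_active[a]] = 2;
      for (size_t a = 0; a < next_active.size(); ++a) {
        state[next_active[a]] = 1;
        pending[next_active[a]] = 0;
      }
      if (t >= burn_in) {
        par += (double)cur_active.size();
        chi += (double)next_active.size();
      }
      total += (long)next_active.size();
      cur_active.swap(next_active);
    }
    // leave remaining refractory/active units marked; they are in `touched`
    for (size_t a = 0; a < refr.size(); ++a) touched.push_back(refr[a]);
    parents[rep] = par;
    children[rep] = chi;
    if (rep % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["parents"] = parents, _["children"] = children);
}
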