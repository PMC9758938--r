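#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Colour codes shared with the R side: 0 off, 1 white, 2 blue, 3 green.

static inline int nearest_beam(double x, const NumericVector& bp) {
  int n = bp.size();
  if (x <= bp[0]) return 1;
  if (x >= bp[n - 1]) return n;
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (bp[mid] <= x) lo = mid; else hi = mid;
  }
  return (x - bp[lo] <= bp[hi] - x) ? lo + 1 : hi + 1;
}

// Beam-cell boundary crossings along a reflecting path from x by dx.
// Returns the final position in *x_out. Crossings are counted per monotone
// sub-segment as the change in nearest-beam cell index, which guarantees
// counts >= |net cell displacement|.
static inline int folded_crossings(double x, double dx, double L,
                                   const NumericVector& bp, double* x_out) {
  double target = x + dx;
  double cur = x;
  int crossings = 0;
  int guard = 0;
  while ((target < 0.0 || target > L) && guard++ < 64) {
    double wall = (target < 0.0) ? 0.0 : L;
    crossings += std::abs(nearest_beam(wall, bp) - nearest_beam(cur, bp));
    target = (target < 0.0) ? -target : 2.0 * L - target;
    cur = wall;
  }
  if (target < 0.0) target = 0.0;
  if (target > L) target = L;
  crossings += std::abs(nearest_beam(target, bp) - nearest_beam(cur, bp));
  *x_out = target;
  return crossings;
}

// Simulate one fly for `duration` seconds.
//
// Per second: movement occurs with probability
//   clamp(p_move * phase_factor + effective_beta, 0, 1);
// a moving fly displaces by N(drift, step_scale) mm with reflecting walls
// and scores max(1, cell boundaries crossed). Drift pools food attraction
// (toward the nearer end, plus a dark-phase pull toward the ethanol end at
// x = L), innate blue-light aversion (away from the occupied zone while the
// tube is lit blue) and learned, position-bound avoidance weights that grow
// with blue exposure up to learn_cap.
//
// Sudden-darkness stimuli (stim_sec) set effective_beta to
// gain * kappa^n_eff, where the habituation load n_eff relaxes toward zero
// with time constant tau_rec between stimuli and increments by one per
// stimulus; effective_beta itself decays with time constant tau.
//
// In feedback mode the applied colour at second s (>= feedback_start) is the
// rule colour of the zone occupied at s-1 (one-tick controller latency);
// before feedback_start the tube shows white. In open-loop mode the ambient
// colour comes from color_ol (length duration; empty = constant white).
// [[Rcpp::export]]
List sim_fly_cpp(double x0, int duration, NumericVector beam_pos,
                 double tube_len, List par, LogicalVector dark_phase,
                 IntegerVector stim_sec, IntegerVector color_ol,
                 bool feedback, int feedback_start, int boundary_beam,
                 int left_color_pre, int right_color_pre,
                 int left_color_post, int right_color_post, int swap_at_s,
                 List state0) {
  const double p_move = as<double>(par["p_move"]);
  const double step_scale = as<double>(par["step_scale"]);
  const double gain = as<double>(par["startle_gain"]);
  const double tau = as<double>(par["startle_tau"]);
  const double kappa = as<double>(par["habit_decay"]);
  const double tau_rec = as<double>(par["habit_recovery"]);
  const double light_f = as<double>(par["light_factor"]);
  const double dark_f = as<double>(par["dark_factor"]);
  const double food_a = as<double>(par["food_bias_a"]);
  const double food_b = as<double>(par["food_bias_b"]);
  const double etoh = as<double>(par["ethanol_dark_boost"]);
  const double blue_av = as<double>(par["blue_aversion"]);
  const double learn_rate = as<double>(par["learn_rate"]);
  const double learn_cap = as<double>(par["learn_cap"]);

  const double L = tube_len;
  const double eb_decay = std::exp(-1.0 / tau);
  const bool has_dark = dark_phase.size() > 0;
  const bool has_ol = color_ol.size() > 0;

  IntegerVector counts(duration), position(duration);
  IntegerVector zone_out(feedback ? duration : 0);
  IntegerVector color_out(feedback ? duration : 0);
  NumericVector eb_at_stim(stim_sec.size());

  double x = x0;
  double eb = state0.containsElementNamed("effective_beta")
                ? as<double>(state0["effective_beta"]) : 0.0;
  double n_eff = state0.containsElementNamed("habit_load")
                ? as<double>(state0["habit_load"]) : 0.0;
  double last_stim = state0.containsElementNamed("last_stim_s")
                ? as<double>(state0["last_stim_s"]) : -1.0;
  double wL = state0.containsElementNamed("learned_left")
                ? as<double>(state0["learned_left"]) : 0.0;
  double wR = state0.containsElementNamed("learned_right")
                ? as<double>(state0["learned_right"]) : 0.0;
  int stim_ptr = 0;
  int idx0 = nearest_beam(x, beam_pos);
  int zone = (idx0 < boundary_beam) ? 1 : (idx0 > boundary_beam ? 2 : 1);

  for (int s = 0; s < duration; ++s) {
    // startle stimulus at this second
    if (stim_ptr < stim_sec.size() && s == stim_sec[stim_ptr]) {
      if (last_stim >= 0.0) n_eff *= std::exp(-(s - last_stim) / tau_rec);
      eb = gain * std::pow(kappa, n_eff);
      eb_at_stim[stim_ptr] = eb;
      n_eff += 1.0;
      last_stim = s;
      ++stim_ptr;
    }

    // colour experienced during this second
    int col;
    if (feedback) {
      if (s < feedback_start) {
        col = 1;  // white habituation backdrop
      } else {
        bool swapped = (swap_at_s >= 0 && s >= swap_at_s);
        int lc = swapped ? left_color_post : left_color_pre;
        int rc = swapped ? right_color_post : right_color_pre;
        col = (zone == 1) ? lc : rc;  // zone from previous second: 1-tick latency
      }
      color_out[s] = col;
    } else {
      col = has_ol ? color_ol[s] : 1;
    }

    bool dark = has_dark && dark_phase[s];
    double q = p_move * (dark ? dark_f : light_f) + eb;
    if (q < 0.0) q = 0.0;
    if (q > 1.0) q = 1.0;

    if (unif_rand() < q) {
      double drift = 0.0;
      if (food_a > 0.0 || food_b > 0.0) {
        drift += (x < L / 2.0) ? -food_a : food_b;
      }
      if (dark) drift += etoh;
      if (col == 2 && blue_av > 0.0) {
        drift += (zone == 1) ? blue_av : -blue_av;
      }
      if (wL > 0.0 || wR > 0.0) {
        drift += (zone == 1) ? wL : -wR;
      }
      double dx = norm_rand() * step_scale + drift;
      double x_new;
      int cr = folded_crossings(x, dx, L, beam_pos, &x_new);
      counts[s] = cr > 0 ? cr : 1;
      x = x_new;
    } else {
      counts[s] = 0;
    }

    int idx = nearest_beam(x, beam_pos);
    position[s] = idx;
    if (idx < boundary_beam) zone = 1;
    else if (idx > boundary_beam) zone = 2;
    if (feedback) zone_out[s] = zone;

    // learned place avoidance grows with blue exposure on the current side
    if (col == 2 && learn_rate > 0.0) {
      if (zone == 1) { wL += learn_rate; if (wL > learn_cap) wL = learn_cap; }
      else           { wR += learn_rate; if (wR > learn_cap) wR = learn_cap; }
    }

    eb *= eb_decay;
  }

  List out = List::create(_["counts"] = counts, _["position"] = position,
                          _["eb_at_stim"] = eb_at_stim,
                          _["initial_beam"] = idx0,
                          _["state"] = List::create(
                            _["x"] = x, _["effective_beta"] = eb,
                            _["habit_load"] = n_eff,
                            _["last_stim_s"] = last_stim,
                            _["learned_left"] = wL,
                            _["learned_right"] = wR));
  if (feedback) {
    out["zone"] = zone_out;
    out["color"] = color_out;
  }
  return out;
}
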