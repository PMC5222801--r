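#include <Rcpp.h>
using namespace Rcpp;

// Coupled forward-Euler simulation of one leaky integrate-and-fire neuron
// driven by presynaptic spike trains through current-based exponential
// synapses, with online spike-timing-dependent plasticity.
//
// Time is discretized in steps of width dt. Presynaptic spikes arrive as
// parallel vectors (pre_step, pre_id), 0-based and sorted by step. At most
// one spike per synapse per step is assumed (Bernoulli-sampled upstream).
//
// Plasticity uses eligibility traces realizing the all-to-all pair sum:
//   r1_i : presynaptic trace of synapse i, decay tau_causal
//   o1   : postsynaptic trace, decay tau_acausal
// and, for the triplet extension (Pfister-Gerstner style), the slow traces
//   r2_i : presynaptic, decay tau_x;   o2 : postsynaptic, decay tau_y.
// On a presynaptic spike:  dw = alpha * o1 * (a_acausal - a3_acausal * r2_i)
// On a postsynaptic spike: dw = alpha * r1_i * (a_causal + a3_causal * o2)
// where r2_i and o2 are taken just before the triggering spike increments
// them. Spikes of both kinds falling in the same step contribute zero to
// each other (dt = 0 convention): trace increments happen at end of step.
//
// [[Rcpp::export]]
List engine_run(IntegerVector pre_step, IntegerVector pre_id,
                int n_inputs, int n_steps, double dt,
                NumericVector w0, double w_min, double w_max,
                double tau_m, double v_rest, double v_thresh, double v_reset,
                int refrac_steps, double tau_syn, double syn_gain,
                double noise_mean, double noise_sd,
                double escape_rate0, double escape_width, double escape_rate_max,
                bool plastic,
                double alpha, double a_causal, double a_acausal,
                double tau_causal, double tau_acausal,
                double a3_causal, double a3_acausal,
                double tau_x, double tau_y,
                bool freeze_weights,
                int norm_mode, double norm_target, int norm_interval,
                int record_interval, bool record_v) {
  if (w0.size() != n_inputs) stop("length of initial weights must equal n_inputs");
  if (w_min >= w_max) stop("w_min must be < w_max");

  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> dw_total(n_inputs, 0.0);
  std::vector<double> r1(n_inputs, 0.0), r2(n_inputs, 0.0);
  double o1 = 0.0, o2 = 0.0;

  const double e_syn = std::exp(-dt / tau_syn);
  const double e_c   = std::exp(-dt / tau_causal);
  const double e_ac  = std::exp(-dt / tau_acausal);
  const double e_x   = std::exp(-dt / tau_x);
  const double e_y   = std::exp(-dt / tau_y);
  const double noise_scale = noise_sd * std::sqrt(dt / tau_m);

  double V = v_rest, I_syn = 0.0;
  int refrac = 0;

  const int n_pre = pre_step.size();
  int ev = 0; // cursor into presynaptic event stream

  // weight trajectory: initial row + one row per record_interval steps
  int n_rec = (record_interval > 0) ? (n_steps / record_interval + 1) : 2;
  NumericMatrix W(n_rec, n_inputs);
  NumericVector rec_times(n_rec);
  for (int i = 0; i < n_inputs; ++i) W(0, i) = w[i];
  rec_times[0] = 0.0;
  int rec_row = 1;

  std::vector<int> post_steps;
  NumericVector Vtrace(record_v ? n_steps : 0);

  std::vector<int> step_pre; // synapse ids spiking this step
  step_pre.reserve(8);

  for (int s = 0; s < n_steps; ++s) {
    // synaptic current decay + arrivals
    I_syn *= e_syn;
    step_pre.clear();
    while (ev < n_pre && pre_step[ev] == s) {
      int i = pre_id[ev];
      I_syn += w[i] * syn_gain;
      step_pre.push_back(i);
      ++ev;
    }

    // membrane update
    bool post_spike = false;
    if (refrac > 0) {
      --refrac;
      V = v_reset;
    } else {
      V += (dt / tau_m) * (-(V - v_rest) + I_syn + noise_mean);
      if (noise_scale > 0.0) V += noise_scale * norm_rand();
      if (escape_width > 0.0) {
        // stochastic spike emission: hazard lambda(V) = rate0*exp((V-VT)/width),
        // cut to zero more than six e-folds below threshold so a neuron
        // resting far from threshold is deterministically silent
        double x = (V - v_thresh) / escape_width;
        if (x > -6.0) {
          if (x > 30.0) x = 30.0;
          double lam = escape_rate0 * std::exp(x);
          // saturating hazard: exponential far below threshold, capped at
          // escape_rate_max for strong drive (softly, Michaelis-Menten form)
          if (escape_rate_max > 0.0) lam = lam / (1.0 + lam / escape_rate_max);
          double p = 1.0 - std::exp(-lam * dt);
          if (unif_rand() < p) post_spike = true;
        }
      } else if (V >= v_thresh) {
        post_spike = true;
      }
      if (post_spike) {
        post_steps.push_back(s);
        V = v_reset;
        refrac = refrac_steps;
      }
    }
    if (record_v) Vtrace[s] = V;

    if (plastic) {
      // decay traces to current step
      for (int i = 0; i < n_inputs; ++i) { r1[i] *= e_c; r2[i] *= e_x; }
      o1 *= e_ac; o2 *= e_y;

      // weight updates (traces exclude same-step spikes)
      for (size_t k = 0; k < step_pre.size(); ++k) {
        int i = step_pre[k];
        double dw = alpha * o1 * (a_acausal - a3_acausal * r2[i]);
        if (freeze_weights) dw_total[i] += dw;
        else {
          w[i] += dw;
          if (w[i] < w_min) w[i] = w_min; else if (w[i] > w_max) w[i] = w_max;
        }
      }
      if (post_spike) {
        double gain = alpha * (a_causal + a3_causal * o2);
        for (int i = 0; i < n_inputs; ++i) {
          double dw = gain * r1[i];
          if (freeze_weights) dw_total[i] += dw;
          else {
            w[i] += dw;
            if (w[i] < w_min) w[i] = w_min; else if (w[i] > w_max) w[i] = w_max;
          }
        }
      }

      // end-of-step trace increments
      for (size_t k = 0; k < step_pre.size(); ++k) {
        int i = step_pre[k];
        r1[i] += 1.0; r2[i] += 1.0;
      }
      if (post_spike) { o1 += 1.0; o2 += 1.0; }
    }

    // weight normalization on its own clock
    // norm_mode: 0 none, 1 multiplicative rescale, 2 uniform (subtractive)
    // shift; both respect the bounds, the shift solves for the offset that
    // restores the target sum given clipping (monotone -> bisection)
    if (norm_mode > 0 && norm_interval > 0 && ((s + 1) % norm_interval == 0)) {
      double tot = 0.0;
      for (int i = 0; i < n_inputs; ++i) tot += w[i];
      if (norm_mode == 1) {
        if (tot > 0.0) {
          double f = norm_target / tot;
          for (int i = 0; i < n_inputs; ++i) {
            w[i] *= f;
            if (w[i] < w_min) w[i] = w_min; else if (w[i] > w_max) w[i] = w_max;
          }
        }
      } else if (tot != norm_target) {
        double lo = -(w_max - w_min), hi = w_max - w_min;
        for (int it = 0; it < 60; ++it) {
          double d = 0.5 * (lo + hi), su = 0.0;
          for (int i = 0; i < n_inputs; ++i) {
            double v = w[i] + d;
            if (v < w_min) v = w_min; else if (v > w_max) v = w_max;
            su += v;
          }
          if (su < norm_target) lo = d; else hi = d;
        }
        double d = 0.5 * (lo + hi);
        for (int i = 0; i < n_inputs; ++i) {
          w[i] += d;
          if (w[i] < w_min) w[i] = w_min; else if (w[i] > w_max) w[i] = w_max;
        }
      }
    }

    if (record_interval > 0 && ((s + 1) % record_interval == 0) && rec_row < n_rec) {
      for (int i = 0; i < n_inputs; ++i) W(rec_row, i) = w[i];
      rec_times[rec_row] = (s + 1) * dt;
      ++rec_row;
    }
  }

  // truncate recording if record_interval did not divide n_steps evenly
  if (rec_row < n_rec) {
    W = W(Range(0, rec_row - 1), _);
    rec_times = rec_times[Range(0, rec_row - 1)];
  }

  IntegerVector ps(post_steps.begin(), post_steps.end());
  List out = List::create(
    _["post_steps"] = ps,
    _["post_times"] = NumericVector(ps.begin(), ps.end()) * dt + 0.5 * dt,
    _["w_final"] = NumericVector(w.begin(), w.end()),
    _["dw_total"] = NumericVector(dw_total.begin(), dw_total.end()),
    _["weights"] = W,
    _["rec_times"] = rec_times,
    _["n_post"] = (int)ps.size());
  if (record_v) out["v_trace"] = Vtrace;
  return out;
}
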