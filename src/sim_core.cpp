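#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integrator for the four-population delayed stochastic
// spiking network. Synaptic traces are exponentially filtered spike
// trains held in a ring buffer spanning the maximal conduction delay;
// recurrent input to neuron j is the weighted sum of delayed traces of
// its presynaptic partners (weights already carry the 1/N_source
// normalization). Edges arrive sorted by (delay bin, source) so each
// history column is read sequentially; the accumulation order per
// target matches the R reference integrator bit-for-bit.
//
// All random draws come from the R RNG stream so that a set.seed()
// call on the R side makes the full simulation reproducible; the draw
// order per step is one normal per neuron (membrane noise) followed by
// one uniform per neuron (spike thinning), in global neuron order
// (e, i, lgn, rtn).
//
// [[Rcpp::export]]
List sim_core(int n_steps, double dt,
              IntegerVector pop_sizes,
              NumericVector alpha, double a, double b, double tau_m,
              NumericVector I, NumericVector D,
              double f_o, double beta, double h,
              IntegerVector tgt, IntegerVector src,
              NumericVector w, IntegerVector dbin,
              NumericVector u0, NumericVector v0,
              double stim_S, double stim_f, double stim_phase,
              NumericVector phi,
              int record_u_every, IntegerVector record_u_idx) {
  const int n_pop = pop_sizes.size();
  int n_tot = 0;
  for (int p = 0; p < n_pop; ++p) n_tot += pop_sizes[p];
  if (u0.size() != n_tot || v0.size() != n_tot)
    stop("initial state length mismatch");
  const int n_edge = tgt.size();

  std::vector<int> pop_of(n_tot);
  {
    int j = 0;
    for (int p = 0; p < n_pop; ++p)
      for (int k = 0; k < pop_sizes[p]; ++k) pop_of[j++] = p;
  }
  const int n_e = pop_sizes[0], n_i = pop_sizes[1];

  int max_dbin = 0;
  for (int k = 0; k < n_edge; ++k)
    if (dbin[k] > max_dbin) max_dbin = dbin[k];
  const int H = max_dbin + 1;

  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> E(n_tot, 0.0);
  std::vector<double> hist((size_t)n_tot * H, 0.0);

  const double decay = std::exp(-dt / tau_m);
  std::vector<double> noise_sd(n_pop), adt(n_pop);
  for (int p = 0; p < n_pop; ++p) {
    noise_sd[p] = alpha[p] * std::sqrt(2.0 * D[p] * dt);
    adt[p] = alpha[p] * dt;
  }
  const double two_pi = 2.0 * M_PI;

  NumericMatrix rates(n_steps, n_pop);
  NumericVector eeg(n_steps);
  std::vector<int> spike_step, spike_neuron;
  spike_step.reserve(n_steps * 4);
  spike_neuron.reserve(n_steps * 4);

  const int n_rec = record_u_idx.size();
  int n_snap = (record_u_every > 0 && n_rec > 0)
                   ? (n_steps / record_u_every) : 0;
  NumericMatrix u_rec(n_snap, n_rec);

  RNGScope scope;
  std::vector<double> S_in(n_tot), xi(n_tot);

  // pack the (delay-sorted) edge list: 16-bit endpoints and 32-bit
  // weights, with one (delay, range) entry per delay group --- the
  // edge sweep is memory-bandwidth bound
  const bool small_idx = n_tot <= 65535;
  std::vector<uint16_t> tgt16, src16;
  std::vector<float> w32;
  std::vector<int> grp_d, grp_end;
  if (small_idx) {
    tgt16.resize(n_edge);
    src16.resize(n_edge);
    w32.resize(n_edge);
    for (int k = 0; k < n_edge; ++k) {
      tgt16[k] = (uint16_t)tgt[k];
      src16[k] = (uint16_t)src[k];
      w32[k] = (float)w[k];
    }
  }
  for (int k = 0; k < n_edge; ++k) {
    if (grp_d.empty() || dbin[k] != grp_d.back()) {
      grp_d.push_back(dbin[k]);
      grp_end.push_back(k);
    }
    grp_end.back() = k + 1;
  }

  for (int t = 0; t < n_steps; ++t) {
    const int base = t % H;
    std::fill(S_in.begin(), S_in.end(), 0.0);
    {
      int k = 0;
      for (size_t g = 0; g < grp_d.size(); ++g) {
        int sl = base - grp_d[g];
        if (sl < 0) sl += H;
        const double* col = &hist[(size_t)sl * n_tot];
        const int kend = grp_end[g];
        if (small_idx) {
          for (; k < kend; ++k)
            S_in[tgt16[k]] += (double)w32[k] * col[src16[k]];
        } else {
          for (; k < kend; ++k)
            S_in[tgt[k]] += w[k] * col[src[k]];
        }
      }
    }
    for (int j = 0; j < n_tot; ++j) xi[j] = norm_rand();
    const double stim = stim_S * std::sin(two_pi * stim_f * (t * dt) / 1000.0
                                          + stim_phase);
    double rate_sum[8] = {0, 0, 0, 0, 0, 0, 0, 0};
    double eeg_e = 0.0, eeg_i = 0.0;
    for (int j = 0; j < n_tot; ++j) {
      const int p = pop_of[j];
      const double drive = (p < 2) ? stim : 0.0;
      double un = u[j] + adt[p] * (-u[j] + b * v[j] + S_in[j] + I[p] + drive)
                  + noise_sd[p] * xi[j];
      v[j] += a * dt * (-v[j] + u[j]);
      if (!std::isfinite(un))
        stop("simulation diverged at t = %f ms (neuron %d)",
             (t + 1) * dt, j + 1);
      u[j] = un;
    }
    const int sl_new = (t + 1) % H;
    double* col = &hist[(size_t)sl_new * n_tot];
    for (int j = 0; j < n_tot; ++j) {
      const int p = pop_of[j];
      const double r = f_o / (1.0 + std::exp(-beta * (u[j] - h)));
      rate_sum[p] += r;
      const int spk = (unif_rand() < r * dt) ? 1 : 0;
      if (spk) {
        spike_step.push_back(t + 1);
        spike_neuron.push_back(j + 1);
      }
      E[j] = E[j] * decay + spk / tau_m;
      if (E[j] < 1e-12) E[j] = 0.0;  // flush decayed traces (avoids subnormals)
      col[j] = E[j];
      if (p == 0) eeg_e += phi[j] * u[j];
      else if (p == 1) eeg_i += phi[j] * u[j];
    }
    for (int p = 0; p < n_pop; ++p)
      rates(t, p) = rate_sum[p] / pop_sizes[p];
    eeg[t] = eeg_e / n_e + eeg_i / n_i;
    if (n_snap > 0 && (t + 1) % record_u_every == 0) {
      int row = (t + 1) / record_u_every - 1;
      if (row < n_snap)
        for (int k = 0; k < n_rec; ++k)
          u_rec(row, k) = u[record_u_idx[k] - 1];
    }
  }

  return List::create(
      _["rates"] = rates, _["eeg"] = eeg,
      _["spike_step"] = IntegerVector(spike_step.begin(), spike_step.end()),
      _["spike_neuron"] = IntegerVector(spike_neuron.begin(),
                                        spike_neuron.end()),
      _["u_rec"] = u_rec,
      _["u_final"] = NumericVector(u.begin(), u.end()),
      _["v_final"] = NumericVector(v.begin(), v.end()));
}
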