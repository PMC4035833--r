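#include <Rcpp.h>
using namespace Rcpp;

// Fast trial-loop engine.
//
// Mirrors the pure-R reference engine (run_trials_r) operation for
// operation, in the same floating-point order, so the two can be compared
// exactly on small problems.  Per-step order within a trial:
//   1. recurrent currents from x(t-1): per-neuron uniform noise, then the
//      signed sum over active presynaptic units (ascending index);
//   2. inclusive threshold rule, then input-channel forcing (step 1 only);
//   3. decision currents from the fresh excitatory activity + noise,
//      winner-take-all (ties -> lowest index; the competition may be
//      restricted to a cued action pair at the Go step);
//   4. eligibility updates from within-trial (x(t-1), x(t)) pairs;
//   5. homeostatic threshold adaptation;
//   6. at the Go step: score, commit traces to the weights (reward-gated),
//      rectify at zero, synaptic scaling of the rows that changed.
//
// Recurrent eligibility traces are stored lazily: only synapses touched in
// the current trial are kept, each with the step of its last update, and
// decay is applied by repeated multiplication so the arithmetic matches the
// dense per-step decay of the reference engine bit for bit.
//
// rec_mode: 0 = r-STDP, 1 = reward-independent STDP (events committed to the
// weights every step, no traces, no reward gating), 2 = frozen recurrent
// weights.

// [[Rcpp::export]]
List cpp_run_trials(NumericMatrix w_rec_in, LogicalMatrix conn,
                    NumericMatrix w_dec_in,
                    NumericVector theta_exc_in, NumericVector theta_inh_in,
                    NumericVector theta_dec_in,
                    IntegerVector x_in,
                    int n_exc, int n_in,
                    IntegerMatrix trials,  // stim_ch, ctx_ch(0=none), delay, correct, allowed_lo(0=all)
                    int T_trial,
                    double noise_lo, double noise_hi,
                    double x0_rec, double x0_dec,
                    double decay, double f_rec, double f_dec,
                    double eta_rec, double eta_dec,
                    double lam_exc, double lam_dec, double lam_inh,
                    int rec_mode, bool dec_learn, bool ip_on,
                    int record_from) {
  const int N = w_rec_in.nrow();
  const int M = w_dec_in.nrow();
  const int n_trials = trials.nrow();
  const int n_inh = N - n_exc;

  NumericMatrix w_rec = clone(w_rec_in);
  NumericMatrix w_dec = clone(w_dec_in);
  NumericVector theta_exc = clone(theta_exc_in);
  NumericVector theta_inh = clone(theta_inh_in);
  NumericVector theta_dec = clone(theta_dec_in);

  double *w = w_rec.begin();
  double *wd = w_dec.begin();
  const int *cn = conn.begin();  // LogicalMatrix stores int

  std::vector<int> x(x_in.begin(), x_in.end());
  std::vector<int> xn(N, 0);
  std::vector<double> I(N), Idec(M);
  std::vector<int> act_prev, act_now;
  act_prev.reserve(N); act_now.reserve(N);
  for (int i = 0; i < N; ++i) if (x[i]) act_prev.push_back(i);

  // lazy recurrent traces over plastic synapses (presynaptic excitatory)
  std::vector<double> ev(static_cast<size_t>(N) * n_exc, 0.0);
  std::vector<int> estamp(static_cast<size_t>(N) * n_exc, 0);
  std::vector<int> eid(static_cast<size_t>(N) * n_exc, -1);
  std::vector<int> touched;
  touched.reserve(4096);
  std::vector<int> row_id(N, -1);  // rows needing rescaling, tagged by epoch id
  std::vector<int> dirty_rows;
  dirty_rows.reserve(N);

  // dense decision traces
  std::vector<double> ed(static_cast<size_t>(M) * n_exc, 0.0);

  IntegerVector actions(n_trials), rewards(n_trials);
  NumericVector rate(n_trials);

  const int n_rec = record_from > 0 ? n_trials - record_from + 1 : 0;
  IntegerVector raster(static_cast<R_xlen_t>(n_rec) * N * T_trial);
  int *ras = n_rec > 0 ? raster.begin() : nullptr;

  for (int tr = 0; tr < n_trials; ++tr) {
    const int stim_ch = trials(tr, 0);
    const int ctx_ch = trials(tr, 1);
    const int delay = trials(tr, 2);
    const int correct = trials(tr, 3);      // 1-based
    const int allowed_lo = trials(tr, 4);   // 1-based, 0 = unrestricted
    const int go_step = delay + 1;          // delay counted from stimulus onset

    touched.clear();
    std::fill(ed.begin(), ed.end(), 0.0);
    int prev_winner = -1;  // within-trial
    int exc_count_trial = 0;

    for (int t = 1; t <= T_trial; ++t) {
      // 1. recurrent currents: excitatory drive from x(t-1); the inhibitory
      //    population is updated first (from the same excitatory drive) and
      //    gates the excitatory update within the step, so inhibition tracks
      //    activity surges without a one-step lag
      for (int i = 0; i < N; ++i) I[i] = R::runif(noise_lo, noise_hi);
      for (size_t a = 0; a < act_prev.size(); ++a) {
        const int j = act_prev[a];
        if (j >= n_exc) break;
        const double *col = w + static_cast<size_t>(N) * j;
        for (int i = 0; i < N; ++i) I[i] += col[i];
      }
      for (size_t a = 0; a < act_prev.size(); ++a) {  // lagged inh -> inh
        const int j = act_prev[a];
        if (j < n_exc) continue;
        const double *col = w + static_cast<size_t>(N) * j;
        for (int i = n_exc; i < N; ++i) I[i] -= col[i];
      }

      // 2. threshold rule (inhibitory first), fast inhibition, forcing
      act_now.clear();
      for (int i = 0; i < n_inh; ++i)
        xn[n_exc + i] = (I[n_exc + i] >= theta_inh[i]) ? 1 : 0;
      for (int j = n_exc; j < N; ++j) {
        if (!xn[j]) continue;
        const double *col = w + static_cast<size_t>(N) * j;
        for (int i = 0; i < n_exc; ++i) I[i] -= col[i];
      }
      for (int i = 0; i < n_exc; ++i) xn[i] = (I[i] >= theta_exc[i]) ? 1 : 0;
      if (t == 1) {
        for (int u = (stim_ch - 1) * n_in; u < stim_ch * n_in; ++u) xn[u] = 1;
        if (ctx_ch > 0)
          for (int u = (ctx_ch - 1) * n_in; u < ctx_ch * n_in; ++u) xn[u] = 1;
      }
      int exc_count = 0;
      for (int i = 0; i < N; ++i)
        if (xn[i]) { act_now.push_back(i); if (i < n_exc) ++exc_count; }
      exc_count_trial += exc_count;

      // 3. decision WTA (synchronous: reads x(t-1), like every other unit,
      //    so the synapses credited by the trace are the ones that drove
      //    the decision)
      for (int m = 0; m < M; ++m) Idec[m] = R::runif(noise_lo, noise_hi);
      for (size_t a = 0; a < act_prev.size(); ++a) {
        const int j = act_prev[a];
        if (j >= n_exc) break;  // act_prev is ascending
        const double *col = wd + static_cast<size_t>(M) * j;
        for (int m = 0; m < M; ++m) Idec[m] += col[m];
      }
      int lo = 0, hi = M;
      if (t == go_step && allowed_lo > 0) { lo = allowed_lo - 1; hi = lo + 2; }
      int winner = lo;
      for (int m = lo + 1; m < hi; ++m) if (Idec[m] > Idec[winner]) winner = m;

      // 4. eligibility / unsupervised updates (within-trial pairs only)
      if (t >= 2) {
        if (rec_mode == 0) {
          const int id = tr;
          for (size_t a = 0; a < act_prev.size(); ++a) {   // potentiation
            const int j = act_prev[a];
            if (j >= n_exc) break;
            const size_t base = static_cast<size_t>(N) * j;
            for (size_t b = 0; b < act_now.size(); ++b) {
              const int i = act_now[b];
              if (!cn[base + i]) continue;
              const size_t idx = base + i;
              if (eid[idx] != id) {
                eid[idx] = id; ev[idx] = 0.0; estamp[idx] = t;
                touched.push_back(static_cast<int>(idx));
              } else {
                double v = ev[idx];
                for (int k = estamp[idx]; k < t; ++k) v *= decay;
                ev[idx] = v; estamp[idx] = t;
              }
              ev[idx] += 1.0;
            }
          }
          for (size_t a = 0; a < act_now.size(); ++a) {    // depression
            const int j = act_now[a];
            if (j >= n_exc) break;
            const size_t base = static_cast<size_t>(N) * j;
            for (size_t b = 0; b < act_prev.size(); ++b) {
              const int i = act_prev[b];
              if (!cn[base + i]) continue;
              const size_t idx = base + i;
              if (eid[idx] != id) {
                eid[idx] = id; ev[idx] = 0.0; estamp[idx] = t;
                touched.push_back(static_cast<int>(idx));
              } else {
                double v = ev[idx];
                for (int k = estamp[idx]; k < t; ++k) v *= decay;
                ev[idx] = v; estamp[idx] = t;
              }
              ev[idx] -= f_rec;
            }
          }
        } else if (rec_mode == 1) {
          // reward-independent STDP: accumulate this step's net events,
          // commit immediately, rectify, rescale the rows that changed
          const int id = tr * T_trial + t;
          touched.clear();
          for (size_t a = 0; a < act_prev.size(); ++a) {
            const int j = act_prev[a];
            if (j >= n_exc) break;
            const size_t base = static_cast<size_t>(N) * j;
            for (size_t b = 0; b < act_now.size(); ++b) {
              const int i = act_now[b];
              if (!cn[base + i]) continue;
              const size_t idx = base + i;
              if (eid[idx] != id) { eid[idx] = id; ev[idx] = 0.0;
                                    touched.push_back(static_cast<int>(idx)); }
              ev[idx] += 1.0;
            }
          }
          for (size_t a = 0; a < act_now.size(); ++a) {
            const int j = act_now[a];
            if (j >= n_exc) break;
            const size_t base = static_cast<size_t>(N) * j;
            for (size_t b = 0; b < act_prev.size(); ++b) {
              const int i = act_prev[b];
              if (!cn[base + i]) continue;
              const size_t idx = base + i;
              if (eid[idx] != id) { eid[idx] = id; ev[idx] = 0.0;
                                    touched.push_back(static_cast<int>(idx)); }
              ev[idx] -= f_rec;
            }
          }
          if (!touched.empty()) {
            dirty_rows.clear();
            for (size_t k = 0; k < touched.size(); ++k) {
              const size_t idx = touched[k];
              const double dw = eta_rec * ev[idx];
              if (dw != 0.0) {
                double nw = w[idx] + dw;
                if (nw < 0.0) nw = 0.0;
                w[idx] = nw;
                const int i = static_cast<int>(idx % N);
                if (row_id[i] != id) { row_id[i] = id; dirty_rows.push_back(i); }
              }
            }
            for (size_t k = 0; k < dirty_rows.size(); ++k) {
              const int i = dirty_rows[k];
              long double acc = 0.0;  // match R's rowSums accumulation
              for (int j = 0; j < n_exc; ++j) acc += w[static_cast<size_t>(N) * j + i];
              const double s = static_cast<double>(acc);
              if (s != 0.0)
                for (int j = 0; j < n_exc; ++j) w[static_cast<size_t>(N) * j + i] /= s;
            }
          }
        }
      }

      if (dec_learn) {
        for (size_t k = 0; k < ed.size(); ++k) ed[k] *= decay;
        if (t >= 2) {
          for (size_t a = 0; a < act_prev.size(); ++a) {  // pre at t-1, winner now
            const int j = act_prev[a];
            if (j >= n_exc) break;
            ed[static_cast<size_t>(M) * j + winner] += 1.0;
          }
          if (prev_winner >= 0) {
            for (size_t a = 0; a < act_now.size(); ++a) { // pre now, winner at t-1
              const int j = act_now[a];
              if (j >= n_exc) break;
              ed[static_cast<size_t>(M) * j + prev_winner] -= f_dec;
            }
          }
        }
      }

      // 5. homeostatic threshold adaptation
      if (ip_on) {
        for (int i = 0; i < n_exc; ++i) {
          const double dth = lam_exc * (xn[i] - x0_rec);
          theta_exc[i] += dth;
        }
        const double mexc = static_cast<double>(exc_count) / n_exc;
        const double dinh = lam_inh * (mexc - x0_rec);
        for (int i = 0; i < n_inh; ++i) theta_inh[i] -= dinh;
        for (int m = 0; m < M; ++m) {
          const double xd = (m == winner) ? 1.0 : 0.0;
          const double dth = lam_dec * (xd - x0_dec);
          theta_dec[m] += dth;
        }
      }

      // 6. Go step: score and commit
      if (t == go_step) {
        const int r = (winner + 1 == correct) ? 1 : -1;
        actions[tr] = winner + 1;
        rewards[tr] = r;

        if (rec_mode == 0 && !touched.empty()) {
          const double g = eta_rec * r;
          dirty_rows.clear();
          for (size_t k = 0; k < touched.size(); ++k) {
            const size_t idx = touched[k];
            double v = ev[idx];
            for (int kk = estamp[idx]; kk < t; ++kk) v *= decay;
            if (v != 0.0) {
              const double dw = g * v;
              double nw = w[idx] + dw;
              if (nw < 0.0) nw = 0.0;
              w[idx] = nw;
              const int i = static_cast<int>(idx % N);
              if (row_id[i] != -2 - tr) { row_id[i] = -2 - tr; dirty_rows.push_back(i); }
            }
          }
          for (size_t k = 0; k < dirty_rows.size(); ++k) {
            const int i = dirty_rows[k];
            long double acc = 0.0;
            for (int j = 0; j < n_exc; ++j) acc += w[static_cast<size_t>(N) * j + i];
            const double s = static_cast<double>(acc);
            if (s != 0.0)
              for (int j = 0; j < n_exc; ++j) w[static_cast<size_t>(N) * j + i] /= s;
          }
        }

        if (dec_learn) {
          const double gd = eta_dec * r;
          for (int j = 0; j < n_exc; ++j) {
            const size_t base = static_cast<size_t>(M) * j;
            for (int m = 0; m < M; ++m) {
              const double dw = gd * ed[base + m];
              double nw = wd[base + m] + dw;
              if (nw < 0.0) nw = 0.0;
              wd[base + m] = nw;
            }
          }
          for (int m = 0; m < M; ++m) {
            long double acc = 0.0;
            for (int j = 0; j < n_exc; ++j) acc += wd[static_cast<size_t>(M) * j + m];
            const double s = static_cast<double>(acc);
            if (s != 0.0)
              for (int j = 0; j < n_exc; ++j) wd[static_cast<size_t>(M) * j + m] /= s;
          }
        }
      }

      // record
      if (n_rec > 0 && tr + 1 >= record_from) {
        int *dst = ras + (static_cast<size_t>(tr + 1 - record_from) * T_trial +
                          (t - 1)) * N;
        for (int i = 0; i < N; ++i) dst[i] = xn[i];
      }

      x.swap(xn);
      act_prev.swap(act_now);
      prev_winner = winner;
    }
    rate[tr] = static_cast<double>(exc_count_trial) / (n_exc * T_trial);
  }

  IntegerVector x_out(N);
  for (int i = 0; i < N; ++i) x_out[i] = x[i];
  if (n_rec > 0) raster.attr("dim") = IntegerVector::create(N, T_trial, n_rec);

  return List::create(_["w_rec"] = w_rec, _["w_dec"] = w_dec,
                      _["theta_exc"] = theta_exc, _["theta_inh"] = theta_inh,
                      _["theta_dec"] = theta_dec, _["x"] = x_out,
                      _["actions"] = actions, _["rewards"] = rewards,
                      _["rate"] = rate, _["raster"] = raster);
}
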