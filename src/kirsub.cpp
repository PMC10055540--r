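#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding for a K-state HMM with Gaussian emissions, shared sd,
// uniform off-diagonal transition probability p_switch.
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector cpp_viterbi_gaussian(NumericVector x, NumericVector means,
                                   double sd, double p_switch,
                                   NumericVector init_log) {
  const int n = x.size(), K = means.size();
  if (K < 1) stop("need at least one state");
  const double log_stay = std::log(std::max(1.0 - (K - 1) * p_switch, 1e-300));
  const double log_switch = std::log(std::max(p_switch, 1e-300));
  const double inv2v = 1.0 / (2.0 * sd * sd);

  NumericMatrix delta(2, K);
  IntegerMatrix psi(n, K);
  std::vector<double> em(K);

  for (int k = 0; k < K; ++k) {
    double d = x[0] - means[k];
    delta(0, k) = init_log[k] - d * d * inv2v;
  }
  int cur = 0;
  for (int t = 1; t < n; ++t) {
    int prev = cur; cur = 1 - cur;
    // best previous state overall
    int argmax = 0; double vmax = delta(prev, 0);
    for (int k = 1; k < K; ++k)
      if (delta(prev, k) > vmax) { vmax = delta(prev, k); argmax = k; }
    for (int k = 0; k < K; ++k) {
      double stay = delta(prev, k) + log_stay;
      double sw = vmax + log_switch;
      int from; double best;
      if (argmax == k) {
        // best switching-source is the runner-up
        double v2 = -HUGE_VAL; int a2 = k;
        for (int j = 0; j < K; ++j)
          if (j != k && delta(prev, j) > v2) { v2 = delta(prev, j); a2 = j; }
        sw = (K > 1) ? v2 + log_switch : -HUGE_VAL;
        if (stay >= sw) { best = stay; from = k; }
        else { best = sw; from = a2; }
      } else {
        if (stay >= sw) { best = stay; from = k; }
        else { best = sw; from = argmax; }
      }
      double d = x[t] - means[k];
      delta(cur, k) = best - d * d * inv2v;
      psi(t, k) = from;
    }
  }
  IntegerVector path(n);
  int argmax = 0; double vmax = delta(cur, 0);
  for (int k = 1; k < K; ++k)
    if (delta(cur, k) > vmax) { vmax = delta(cur, k); argmax = k; }
  path[n - 1] = argmax;
  for (int t = n - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  for (int t = 0; t < n; ++t) path[t] += 1;
  return path;
}

// Exact-event Gillespie simulation of the independent-subunit protonation
// model: per-class protonation counts (birth-death with per-site rates) plus
// one flicker gate. Returns event times and the state after each event,
// encoded as combo index (mixed-radix over class counts) and gate indicator.
// Uses R's RNG, so set.seed() in R governs reproducibility.
// [[Rcpp::export]]
List cpp_gillespie_protonation(IntegerVector n_sites, NumericVector rate_on,
                               NumericVector rate_off, double k_close,
                               double k_open, double duration,
                               int max_events) {
  const int C = n_sites.size();
  std::vector<int> k(C, 0);
  std::vector<int> stride(C, 1);
  for (int j = 1; j < C; ++j) stride[j] = stride[j - 1] * (n_sites[j - 1] + 1);
  // start fully deprotonated, gate open
  int gate = 1;
  double t = 0.0;
  std::vector<double> times;
  std::vector<int> combos;
  std::vector<int> gates;
  auto combo_index = [&]() {
    int idx = 0;
    for (int j = 0; j < C; ++j) idx += k[j] * stride[j];
    return idx;
  };
  times.reserve(1024); combos.reserve(1024); gates.reserve(1024);
  times.push_back(0.0); combos.push_back(combo_index()); gates.push_back(gate);

  RNGScope scope;
  for (int ev = 0; ev < max_events; ++ev) {
    double total = 0.0;
    std::vector<double> rates(2 * C + 1);
    for (int j = 0; j < C; ++j) {
      rates[2 * j] = (n_sites[j] - k[j]) * rate_on[j];
      rates[2 * j + 1] = k[j] * rate_off[j];
      total += rates[2 * j] + rates[2 * j + 1];
    }
    rates[2 * C] = gate ? k_close : k_open;
    total += rates[2 * C];
    if (total <= 0.0) break;
    double dt = R::exp_rand() / total;
    if (t + dt > duration) { t = duration; break; }
    t += dt;
    double u = unif_rand() * total, acc = 0.0;
    int pick = 2 * C;
    for (int r = 0; r <= 2 * C; ++r) {
      acc += rates[r];
      if (u <= acc) { pick = r; break; }
    }
    if (pick == 2 * C) gate = 1 - gate;
    else if (pick % 2 == 0) k[pick / 2] += 1;
    else k[pick / 2] -= 1;
    times.push_back(t);
    combos.push_back(combo_index());
    gates.push_back(gate);
  }
  return List::create(_["time"] = wrap(times), _["combo"] = wrap(combos),
                      _["gate"] = wrap(gates), _["t_end"] = duration);
}

// Semi-Markov birth-death walk over conducting levels with detailed-balance
// adjacent rates against target occupancies pi, total adjacent exchange
// intensity r, plus flicker closures (rate closure_rate per unit conducting
// time, exponential closed dwells of mean closed_mean seconds) that always
// return to the pre-closure level. Levels are 1-based; 0 denotes closed.
// [[Rcpp::export]]
List cpp_sim_empirical(NumericVector pi, double exchange_rate,
                       double closure_rate, double closed_mean,
                       double duration, int start_level, int max_events) {
  const int K = pi.size();
  std::vector<double> up(K, 0.0), down(K, 0.0);
  for (int i = 0; i + 1 < K; ++i) {
    double s = pi[i] + pi[i + 1];
    if (s > 0) {
      up[i] = exchange_rate * pi[i + 1] / s;     // i -> i+1
      down[i + 1] = exchange_rate * pi[i] / s;   // i+1 -> i
    }
  }
  int lev = start_level - 1;
  double t = 0.0;
  std::vector<double> times; std::vector<int> levels;
  times.reserve(1024); levels.reserve(1024);
  times.push_back(0.0); levels.push_back(lev + 1);

  RNGScope scope;
  for (int ev = 0; ev < max_events; ++ev) {
    double r_up = up[lev], r_down = down[lev], r_c = closure_rate;
    double total = r_up + r_down + r_c;
    if (total <= 0.0) break;
    double dt = R::exp_rand() / total;
    if (t + dt >= duration) break;
    t += dt;
    double u = unif_rand() * total;
    if (u <= r_c && r_c > 0) {
      // closure: insert closed dwell, return to same level
      double cd = R::exp_rand() * closed_mean;
      times.push_back(t); levels.push_back(0);
      t += cd;
      if (t >= duration) { times.push_back(duration); levels.push_back(0); break; }
      times.push_back(t); levels.push_back(lev + 1);
    } else if (u <= r_c + r_up) {
      lev += 1;
      times.push_back(t); levels.push_back(lev + 1);
    } else {
      lev -= 1;
      times.push_back(t); levels.push_back(lev + 1);
    }
  }
  return List::create(_["time"] = wrap(times), _["level"] = wrap(levels),
                      _["t_end"] = duration);
}
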