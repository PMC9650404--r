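#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

// R's mean() for doubles uses long-double accumulation with a second
// correction pass; replicated here so the compiled trainer is bit-identical
// to the pure-R reference engine.
static double r_mean(const double *x, int n) {
  long double s = 0.0;
  for (int i = 0; i < n; ++i) s += x[i];
  s /= n;
  long double t = 0.0;
  for (int i = 0; i < n; ++i) t += (x[i] - s);
  s += t / n;
  return (double)s;
}

static inline double kernel(double x, double v, double s) {
  double k = 1.0 - std::fabs(v - x) / s;
  return k > 0.0 ? k : 0.0;
}

struct Neuron {
  int id;
  double v[4];   // stored centers, one per observation dimension
  int action;    // 0-based efferent output index
  double weight; // signed efferent weight (negative: inhibition)
  double reward; // low-pass accumulated reward
};

// Full cart-pole training run for one seed. Uses R's RNG stream (seeded
// from R with set.seed) in the same order as the reference engine:
// 4 uniforms per trial reset, one uniform per tied action choice.
// [[Rcpp::export]]
List cartpole_train_cpp(double spread, int memory, int max_size, double tau,
                        int max_trials, int max_steps, bool stop_when_solved,
                        NumericVector env, NumericVector obs_low,
                        NumericVector obs_high, bool running_norm) {
  const double gravity = env[0], cart_mass = env[1], pole_mass = env[2],
               half_length = env[3], force_mag = env[4], dt = env[5],
               x_threshold = env[6], theta_threshold = env[7];
  const double total_mass = cart_mass + pole_mass;
  const double polemass_length = pole_mass * half_length;

  RNGScope rng;
  std::vector<Neuron> net;
  int next_id = 1;
  std::vector<int> balance, neuron_counts;
  int trials_to_solve = 0;
  long long window_sum = 0; // balance sum over the last 100 trials

  // rolling failure window
  std::vector<std::array<double, 4> > buf_obs(memory);
  std::vector<int> buf_act(memory);

  // running per-dimension observation range (persists across trials)
  double run_min[4], run_max[4];
  bool range_started = false;

  for (int trial = 1; trial <= max_trials; ++trial) {
    double state[4];
    for (int k = 0; k < 4; ++k) state[k] = -0.05 + 0.1 * unif_rand();
    int buf_len = 0, buf_head = 0; // circular buffer of the last m steps
    int steps = 0;
    bool failed = false;

    while (steps < max_steps) {
      double obs[4];
      if (running_norm) {
        // min-max by the range of observations seen so far; the first
        // observation initializes a degenerate range and maps to 0.5
        if (!range_started) {
          for (int k = 0; k < 4; ++k) {
            run_min[k] = state[k];
            run_max[k] = state[k];
          }
          range_started = true;
        }
        for (int k = 0; k < 4; ++k) {
          if (state[k] < run_min[k]) run_min[k] = state[k];
          if (state[k] > run_max[k]) run_max[k] = state[k];
          double rng_k = run_max[k] - run_min[k];
          obs[k] = rng_k > 0.0 ? (state[k] - run_min[k]) / rng_k : 0.5;
        }
      } else {
        for (int k = 0; k < 4; ++k) {
          double c = state[k];
          if (c < obs_low[k]) c = obs_low[k];
          if (c > obs_high[k]) c = obs_high[k];
          obs[k] = (c - obs_low[k]) / (obs_high[k] - obs_low[k]);
        }
      }

      // forward pass + reward low-pass in one sweep
      double out[2] = {0.0, 0.0};
      for (size_t i = 0; i < net.size(); ++i) {
        double ks[4];
        for (int k = 0; k < 4; ++k) ks[k] = kernel(obs[k], net[i].v[k], spread);
        double a = r_mean(ks, 4);
        double keff = 1.0 - (1.0 - a) / spread;
        if (keff > 0.0) out[net[i].action] += net[i].weight * keff;
        net[i].reward = tau * net[i].reward + (1.0 - tau) * 1.0 * a;
      }

      int action;
      if (out[0] == out[1]) {
        action = (int)(unif_rand() * 2.0);
      } else {
        action = out[1] > out[0] ? 1 : 0;
      }

      // environment step (explicit Euler, accelerations from pre-step state)
      double x = state[0], x_dot = state[1],
             theta = state[2], theta_dot = state[3];
      double force = action == 1 ? force_mag : -force_mag;
      double cos_t = std::cos(theta), sin_t = std::sin(theta);
      double temp =
          (force + polemass_length * (theta_dot * theta_dot) * sin_t) /
          total_mass;
      double theta_acc =
          (gravity * sin_t - cos_t * temp) /
          (half_length *
           (4.0 / 3.0 - pole_mass * (cos_t * cos_t) / total_mass));
      double x_acc = temp - polemass_length * theta_acc * cos_t / total_mass;
      state[0] = x + dt * x_dot;
      state[1] = x_dot + dt * x_acc;
      state[2] = theta + dt * theta_dot;
      state[3] = theta_dot + dt * theta_acc;

      // push onto the failure window
      int slot = (buf_head + buf_len) % memory;
      if (buf_len == memory) {
        slot = buf_head;
        buf_head = (buf_head + 1) % memory;
      } else {
        ++buf_len;
      }
      for (int k = 0; k < 4; ++k) buf_obs[slot][k] = obs[k];
      buf_act[slot] = action;

      ++steps;
      if (std::fabs(state[0]) > x_threshold ||
          std::fabs(state[2]) > theta_threshold) {
        failed = true;
        break;
      }
    }

    if (failed && buf_len > 0) {
      std::vector<double> rewards(net.size());
      for (size_t i = 0; i < net.size(); ++i) rewards[i] = net[i].reward;
      double r0 = net.empty() ? 0.0 : r_mean(rewards.data(), (int)net.size());
      // newest step first: age t = 0 gets weight -1
      for (int t = 0; t < buf_len; ++t) {
        int pos = (buf_head + buf_len - 1 - t) % memory;
        Neuron nu;
        nu.id = next_id++;
        for (int k = 0; k < 4; ++k) nu.v[k] = buf_obs[pos][k];
        nu.action = buf_act[pos];
        nu.weight = -(1.0 - (double)t / (double)memory);
        nu.reward = r0;
        net.push_back(nu);
      }
      if (max_size > 0) {
        while ((int)net.size() > max_size) {
          size_t worst = 0;
          for (size_t i = 1; i < net.size(); ++i) {
            if (net[i].reward < net[worst].reward) worst = i;
          }
          net.erase(net.begin() + worst);
        }
      }
    }

    balance.push_back(steps);
    neuron_counts.push_back((int)net.size());
    window_sum += steps;
    int nb = (int)balance.size();
    if (nb > 100) window_sum -= balance[nb - 101];
    if (nb >= 100 && trials_to_solve == 0 &&
        (double)window_sum / 100.0 > 475.0) {
      trials_to_solve = nb;
      if (stop_when_solved) break;
    }
    if (trial % 50 == 0) Rcpp::checkUserInterrupt();
  }

  int n = (int)net.size();
  IntegerVector ids(n), actions(n);
  NumericVector weights(n), rewards_out(n);
  NumericMatrix centers(n, 4);
  for (int i = 0; i < n; ++i) {
    ids[i] = net[i].id;
    actions[i] = net[i].action + 1; // back to R's 1-based outputs
    weights[i] = net[i].weight;
    rewards_out[i] = net[i].reward;
    for (int k = 0; k < 4; ++k) centers(i, k) = net[i].v[k];
  }
  return List::create(
      _["balance"] = wrap(balance), _["neuron_counts"] = wrap(neuron_counts),
      _["trials_to_solve"] = trials_to_solve, _["ids"] = ids,
      _["centers"] = centers, _["actions"] = actions, _["weights"] = weights,
      _["rewards"] = rewards_out, _["next_id"] = next_id);
}
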