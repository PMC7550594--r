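#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Random-draw primitives. These mirror R/rng.R draw-for-draw: the pure-R
// round dynamics (initialize_run + step_round) and this core consume R's
// global RNG stream in the same order, so results are bit-identical under
// the same seed. Any change here must be mirrored there.

static inline int draw_index(int n) {
  int r = static_cast<int>(unif_rand() * n);
  if (r >= n) r = n - 1;
  return r; // 0-based
}

static inline int draw_categorical(const double *p, int n) {
  double u = unif_rand();
  double acc = 0.0;
  int last_pos = -1;
  for (int j = 0; j < n; ++j) {
    if (p[j] > 0.0) {
      acc += p[j];
      last_pos = j;
      if (u <= acc) return j;
    }
  }
  return last_pos;
}

static void fy_shuffle(std::vector<int> &perm) {
  const int n = static_cast<int>(perm.size());
  for (int t = n; t >= 2; --t) {
    int j = draw_index(t);
    std::swap(perm[t - 1], perm[j]);
  }
}

// Simulate n_runs independent runs of R rounds each and return the raw
// score ingredients, one row per run:
//   [gamma_init, gamma_final, delta_init, delta_final]
// a: N x N row-stochastic communication matrix (zero diagonal);
// s, p_comm, p_obs: per-agent traits; k_env: environment length K;
// m_mask: per-agent access-mask size round(H * K), computed by the caller.
// [[Rcpp::export]]
NumericMatrix cpp_run_batch(NumericMatrix a, NumericVector s,
                            NumericVector p_comm, NumericVector p_obs,
                            int k_env, int m_mask, int n_rounds,
                            int n_runs) {
  const int n = a.nrow();
  if (a.ncol() != n || s.size() != n || p_comm.size() != n ||
      p_obs.size() != n)
    stop("structural error: genome component shapes disagree");
  if (k_env < 1 || n_rounds < 1 || n_runs < 1 || m_mask < 0 ||
      m_mask > k_env)
    stop("invalid run dimensions");

  NumericMatrix out(n_runs, 4);
  std::vector<double> env(k_env), beliefs(n * k_env); // beliefs column-major
  std::vector<int> mask(n * m_mask), pool(k_env), perm(n);
  // copy A row-major for cache-friendly categorical walks
  std::vector<double> arow(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) arow[i * n + j] = a(i, j);

  RNGScope scope;
  for (int run = 0; run < n_runs; ++run) {
    // 1. environment
    for (int k = 0; k < k_env; ++k) env[k] = unif_rand();
    // 2. beliefs, column-major (agent-within-facet order)
    for (int k = 0; k < k_env; ++k)
      for (int i = 0; i < n; ++i) beliefs[i + n * k] = unif_rand();
    // 3. access masks: partial Fisher-Yates per agent, stored sorted
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < k_env; ++k) pool[k] = k;
      for (int t = 0; t < m_mask; ++t) {
        int j = t + draw_index(k_env - t);
        std::swap(pool[t], pool[j]);
      }
      if (m_mask > 0) {
        std::sort(pool.begin(), pool.begin() + m_mask);
        std::copy(pool.begin(), pool.begin() + m_mask,
                  mask.begin() + i * m_mask);
      }
    }

    // initial scores
    double gamma_init = 0.0, delta_init = 0.0;
    for (int k = 0; k < k_env; ++k) {
      double mean = 0.0, sq = 0.0;
      for (int i = 0; i < n; ++i) {
        double b = beliefs[i + n * k];
        gamma_init += std::abs(b - env[k]);
        mean += b;
        sq += b * b;
      }
      mean /= n;
      sq /= n;
      double var = sq - mean * mean;
      delta_init += std::sqrt(var > 0.0 ? var : 0.0);
    }
    gamma_init /= static_cast<double>(n) * k_env;
    delta_init /= k_env;

    // 4. rounds
    for (int r = 0; r < n_rounds; ++r) {
      for (int i = 0; i < n; ++i) perm[i] = i;
      fy_shuffle(perm);
      for (int t = 0; t < n; ++t) {
        const int i = perm[t];
        if (unif_rand() < p_comm[i]) {
          int j = draw_categorical(&arow[i * n], n);
          if (j >= 0) {
            int k = draw_index(k_env);
            double &bj = beliefs[j + n * k];
            bj += s[j] * (beliefs[i + n * k] - bj);
          }
        }
        if (unif_rand() < p_obs[i] && m_mask > 0) {
          int k = mask[i * m_mask + draw_index(m_mask)];
          beliefs[i + n * k] = env[k];
        }
      }
    }

    // final scores
    double gamma_final = 0.0, delta_final = 0.0;
    for (int k = 0; k < k_env; ++k) {
      double mean = 0.0, sq = 0.0;
      for (int i = 0; i < n; ++i) {
        double b = beliefs[i + n * k];
        gamma_final += std::abs(b - env[k]);
        mean += b;
        sq += b * b;
      }
      mean /= n;
      sq /= n;
      double var = sq - mean * mean;
      delta_final += std::sqrt(var > 0.0 ? var : 0.0);
    }
    gamma_final /= static_cast<double>(n) * k_env;
    delta_final /= k_env;

    out(run, 0) = gamma_init;
    out(run, 1) = gamma_final;
    out(run, 2) = delta_init;
    out(run, 3) = delta_final;
  }
  return out;
}
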