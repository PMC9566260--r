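#include <Rcpp.h>
using namespace Rcpp;

// Compiled lifetime engine: runs every individual in a population through
// m periods of the within-lifetime dynamics (encounter frequencies,
// logistic outcome probabilities, prediction errors, leaky updates of
// prediction/reinforcement, and effort under the absolute-effort budget).
//
// RNG: reallocation pair draws use R's uniform stream with exactly the
// same draw protocol as the R reference engine (one unif_rand per index,
// rejection of the duplicate partner), so seeded runs match the R engine
// bit for bit. Individuals are processed in row order.

static inline int draw_index(int n) {
  int i = (int)std::floor(unif_rand() * n);
  if (i >= n) i = n - 1;
  return i;
}

// [[Rcpp::export]]
List cpp_run_lifetimes(NumericMatrix G, NumericMatrix V,
                       NumericVector z, NumericVector p,
                       List params,
                       bool freeze_reinforcement,
                       bool freeze_effort) {
  const int S = G.nrow();
  const int n = G.ncol();
  if (V.nrow() != S || V.ncol() != n || z.size() != n || p.size() != n)
    stop("dimension mismatch between profiles and situation grid");

  const int m = as<int>(params["n_periods"]);
  const double A = as<double>(params["A"]);
  const double alpha_e = as<double>(params["alpha_e"]);
  const double gamma_e = as<double>(params["gamma_e"]);
  const double alpha_r = as<double>(params["alpha_r"]);
  const double gamma_g = as<double>(params["gamma_g"]);
  const double alpha_c = as<double>(params["alpha_c"]);
  const double kappa = as<double>(params["kappa"]);
  const int n_decisions = as<int>(params["n_decisions"]);

  NumericVector fitness(S);
  NumericMatrix wellbeing(m, S);
  NumericMatrix first_bq(S, n), final_bq(S, n), final_eps(S, n);
  NumericMatrix final_lambda(S, n), final_R(S, n), final_effort(S, n);
  NumericMatrix final_b(S, n), final_q(S, n), final_omega(S, n);
  NumericVector final_fitness_increment(S);

  std::vector<double> lam(n), R(n), phi(n), b(n), q(n), eps(n), w(n);

  for (int y = 0; y < S; ++y) {
    std::fill(lam.begin(), lam.end(), 0.0);
    std::fill(R.begin(), R.end(), 0.0);
    std::fill(phi.begin(), phi.end(), 0.0);
    double F = 0.0;

    for (int k = 0; k < m; ++k) {
      double pos = 0.0, tot = 0.0, dF = 0.0;
      for (int i = 0; i < n; ++i) {
        q[i] = std::pow(A, phi[i]) * p[i];
        b[i] = 1.0 / (1.0 + std::exp(-(G(y, i) + R[i])));
        eps[i] = V(y, i) - lam[i];
        w[i] = b[i] * q[i] * eps[i];
        if (w[i] > 0.0) pos += w[i];
        tot += std::fabs(w[i]);
        dF += b[i] * q[i] * z[i];
      }
      wellbeing(k, y) = (tot > 0.0) ? pos / tot : 0.5;
      F += dF;

      if (k == 0) {
        for (int i = 0; i < n; ++i) first_bq(y, i) = b[i] * q[i];
      }
      if (k == m - 1) {
        for (int i = 0; i < n; ++i) {
          final_bq(y, i) = b[i] * q[i];
          final_eps(y, i) = eps[i];
          final_b(y, i) = b[i];
          final_q(y, i) = q[i];
          final_omega(y, i) = w[i];
        }
        final_fitness_increment[y] = dF;
      }

      double abs_phi = 0.0;
      for (int i = 0; i < n; ++i) {
        lam[i] = gamma_e * lam[i] + alpha_e * w[i];
        if (!freeze_reinforcement) R[i] = gamma_g * R[i] + alpha_r * w[i];
        abs_phi += std::fabs(phi[i]);
      }
      if (!freeze_effort) {
        if (abs_phi < kappa) {
          for (int i = 0; i < n; ++i) phi[i] += alpha_c * w[i];
        } else {
          for (int u = 0; u < n_decisions; ++u) {
            int i = draw_index(n);
            int j = draw_index(n);
            while (j == i) j = draw_index(n);
            double s = (phi[i] >= 0.0) ? 1.0 : -1.0;
            double delta =
              (std::pow(A, phi[i] + alpha_c * s) - std::pow(A, phi[i])) * w[i] +
              (std::pow(A, phi[j] - alpha_c * s) - std::pow(A, phi[j])) * w[j];
            if (delta > 0.0) {
              phi[i] += alpha_c * s;
              phi[j] -= alpha_c * s;
            } else if (delta < 0.0) {
              phi[i] -= alpha_c * s;
              phi[j] += alpha_c * s;
            }
          }
        }
      }
    }

    fitness[y] = F;
    for (int i = 0; i < n; ++i) {
      final_lambda(y, i) = lam[i];
      final_R(y, i) = R[i];
      final_effort(y, i) = phi[i];
    }
  }

  return List::create(
    _["fitness"] = fitness,
    _["wellbeing"] = wellbeing,
    _["first_bq"] = first_bq,
    _["final_bq"] = final_bq,
    _["final_eps"] = final_eps,
    _["final_lambda"] = final_lambda,
    _["final_R"] = final_R,
    _["final_effort"] = final_effort,
    _["final_b"] = final_b,
    _["final_q"] = final_q,
    _["final_omega"] = final_omega,
    _["final_fitness_increment"] = final_fitness_increment
  );
}
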