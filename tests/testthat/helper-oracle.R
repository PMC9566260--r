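# Scalar, loop-based oracle for the within-period dynamics, written with
# element-by-element arithmetic and no calls into the package's update
# functions. Used to verify the vectorized and compiled engines.

oracle_step <- function(G, V, lam, R, phi, z, p, par,
                        freeze_R = FALSE, freeze_phi = FALSE) {
  n <- length(z)
  b <- q <- eps <- w <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- par$A^phi[i] * p[i]
    b[i] <- 1 / (1 + exp(-(G[i] + R[i])))
    eps[i] <- V[i] - lam[i]
    w[i] <- b[i] * q[i] * eps[i]
  }
  pos <- 0; tot <- 0; fit <- 0
  for (i in seq_len(n)) {
    if (w[i] > 0) pos <- pos + w[i]
    tot <- tot + abs(w[i])
    fit <- fit + b[i] * q[i] * z[i]
  }
  wellbeing <- if (tot == 0) 0.5 else pos / tot

  abs_phi <- 0
  for (i in seq_len(n)) {
    lam[i] <- par$gamma_e * lam[i] + par$alpha_e * w[i]
    if (!freeze_R) R[i] <- par$gamma_g * R[i] + par$alpha_r * w[i]
    abs_phi <- abs_phi + abs(phi[i])
  }
  if (!freeze_phi) {
    if (abs_phi < par$kappa) {
      for (i in seq_len(n)) phi[i] <- phi[i] + par$alpha_c * w[i]
    } else {
      for (u in seq_len(par$n_decisions)) {
        draw <- function() {
          k <- floor(runif(1) * n) + 1
          if (k > n) n else k
        }
        i <- draw()
        j <- draw()
        while (j == i) j <- draw()
        s <- if (phi[i] >= 0) 1 else -1
        delta <- (par$A^(phi[i] + par$alpha_c * s) - par$A^phi[i]) * w[i] +
          (par$A^(phi[j] - par$alpha_c * s) - par$A^phi[j]) * w[j]
        if (delta > 0) {
          phi[i] <- phi[i] + par$alpha_c * s
          phi[j] <- phi[j] - par$alpha_c * s
        } else if (delta < 0) {
          phi[i] <- phi[i] - par$alpha_c * s
          phi[j] <- phi[j] + par$alpha_c * s
        }
      }
    }
  }
  list(b = b, q = q, eps = eps, w = w, wellbeing = wellbeing,
       fitness_increment = fit, lam = lam, R = R, phi = phi)
}

# Random small agent state used in the property tests.
random_state <- function(n, par, budget_used = NULL) {
  prof <- heritable_profile(runif(n, -2, 2), runif(n, -2, 2))
  st <- agent_state(prof)
  st$lambda <- runif(n, -1, 1)
  st$R <- runif(n, -1, 1)
  phi <- runif(n, -1, 1)
  if (!is.null(budget_used)) {
    phi <- phi / sum(abs(phi)) * budget_used
  }
  st$effort <- phi
  st
}

# Reduced-size study profile used where the full configuration would be
# disproportionate to what the property under test needs.
reduced_params <- function(...) {
  amm_params(n_situations = 40, n_periods = 100, pop_size = 50,
             n_generations = 10, ...)
}
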