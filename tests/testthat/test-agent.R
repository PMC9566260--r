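test_that("outcome probability is the logistic of instinct plus reinforcement", {
  expect_equal(outcome_probability(0, 0), 0.5)
  # logistic(3) computed independently: 1/(1+exp(-3))
  expect_equal(outcome_probability(1.5, 1.5), 0.952574126822433,
               tolerance = 1e-12)
  expect_equal(outcome_probability(-1.5, -1.5), 1 - 0.952574126822433,
               tolerance = 1e-12)
  x <- runif(20, -5, 5)
  expect_true(all(outcome_probability(x, 0) > 0 &
                    outcome_probability(x, 0) < 1))
})

test_that("prediction error and its weighting are elementwise products", {
  expect_equal(prediction_error(1, 0), 1)
  expect_equal(prediction_error(-1.2, -0.5), -0.7)
  expect_equal(prediction_error(0.37, 0.37), 0)
  expect_equal(weighted_prediction_error(0.5, 0.4, 1.0), 0.2)
  expect_equal(weighted_prediction_error(0.8, 3.2, 0), 0)
  expect_equal(weighted_prediction_error(0.9526, 0.5, -0.7), -0.333410,
               tolerance = 1e-6)
})

test_that("prediction and reinforcement updates have the stated fixed points", {
  p <- amm_params()
  expect_equal(update_prediction(0, 0.1, p), 0.2)
  expect_equal(update_prediction(1, 0, p), 0.99)
  expect_equal(update_reinforcement(0, 0.1, p), 0.3)
  expect_equal(update_reinforcement(1, 0, p), 0.98)
  # constant-signal fixed points: alpha * omega / (1 - gamma), verified by
  # iterating to convergence rather than assuming the closed form
  for (omega_bar in c(0.02, -0.013)) {
    lam <- 0
    R <- 0
    for (k in 1:3000) {
      lam <- update_prediction(lam, omega_bar, p)
      R <- update_reinforcement(R, omega_bar, p)
    }
    expect_equal(lam, 200 * omega_bar, tolerance = 1e-8)
    expect_equal(R, 150 * omega_bar, tolerance = 1e-10)
  }
})

test_that("unconstrained effort follows the weighted error; reinforcement sign is correct", {
  p <- amm_params()
  expect_equal(update_effort_unconstrained(0, 0.05, p), 5e-4)
  expect_equal(update_effort_unconstrained(0.2, 0, p), 0.2)
  expect_equal(update_effort_unconstrained(0.1, -0.3, p), 0.097)
  # positive omega reinforces approach, negative suppresses it
  expect_gt(update_reinforcement(0.4, 0.2, p), 0.4 * p$gamma_g)
  expect_lt(update_reinforcement(0.4, -0.2, p), 0.4 * p$gamma_g)
})

test_that("a single reallocation decision moves effort toward the better margin", {
  # two situations so the drawn pair is always {1, 2}; the marginal gain
  # (evaluated by hand from the swap formula) favours effort on the first:
  # (5^0.51 - 5^0.5)*0.2 + (5^0.29 - 5^0.3)*0.1 = +0.00467 > 0
  p <- amm_params(n_situations = 2, n_decisions = 1L)
  set.seed(11)
  out <- reallocate_effort(c(0.5, 0.3), c(0.2, 0.1), p)
  expect_equal(out, c(0.51, 0.29), tolerance = 1e-12)
  delta <- (5^0.51 - 5^0.5) * 0.2 + (5^0.29 - 5^0.3) * 0.1
  expect_equal(delta, 0.00466839, tolerance = 1e-5)
})

test_that("reallocation conserves the signed effort sum and ignores zero margins", {
  p <- amm_params(n_situations = 6)
  for (trial in 1:25) {
    phi <- runif(6, -1, 1)
    omega <- runif(6, -0.5, 0.5)
    out <- reallocate_effort(phi, omega, p)
    expect_equal(sum(out), sum(phi), tolerance = 1e-12)
  }
  # zero weighted errors: no decision has a margin, effort unchanged
  phi <- c(0.4, -0.2, 0.1)
  expect_equal(reallocate_effort(phi, c(0, 0, 0), amm_params(n_situations = 3)),
               phi)
  expect_error(reallocate_effort(0.1, 0.2, amm_params(n_situations = 2)),
               "two situations")
})

test_that("first period of a naive agent reflects only heritable values", {
  p <- amm_params(n_situations = 10)
  env <- situation_grid(p)
  prof <- heritable_profile(G = seq(-1, 1, length.out = 10),
                            V = seq(1, -1, length.out = 10))
  st <- agent_state(prof)
  expect_equal(st$lambda, numeric(10))
  expect_equal(st$R, numeric(10))
  expect_equal(st$effort, numeric(10))
  out <- step_period(st, env, p)
  expect_equal(out$record$eps, prof$V)
  expect_equal(out$record$b, 1 / (1 + exp(-prof$G)))
  expect_equal(out$record$q, env$base_frequency)
  expect_equal(out$record$omega,
               out$record$b * out$record$q * out$record$eps)
})

test_that("an agent with no cue values or instincts has neutral wellbeing", {
  p <- amm_params(n_situations = 4)
  env <- situation_grid(p)
  st <- agent_state(heritable_profile(numeric(4), numeric(4)))
  out <- step_period(st, env, p)
  expect_equal(out$record$wellbeing, 0.5)
  expect_equal(out$record$fitness_increment, 0)
})

test_that("step_period matches the scalar oracle on random 3-situation states", {
  p <- amm_params(n_situations = 3)
  env <- situation_grid(p)
  set.seed(42)
  for (trial in 1:100) {
    st <- random_state(3, p)
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    got <- step_period(st, env, p)
    set.seed(seed)
    want <- oracle_step(st$heritable$G, st$heritable$V, st$lambda, st$R,
                        st$effort, env$z, env$base_frequency, p)
    expect_equal(got$record$omega, want$w, tolerance = 1e-12)
    expect_equal(got$record$wellbeing, want$wellbeing, tolerance = 1e-12)
    expect_equal(got$record$fitness_increment, want$fitness_increment,
                 tolerance = 1e-12)
    expect_equal(got$state$lambda, want$lam, tolerance = 1e-12)
    expect_equal(got$state$R, want$R, tolerance = 1e-12)
    expect_equal(got$state$effort, want$phi, tolerance = 1e-12)
  }
})

test_that("step_period matches the scalar oracle in the constrained (reallocation) regime", {
  p <- amm_params(n_situations = 3, kappa = 0.5)
  env <- situation_grid(p)
  set.seed(4242)
  for (trial in 1:30) {
    st <- random_state(3, p, budget_used = p$kappa * 1.2)
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    got <- step_period(st, env, p)
    set.seed(seed)
    want <- oracle_step(st$heritable$G, st$heritable$V, st$lambda, st$R,
                        st$effort, env$z, env$base_frequency, p)
    expect_equal(got$state$effort, want$phi, tolerance = 1e-12)
    expect_equal(sum(got$state$effort), sum(st$effort), tolerance = 1e-12)
  }
})

test_that("compiled and R lifetime engines agree to machine precision", {
  p <- amm_params(n_situations = 15, n_periods = 60)
  env <- situation_grid(p)
  set.seed(3)
  prof <- heritable_profile(rnorm(15, 0, 0.4), rnorm(15, 0, 0.4))
  set.seed(99)
  a <- run_lifetime(prof, env, p, engine = "cpp")
  set.seed(99)
  b <- run_lifetime(prof, env, p, engine = "r")
  expect_equal(a$fitness, b$fitness, tolerance = 1e-12)
  expect_equal(a$wellbeing, b$wellbeing, tolerance = 1e-12)
  expect_equal(a$final_state$lambda, b$final_state$lambda, tolerance = 1e-12)
  expect_equal(a$final_state$R, b$final_state$R, tolerance = 1e-12)
  expect_equal(a$final_state$effort, b$final_state$effort, tolerance = 1e-12)
  expect_equal(a$final_record$omega, b$final_record$omega, tolerance = 1e-12)
  # constrained regime: tiny budget forces reallocation mid-lifetime
  p2 <- amm_params(n_situations = 8, n_periods = 80, kappa = 0.02)
  env2 <- situation_grid(p2)
  prof2 <- heritable_profile(1.2 * sign(env2$z), 1.2 * sign(env2$z))
  set.seed(7)
  a2 <- run_lifetime(prof2, env2, p2, engine = "cpp")
  set.seed(7)
  b2 <- run_lifetime(prof2, env2, p2, engine = "r")
  expect_equal(a2$final_state$effort, b2$final_state$effort,
               tolerance = 1e-12)
})

test_that("lifetime fitness is the b*q*z double sum and responds to adaptation", {
  # single-period sanity: one dominant situation, known product
  p <- amm_params(n_situations = 2, n_periods = 1)
  env <- situation_grid(p)
  prof <- heritable_profile(c(0, 0), c(0, 0))
  life <- run_lifetime(prof, env, p, engine = "r")
  expect_equal(life$fitness, sum(0.5 * env$base_frequency * env$z))
  # all z = 0: fitness identically 0
  env0 <- env
  env0$z <- c(0, 0)
  expect_equal(run_lifetime(prof, env0, p, engine = "r")$fitness, 0)
  # adapted profile beats the zero profile in the same environment
  p3 <- amm_params(n_situations = 20, n_periods = 100)
  env3 <- situation_grid(p3)
  adapted <- heritable_profile(1.5 * sign(env3$z), 1.5 * sign(env3$z))
  zero <- heritable_profile(numeric(20), numeric(20))
  set.seed(1)
  f_adapted <- run_lifetime(adapted, env3, p3)$fitness
  set.seed(1)
  f_zero <- run_lifetime(zero, env3, p3)$fitness
  expect_gt(f_adapted, f_zero)
})

test_that("with frozen behaviour the prediction converges to its closed-form limit", {
  # freezes hold b and q constant, so lambda iterates a linear map whose
  # fixed point is alpha_e*b*q*V / (1 - gamma_e + alpha_e*b*q)
  p <- amm_params(n_situations = 2, n_periods = 1)
  env <- situation_grid(p)
  prof <- heritable_profile(c(0.8, -0.6), c(1.1, -0.9))
  st <- agent_state(prof)
  b <- outcome_probability(prof$G, 0)
  q <- env$base_frequency
  lam_star <- p$alpha_e * b * q * prof$V / (1 - p$gamma_e + p$alpha_e * b * q)
  prev_abs_eps <- abs(prof$V)
  monotone <- TRUE
  for (k in 1:4000) {
    st <- step_period(st, env, p,
                      freeze_reinforcement = TRUE, freeze_effort = TRUE)$state
    abs_eps <- abs(prof$V - st$lambda)
    monotone <- monotone && all(abs_eps <= prev_abs_eps + 1e-14)
    prev_abs_eps <- abs_eps
  }
  expect_true(monotone)
  expect_equal(st$lambda, lam_star, tolerance = 1e-8)
  # the residual error embodies incomplete hedonic adaptation
  expect_true(all(abs(prof$V - lam_star) > 0))
})

test_that("the effort budget bound holds over default-parameter lifetimes", {
  p <- amm_params(n_situations = 20, n_periods = 200)
  env <- situation_grid(p)
  set.seed(5)
  for (trial in 1:5) {
    prof <- heritable_profile(rnorm(20, 0, 0.4), rnorm(20, 0, 0.4))
    life <- run_lifetime(prof, env, p)
    expect_lte(sum(abs(life$final_state$effort)),
               p$kappa + p$n_decisions * p$alpha_c)
  }
})
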