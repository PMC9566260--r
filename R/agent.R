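#' Probability of allowing a situation's outcome
#'
#' One of two behaviours is chosen in every encounter: nullify the situation
#' (no outcome, no fitness change) or allow the outcome. The probability of
#' allowing it is a logistic function of the sum of the heritable instinct
#' and the learned reinforcement value, `1 / (1 + exp(-(G + R)))`; the
#' nullifying behaviour has the complementary probability.
#'
#' @param G Instinct value(s).
#' @param R Reinforcement value(s).
#' @return Outcome probability(ies) in (0, 1).
#' @examples
#' outcome_probability(0, 0)       # 0.5
#' outcome_probability(1.5, 1.5)   # ~0.9526
#' @export
outcome_probability <- function(G, R) {
  1 / (1 + exp(-(G + R)))
}

#' Prediction error of a cue
#'
#' The difference between a cue's (heritable) value and its current
#' predicted value, `V - lambda`. Its magnitude is the model's proxy for
#' emotional intensity.
#'
#' @param V Cue value(s).
#' @param lambda Predicted value(s).
#' @return Prediction error(s).
#' @examples
#' prediction_error(1, 0)
#' prediction_error(-1.2, -0.5)
#' @export
prediction_error <- function(V, lambda) {
  V - lambda
}

#' Frequency-weighted prediction error
#'
#' The prediction error scaled by how often the outcome is actually
#' experienced: outcome probability `b` times encounter frequency `q`.
#' This weighted error is the common learning signal for predictions,
#' reinforcement and effort, and the ingredient of reflective wellbeing.
#'
#' @param b Outcome probability(ies) in (0, 1).
#' @param q Encounter frequency(ies), non-negative.
#' @param eps Prediction error(s).
#' @return Weighted prediction error(s) `b * q * eps`.
#' @examples
#' weighted_prediction_error(0.5, 0.4, 1.0)  # 0.2
#' @export
weighted_prediction_error <- function(b, q, eps) {
  b * q * eps
}

#' Update the predicted value
#'
#' Leaky integration of the weighted prediction error:
#' `lambda' = gamma_e * lambda + alpha_e * omega`. Under a constant signal
#' `omega`, iterates converge geometrically to
#' `alpha_e * omega / (1 - gamma_e)`.
#'
#' @param lambda Current predicted value(s).
#' @param omega Weighted prediction error(s) of the current period.
#' @param params An [amm_params()] object supplying `gamma_e` and `alpha_e`.
#' @return Updated predicted value(s).
#' @export
update_prediction <- function(lambda, omega, params = amm_params()) {
  params <- as_amm_params(params)
  params$gamma_e * lambda + params$alpha_e * omega
}

#' Update the learned reinforcement value
#'
#' `R' = gamma_g * R + alpha_r * omega`: positive weighted errors reinforce
#' allowing the outcome, negative ones suppress it, and retention
#' `gamma_g < 1` makes unrefreshed reinforcement decay.
#'
#' @param R Current reinforcement value(s).
#' @inheritParams update_prediction
#' @return Updated reinforcement value(s).
#' @export
update_reinforcement <- function(R, omega, params = amm_params()) {
  params <- as_amm_params(params)
  params$gamma_g * R + params$alpha_r * omega
}

#' Unconstrained effort update
#'
#' While the total absolute effort is below the budget `kappa`, effort on
#' every situation moves in the direction of its weighted prediction error:
#' `phi' = phi + alpha_c * omega`.
#'
#' @param effort Effort vector.
#' @param omega Weighted prediction errors, same length.
#' @inheritParams update_prediction
#' @return Updated effort vector.
#' @export
update_effort_unconstrained <- function(effort, omega, params = amm_params()) {
  params <- as_amm_params(params)
  effort + params$alpha_c * omega
}

# sign convention for effort reallocation: s(0) = +1 so a zero-effort
# situation is not an absorbing state.
effort_sign <- function(phi) {
  ifelse(phi >= 0, 1, -1)
}

# Draw an index in 1..n from R's uniform stream. The draw protocol
# (one unif_rand per index, rejection for the duplicate partner) is
# mirrored exactly in src/lifetimes.cpp so both engines consume the
# RNG identically.
draw_index <- function(n) {
  i <- as.integer(floor(stats::runif(1L) * n)) + 1L
  if (i > n) n else i
}

#' Reallocate effort between situations under a binding budget
#'
#' Once the absolute-effort budget `kappa` binds, an agent can no longer
#' add net effort and instead makes `n_decisions` pairwise reallocation
#' decisions per period. Each decision draws two distinct situations `i`
#' and `j` at random and evaluates the marginal change in weighted
#' prediction error of shifting one effort step from `j` to `i`:
#' `Delta = (A^(phi_i + alpha_c s_i) - A^(phi_i)) * omega_i +
#'          (A^(phi_j - alpha_c s_i) - A^(phi_j)) * omega_j`
#' with `s_i` the sign of `phi_i` (the sign of zero taken as +1). If
#' `Delta > 0` the shift is applied; if `Delta < 0` the opposite shift is
#' applied; a zero margin leaves effort unchanged. Decisions are applied
#' sequentially, and the signed total effort is conserved exactly.
#'
#' @param effort Effort vector (length >= 2).
#' @param omega Weighted prediction errors, same length.
#' @inheritParams update_prediction
#' @return Updated effort vector with the same signed sum.
#' @export
reallocate_effort <- function(effort, omega, params = amm_params()) {
  params <- as_amm_params(params)
  n <- length(effort)
  if (n < 2L) {
    stop("effort reallocation needs at least two situations", call. = FALSE)
  }
  stopifnot(length(omega) == n)
  A <- params$A
  ac <- params$alpha_c
  for (u in seq_len(params$n_decisions)) {
    i <- draw_index(n)
    j <- draw_index(n)
    while (j == i) j <- draw_index(n)
    s <- effort_sign(effort[i])
    delta <- (A^(effort[i] + ac * s) - A^effort[i]) * omega[i] +
      (A^(effort[j] - ac * s) - A^effort[j]) * omega[j]
    if (delta > 0) {
      effort[i] <- effort[i] + ac * s
      effort[j] <- effort[j] - ac * s
    } else if (delta < 0) {
      effort[i] <- effort[i] - ac * s
      effort[j] <- effort[j] + ac * s
    }
  }
  effort
}

#' Create a heritable profile
#'
#' @param G Instinct values, one per situation.
#' @param V Cue values, same length.
#' @return A list of class `amm_profile` with elements `G` and `V`.
#' @export
heritable_profile <- function(G, V) {
  stopifnot("G and V must have equal length" = length(G) == length(V),
            all(is.finite(G)), all(is.finite(V)))
  structure(list(G = as.numeric(G), V = as.numeric(V)), class = "amm_profile")
}

#' Initial (naive) agent state
#'
#' Predictions, reinforcement and effort all start at zero for the first
#' period; only the heritable profile is carried in.
#'
#' @param heritable An [heritable_profile()].
#' @return A list of class `amm_state` with elements `heritable`, `lambda`,
#'   `R`, `effort`, and `period` (0-based count of completed periods).
#' @export
agent_state <- function(heritable) {
  n <- length(heritable$G)
  structure(
    list(
      heritable = heritable,
      lambda = numeric(n),
      R = numeric(n),
      effort = numeric(n),
      period = 0L
    ),
    class = "amm_state"
  )
}

#' Advance an agent by one period
#'
#' The within-period order is: (1) encounter frequencies `q` from current
#' effort; (2) outcome probabilities `b` from current instinct and
#' reinforcement; (3) prediction errors `eps` from cue values and current
#' predictions; (4) weighted errors `omega = b q eps`; (5) the period's
#' reflective wellbeing and fitness increment from those quantities; then
#' (6) the updates, all driven by this period's `omega`: predictions,
#' reinforcement (unless frozen), and effort — the unconstrained step while
#' total absolute effort is below `kappa` (checked before the update),
#' otherwise pairwise reallocation (unless frozen).
#'
#' @param state An [agent_state()].
#' @param env A [situation_grid()] tibble (columns `z`, `base_frequency`).
#' @param params An [amm_params()] object.
#' @param freeze_reinforcement,freeze_effort If `TRUE`, hold `R` / effort
#'   constant this period (used by the hedonic-adaptation shock protocol).
#' @return A list with elements `state` (advanced state) and `record` (the
#'   period's observables: vectors `b`, `q`, `eps`, `omega` and scalars
#'   `wellbeing`, `fitness_increment`).
#' @export
step_period <- function(state, env, params = amm_params(),
                        freeze_reinforcement = FALSE,
                        freeze_effort = FALSE) {
  params <- as_amm_params(params)
  env <- as_situations(env)
  G <- state$heritable$G
  V <- state$heritable$V

  q <- effective_frequency(state$effort, env$base_frequency, params$A)
  b <- outcome_probability(G, state$R)
  eps <- prediction_error(V, state$lambda)
  omega <- weighted_prediction_error(b, q, eps)

  record <- list(
    b = b, q = q, eps = eps, omega = omega,
    wellbeing = reflective_wellbeing(omega),
    fitness_increment = sum(b * q * env$z)
  )

  state$lambda <- update_prediction(state$lambda, omega, params)
  if (!freeze_reinforcement) {
    state$R <- update_reinforcement(state$R, omega, params)
  }
  if (!freeze_effort) {
    if (sum(abs(state$effort)) < params$kappa) {
      state$effort <- update_effort_unconstrained(state$effort, omega, params)
    } else {
      state$effort <- reallocate_effort(state$effort, omega, params)
    }
  }
  state$period <- state$period + 1L

  list(state = state, record = record)
}

#' Run one agent's lifetime
#'
#' Iterates [step_period()] for `n_periods` from a naive state (predictions,
#' reinforcement and effort all zero). Lifetime fitness is the
#' expectation-weighted sum of experienced fitness changes,
#' `F = sum_k sum_i b q z`.
#'
#' @param heritable An [heritable_profile()].
#' @param env A [situation_grid()] tibble.
#' @param params An [amm_params()] object.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference R loop).
#'   Both consume the RNG identically, so seeded runs agree to machine
#'   precision.
#' @param trace If `TRUE` (R engine only) keep the full per-situation,
#'   per-period trace.
#' @return An object of class `amm_lifetime`: list with `fitness`,
#'   `wellbeing` (per-period trace), `final_state`, the final period's
#'   `record`, and optionally `trace` (a long tibble).
#' @examples
#' params <- amm_params(n_situations = 10, n_periods = 20)
#' env <- situation_grid(params)
#' prof <- heritable_profile(G = 1.5 * sign(env$z), V = 1.5 * sign(env$z))
#' set.seed(1)
#' life <- run_lifetime(prof, env, params)
#' life$fitness
#' @export
run_lifetime <- function(heritable, env, params = amm_params(),
                         engine = c("cpp", "r"), trace = FALSE) {
  engine <- match.arg(engine)
  params <- as_amm_params(params)
  env <- as_situations(env)
  stopifnot(length(heritable$G) == nrow(env))

  if (engine == "cpp" && !trace) {
    res <- cpp_run_lifetimes(
      matrix(heritable$G, nrow = 1L), matrix(heritable$V, nrow = 1L),
      env$z, env$base_frequency, params,
      FALSE, FALSE
    )
    state <- structure(
      list(
        heritable = heritable,
        lambda = drop(res$final_lambda),
        R = drop(res$final_R),
        effort = drop(res$final_effort),
        period = params$n_periods
      ),
      class = "amm_state"
    )
    record <- list(
      b = drop(res$final_b), q = drop(res$final_q),
      eps = drop(res$final_eps), omega = drop(res$final_omega),
      wellbeing = res$wellbeing[params$n_periods, 1L],
      fitness_increment = res$final_fitness_increment[1L]
    )
    out <- list(
      fitness = res$fitness[1L],
      wellbeing = res$wellbeing[, 1L],
      final_state = state,
      final_record = record
    )
    return(structure(out, class = "amm_lifetime"))
  }

  state <- agent_state(heritable)
  m <- params$n_periods
  wellbeing <- numeric(m)
  fitness <- 0
  rows <- if (trace) vector("list", m) else NULL
  record <- NULL
  for (k in seq_len(m)) {
    stepped <- step_period(state, env, params)
    state <- stepped$state
    record <- stepped$record
    wellbeing[k] <- record$wellbeing
    fitness <- fitness + record$fitness_increment
    if (trace) {
      rows[[k]] <- tibble::tibble(
        period = k,
        situation = env$situation,
        b = record$b, q = record$q,
        eps = record$eps, omega = record$omega
      )
    }
  }
  out <- list(
    fitness = fitness,
    wellbeing = wellbeing,
    final_state = state,
    final_record = record
  )
  if (trace) out$trace <- dplyr::bind_rows(rows)
  structure(out, class = "amm_lifetime")
}

#' @export
print.amm_lifetime <- function(x, ...) {
  m <- length(x$wellbeing)
  cat("<amm_lifetime>\n")
  cat(sprintf("  %d periods; fitness %.4f; final wellbeing %.4f\n",
              m, x$fitness, x$wellbeing[m]))
  invisible(x)
}
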