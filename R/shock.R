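#' Hedonic-adaptation shock protocol
#'
#' Describes a transient environmental change applied to one adapted
#' individual: after `pre_periods` of normal life, the base frequency of
#' the grid situation nearest `target_z` is multiplied by `factor` for
#' `duration` periods and then restored for `post_periods`. At shock onset
#' reinforcement learning and effort (planned control) are frozen so
#' behavioural change cannot mask the affective dynamics; prediction
#' learning stays active — it is the mechanism of hedonic adaptation.
#'
#' @param target_z Fitness-change value of the shocked situation; the
#'   nearest grid situation is used. Negative values shock an avoidance
#'   situation, positive an approach situation.
#' @param factor Frequency multiplier during the shock (default 20).
#' @param pre_periods Normal periods before onset (default 200).
#' @param duration Shock periods (default 40).
#' @param post_periods Recovery periods after reversal (default 80).
#' @param freeze_reinforcement,freeze_effort Freeze flags applied from
#'   onset onwards (defaults `TRUE`).
#' @return A list of class `amm_shock_protocol`.
#' @export
shock_protocol <- function(target_z, factor = 20,
                           pre_periods = 200L, duration = 40L,
                           post_periods = 80L,
                           freeze_reinforcement = TRUE,
                           freeze_effort = TRUE) {
  stopifnot("`factor` must be positive" = factor > 0,
            "`duration` must be at least 1" = duration >= 1L,
            pre_periods >= 0L, post_periods >= 0L)
  structure(
    list(
      target_z = as.numeric(target_z),
      factor = as.numeric(factor),
      pre_periods = as.integer(pre_periods),
      duration = as.integer(duration),
      post_periods = as.integer(post_periods),
      freeze_reinforcement = isTRUE(freeze_reinforcement),
      freeze_effort = isTRUE(freeze_effort)
    ),
    class = "amm_shock_protocol"
  )
}

#' Run a hedonic-adaptation shock experiment
#'
#' Runs one individual's lifetime in three phases — `pre` (full learning,
#' normal environment), `shock` (target situation's base frequency
#' multiplied by `factor`; reinforcement and effort frozen per the
#' protocol; prediction learning continues), and `post` (frequency
#' restored, freezes kept) — and records the per-period reflective
#' wellbeing with phase labels.
#'
#' @param heritable An [heritable_profile()], typically an adapted member
#'   of a final generation (see [representative_individual()]).
#' @param env A [situation_grid()] tibble.
#' @param protocol A [shock_protocol()].
#' @param params An [amm_params()] object.
#' @return An object of class `amm_shock`: a tibble with columns `period`,
#'   `phase` (factor pre/shock/post), and `wellbeing`, with attributes
#'   `target_situation` (grid index), `target_z` (grid value actually
#'   shocked), `protocol`, and `phase_states` (agent state at the end of
#'   each phase, used to verify the freezes).
#' @examples
#' params <- amm_params(n_situations = 20, n_periods = 50)
#' env <- situation_grid(params)
#' prof <- heritable_profile(G = 1.5 * sign(env$z), V = 1.5 * sign(env$z))
#' set.seed(1)
#' tr <- run_shock_experiment(prof, env,
#'   shock_protocol(-1.5, pre_periods = 50, duration = 20, post_periods = 30),
#'   params)
#' head(tr)
#' @export
run_shock_experiment <- function(heritable, env, protocol,
                                 params = amm_params()) {
  params <- as_amm_params(params)
  env <- as_situations(env)
  stopifnot(inherits(protocol, "amm_shock_protocol"))
  if (protocol$target_z < min(env$z) || protocol$target_z > max(env$z)) {
    stop("`target_z` lies outside the situation grid", call. = FALSE)
  }
  target <- which.min(abs(env$z - protocol$target_z))

  shocked_env <- env
  shocked_env$base_frequency[target] <-
    shocked_env$base_frequency[target] * protocol$factor

  state <- agent_state(heritable)
  phases <- c(
    rep("pre", protocol$pre_periods),
    rep("shock", protocol$duration),
    rep("post", protocol$post_periods)
  )
  wellbeing <- numeric(length(phases))
  phase_states <- list()
  for (k in seq_along(phases)) {
    ph <- phases[k]
    stepped <- step_period(
      state,
      if (ph == "shock") shocked_env else env,
      params,
      freeze_reinforcement = ph != "pre" && protocol$freeze_reinforcement,
      freeze_effort = ph != "pre" && protocol$freeze_effort
    )
    state <- stepped$state
    wellbeing[k] <- stepped$record$wellbeing
    if (k == length(phases) || phases[k + 1L] != ph) {
      phase_states[[ph]] <- state
    }
  }

  out <- tibble::tibble(
    period = seq_along(phases),
    phase = factor(phases, levels = c("pre", "shock", "post")),
    wellbeing = wellbeing
  )
  structure(
    out,
    class = c("amm_shock", class(out)),
    target_situation = target,
    target_z = env$z[target],
    protocol = protocol,
    phase_states = phase_states
  )
}

#' Phase summary of a shock trace
#'
#' Summarises the five-stage hedonic response: the pre-shock baseline, the
#' extremum at onset, the plateau reached by the end of the shock, the
#' post-reversal rebound extremum, and the late-post return level.
#' Extrema are taken in the direction of the shock's effect (minimum for
#' an avoidance shock, maximum for an approach shock, decided by the sign
#' of the onset deflection).
#'
#' @param trace An `amm_shock` tibble.
#' @param window Number of periods used for the baseline (tail of pre),
#'   the shock plateau (tail of shock), and the late-post level (tail of
#'   post). Default 10.
#' @return A one-row tibble: `baseline`, `onset_extremum`,
#'   `shock_plateau`, `rebound_extremum`, `late_post`, and `direction`
#'   (-1 for a wellbeing-lowering shock, +1 for a raising one).
#' @export
shock_phase_summary <- function(trace, window = 10L) {
  stopifnot(inherits(trace, "amm_shock"))
  pre <- trace$wellbeing[trace$phase == "pre"]
  shock <- trace$wellbeing[trace$phase == "shock"]
  post <- trace$wellbeing[trace$phase == "post"]
  tail_mean <- function(x) mean(utils::tail(x, window))
  baseline <- tail_mean(pre)
  direction <- if (shock[1L] < baseline) -1 else 1
  onset_extremum <- if (direction < 0) min(shock) else max(shock)
  rebound_extremum <- if (direction < 0) max(post) else min(post)
  tibble::tibble(
    baseline = baseline,
    onset_extremum = onset_extremum,
    shock_plateau = tail_mean(shock),
    rebound_extremum = rebound_extremum,
    late_post = tail_mean(post),
    direction = direction
  )
}

#' Recovery half-life within the shock phase
#'
#' Number of periods, counted from the onset extremum, until the wellbeing
#' trace first closes half the gap between the onset extremum and the
#' shock-phase plateau. Shorter half-lives mean faster hedonic adaptation.
#'
#' @inheritParams shock_phase_summary
#' @return Integer number of periods (NA if the gap is never half-closed).
#' @export
recovery_half_life <- function(trace, window = 10L) {
  s <- shock_phase_summary(trace, window)
  shock <- trace$wellbeing[trace$phase == "shock"]
  k0 <- if (s$direction < 0) which.min(shock) else which.max(shock)
  target <- (s$onset_extremum + s$shock_plateau) / 2
  after <- shock[seq(k0, length(shock))]
  hit <- if (s$direction < 0) which(after >= target) else which(after <= target)
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L] - 1L
}

#' Pick a representative adapted individual
#'
#' The member of the final generation whose final-period reflective
#' wellbeing is the population median (lower median for even sizes) — a
#' deterministic choice of a "typical" individual for shock experiments.
#'
#' @param evo An `amm_evolution` object.
#' @return An [heritable_profile()].
#' @export
representative_individual <- function(evo) {
  stopifnot(inherits(evo, "amm_evolution"))
  w <- evo$final$wellbeing[nrow(evo$final$wellbeing), ]
  idx <- order(w)[ceiling(length(w) / 2)]
  population_member(evo$final_population, idx)
}
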