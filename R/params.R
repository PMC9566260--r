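#' Simulation parameters
#'
#' Builds the full parameter set for the adaptive-motivation simulator.
#' Defaults are the reference configuration used throughout the package:
#' 80 situations on an even grid over \[-2, 2\], 200 periods per lifetime,
#' 300 individuals per generation, 80 generations, and the learning,
#' decay, effort and inheritance constants listed below.
#'
#' @param n_situations Number of situations on the grid (default 80).
#' @param n_periods Periods per lifetime, `m` (default 200).
#' @param pop_size Individuals per generation, `S` (default 300).
#' @param n_generations Number of generations bred (default 80).
#' @param A Base of the exponential mapping from effort to encounter
#'   frequency (default 5). Must exceed 1 so positive effort increases
#'   frequency.
#' @param alpha_e Prediction learning rate (default 2).
#' @param gamma_e Prediction retention per period, in (0,1) (default 0.99).
#' @param alpha_r Reinforcement learning rate (default 3).
#' @param gamma_g Reinforcement retention per period, in (0,1) (default 0.98).
#' @param alpha_c Effort step size per period (default 0.01).
#' @param kappa Total absolute-effort budget (default 8).
#' @param inherit_cap Magnitude cap applied to the inherited component of
#'   instincts and cue values before mutation noise (default 1.5).
#' @param mutation_sd Standard deviation of the additive mutation noise and
#'   of the founding generation's values (default 0.4).
#' @param elite_frac Fraction of the population forming the elite parent
#'   pool (default 0.10).
#' @param mate_frac Fraction forming the mate parent pool (default 0.60).
#' @param n_decisions Number of pairwise effort-reallocation decisions per
#'   period once the budget binds (default 20).
#'
#' @return An object of class `amm_params`: a validated named list.
#' @examples
#' p <- amm_params()
#' p$kappa
#' small <- amm_params(n_situations = 40, pop_size = 50, n_generations = 10,
#'                     n_periods = 100)
#' @export
amm_params <- function(n_situations = 80L,
                       n_periods = 200L,
                       pop_size = 300L,
                       n_generations = 80L,
                       A = 5,
                       alpha_e = 2,
                       gamma_e = 0.99,
                       alpha_r = 3,
                       gamma_g = 0.98,
                       alpha_c = 0.01,
                       kappa = 8,
                       inherit_cap = 1.5,
                       mutation_sd = 0.4,
                       elite_frac = 0.10,
                       mate_frac = 0.60,
                       n_decisions = 20L) {
  p <- list(
    n_situations = as.integer(n_situations),
    n_periods = as.integer(n_periods),
    pop_size = as.integer(pop_size),
    n_generations = as.integer(n_generations),
    A = as.numeric(A),
    alpha_e = as.numeric(alpha_e),
    gamma_e = as.numeric(gamma_e),
    alpha_r = as.numeric(alpha_r),
    gamma_g = as.numeric(gamma_g),
    alpha_c = as.numeric(alpha_c),
    kappa = as.numeric(kappa),
    inherit_cap = as.numeric(inherit_cap),
    mutation_sd = as.numeric(mutation_sd),
    elite_frac = as.numeric(elite_frac),
    mate_frac = as.numeric(mate_frac),
    n_decisions = as.integer(n_decisions)
  )
  validate_amm_params(p)
  structure(p, class = "amm_params")
}

validate_amm_params <- function(p) {
  stopifnot(
    "n_situations must be a positive integer >= 2" =
      is.finite(p$n_situations) && p$n_situations >= 2L,
    "n_periods must be positive" = p$n_periods >= 1L,
    "pop_size must be positive" = p$pop_size >= 1L,
    "n_generations must be positive" = p$n_generations >= 1L,
    "A must exceed 1" = is.finite(p$A) && p$A > 1,
    "learning rates must be positive" =
      p$alpha_e > 0 && p$alpha_r > 0 && p$alpha_c > 0,
    "retentions must lie in (0,1)" =
      p$gamma_e > 0 && p$gamma_e < 1 && p$gamma_g > 0 && p$gamma_g < 1,
    "kappa must be positive" = p$kappa > 0,
    "inherit_cap must be positive" = p$inherit_cap > 0,
    "mutation_sd must be non-negative" = p$mutation_sd >= 0,
    "elite_frac must not exceed mate_frac" =
      p$elite_frac > 0 && p$elite_frac <= p$mate_frac && p$mate_frac <= 1,
    "n_decisions must be positive" = p$n_decisions >= 1L
  )
  invisible(p)
}

#' @export
print.amm_params <- function(x, ...) {
  cat("<amm_params>\n")
  cat(sprintf("  grid: %d situations; lifetime: %d periods\n",
              x$n_situations, x$n_periods))
  cat(sprintf("  population: %d individuals x %d generations\n",
              x$pop_size, x$n_generations))
  cat(sprintf("  learning: alpha_e=%g gamma_e=%g alpha_r=%g gamma_g=%g\n",
              x$alpha_e, x$gamma_e, x$alpha_r, x$gamma_g))
  cat(sprintf("  effort: A=%g alpha_c=%g kappa=%g (%d decisions/period)\n",
              x$A, x$alpha_c, x$kappa, x$n_decisions))
  cat(sprintf("  inheritance: cap %g, mutation sd %g; selection top %g%% x top %g%%\n",
              x$inherit_cap, x$mutation_sd, 100 * x$elite_frac, 100 * x$mate_frac))
  invisible(x)
}

as_amm_params <- function(x) {
  if (inherits(x, "amm_params")) return(x)
  if (is.list(x)) return(do.call(amm_params, x))
  stop("`params` must be an amm_params object or a named list", call. = FALSE)
}
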