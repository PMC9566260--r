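#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evolutionary run
#'
#' @param x An `amm_evolution` object.
#' @param ... Unused.
#' @return The per-generation summary tibble (`generation`,
#'   `mean_fitness`, `min_fitness`, `max_fitness`,
#'   `mean_final_wellbeing`).
#' @export
tidy.amm_evolution <- function(x, ...) {
  x$generations
}

#' One-row summary of an evolutionary run
#'
#' @param x An `amm_evolution` object.
#' @param ... Unused.
#' @return A one-row tibble: first/last-generation mean fitness, final
#'   mean wellbeing, the negativity ratio of final prediction errors over
#'   `|z| <= 1`, and the run dimensions.
#' @export
glance.amm_evolution <- function(x, ...) {
  g <- x$generations
  tibble::tibble(
    n_generations = nrow(g),
    pop_size = x$params$pop_size,
    n_periods = x$params$n_periods,
    n_situations = x$params$n_situations,
    mean_fitness_first = g$mean_fitness[1L],
    mean_fitness_last = g$mean_fitness[nrow(g)],
    mean_final_wellbeing = g$mean_final_wellbeing[nrow(g)],
    negativity_ratio = negativity_ratio(prediction_error_profile(x))
  )
}

#' Tidy a lifetime
#'
#' @param x An `amm_lifetime` object.
#' @param ... Unused.
#' @return A tibble with `period` and `wellbeing` (plus the long
#'   per-situation trace columns if the lifetime was run with
#'   `trace = TRUE`).
#' @export
tidy.amm_lifetime <- function(x, ...) {
  wb <- tibble::tibble(period = seq_along(x$wellbeing),
                       wellbeing = x$wellbeing)
  if (!is.null(x$trace)) {
    return(dplyr::left_join(x$trace, wb, by = "period"))
  }
  wb
}

#' One-row summary of a lifetime
#'
#' @param x An `amm_lifetime` object.
#' @param ... Unused.
#' @return A one-row tibble with `fitness`, `final_wellbeing`,
#'   `mean_wellbeing`, and `total_abs_effort`.
#' @export
glance.amm_lifetime <- function(x, ...) {
  tibble::tibble(
    fitness = x$fitness,
    final_wellbeing = x$wellbeing[length(x$wellbeing)],
    mean_wellbeing = mean(x$wellbeing),
    total_abs_effort = sum(abs(x$final_state$effort))
  )
}

#' Tidy a shock trace
#'
#' @param x An `amm_shock` object.
#' @param ... Unused.
#' @return A plain tibble with `period`, `phase`, `wellbeing`.
#' @export
tidy.amm_shock <- function(x, ...) {
  tibble::tibble(period = x$period, phase = x$phase, wellbeing = x$wellbeing)
}

#' One-row summary of a shock trace
#'
#' @param x An `amm_shock` object.
#' @param ... Unused.
#' @return [shock_phase_summary()] augmented with the shocked situation's
#'   grid `z` and the recovery half-life.
#' @export
glance.amm_shock <- function(x, ...) {
  dplyr::mutate(
    shock_phase_summary(x),
    target_z = attr(x, "target_z"),
    half_life = recovery_half_life(x)
  )
}
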