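#' Plot an evolutionary run
#'
#' Mean lifetime fitness (with min-max ribbon) and mean final-period
#' reflective wellbeing across generations.
#'
#' @param object An `amm_evolution` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amm_evolution <- function(object, ...) {
  g <- tidyr::pivot_longer(
    dplyr::mutate(object$generations, wellbeing = .data$mean_final_wellbeing),
    c("mean_fitness", "wellbeing"),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(g, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "generation", y = NULL,
                  title = "Selection response and reflective wellbeing")
}

#' Plot per-situation final-generation summaries
#'
#' Population mean (point) and min-max range (segment) of a per-situation
#' quantity against the situation's fitness change `z`.
#'
#' @param evo An `amm_evolution` object.
#' @param what One of `"V"` (cue values), `"G"` (instincts), or `"eps"`
#'   (final-period prediction errors).
#' @return A ggplot object.
#' @export
plot_situations <- function(evo, what = c("V", "G", "eps")) {
  what <- match.arg(what)
  s <- evo$situations
  cols <- paste0(c("mean_", "min_", "max_"), what)
  d <- tibble::tibble(z = s$z, mean = s[[cols[1]]],
                      min = s[[cols[2]]], max = s[[cols[3]]])
  ggplot2::ggplot(d, ggplot2::aes(.data$z, .data$mean)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                            colour = "grey70") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "fitness change z", y = what,
                  title = sprintf("Final-generation %s by situation", what))
}

#' Plot a prediction-error profile
#'
#' @param object An `amm_pe_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amm_pe_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$z, .data$mean_eps)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$min_eps, ymax = .data$max_eps),
      colour = "grey70"
    ) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "fitness change z", y = "final-period prediction error",
                  title = "Negativity bias in prediction errors")
}

#' Plot a hedonic-adaptation shock trace
#'
#' @param object An `amm_shock` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amm_shock <- function(object, ...) {
  d <- tidy.amm_shock(object)
  bounds <- cumsum(table(d$phase))[1:2] + 0.5
  ggplot2::ggplot(d, ggplot2::aes(.data$period, .data$wellbeing)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = bounds, linetype = 3) +
    ggplot2::labs(x = "period", y = "reflective wellbeing",
                  title = sprintf("Hedonic adaptation (shock at z = %.2f)",
                                  attr(object, "target_z")))
}
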