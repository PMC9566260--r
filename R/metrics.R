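#' Reflective wellbeing of a period
#'
#' The share of the total weighted-prediction-error magnitude that is
#' positively valued: `sum(omega[omega > 0]) / sum(abs(omega))`, bounded in
#' \[0, 1\]. A period with no prediction error at all (all `omega` zero) is
#' defined as neutral, 0.5. The statistic is invariant to positive
#' rescaling of `omega`.
#'
#' @param omega Numeric vector of weighted prediction errors.
#' @return A number in \[0, 1\].
#' @examples
#' reflective_wellbeing(c(0.3, -0.1, 0.2))  # 0.8333
#' reflective_wellbeing(c(1, -1))           # 0.5
#' @export
reflective_wellbeing <- function(omega) {
  stopifnot(all(is.finite(omega)))
  tot <- sum(abs(omega))
  if (tot == 0) return(0.5)
  sum(omega[omega > 0]) / tot
}

#' Population-mean wellbeing at a period
#'
#' @param x An `amm_evolution` object, or a periods-by-individuals
#'   wellbeing matrix.
#' @param period Period index; defaults to the final period.
#' @return Mean reflective wellbeing across individuals at that period.
#' @export
population_mean_wellbeing <- function(x, period = NULL) {
  W <- if (inherits(x, "amm_evolution")) x$final$wellbeing else as.matrix(x)
  if (is.null(period)) period <- nrow(W)
  stopifnot(period >= 1L, period <= nrow(W))
  mean(W[period, ])
}

#' Per-situation prediction-error profile
#'
#' Population mean, minimum and maximum of the final-period (unweighted)
#' prediction error for each situation of the final evaluated generation.
#' The magnitude of these errors is the model's proxy for the strength of
#' the emotion a cue elicits.
#'
#' @param x An `amm_evolution` object, or a data frame already holding
#'   columns `z` and `mean_eps` (and optionally `min_eps`, `max_eps`).
#' @return A tibble of class `amm_pe_profile` with columns `situation`,
#'   `z`, `mean_eps`, `min_eps`, `max_eps`.
#' @export
prediction_error_profile <- function(x) {
  if (inherits(x, "amm_evolution")) {
    out <- dplyr::select(x$situations, "situation", "z",
                         "mean_eps", "min_eps", "max_eps")
  } else if (is.data.frame(x) && all(c("z", "mean_eps") %in% names(x))) {
    out <- tibble::as_tibble(x)
  } else {
    stop("`x` must be an amm_evolution or a data frame with z and mean_eps",
         call. = FALSE)
  }
  class(out) <- c("amm_pe_profile", class(tibble::tibble()))
  out
}

#' Negativity ratio of prediction errors
#'
#' Mean absolute population-mean prediction error over avoidance
#' situations (`-z_band <= z < 0`) divided by the same over approach
#' situations (`0 < z <= z_band`). A ratio above 1 means avoidance cues
#' elicit stronger prediction errors (a negativity bias). The default band
#' `z_band = 1` restricts the comparison to relatively common situations
#' (the denser half of the normal frequency curve).
#'
#' @param profile A data frame with columns `z` and `mean_eps`, e.g. from
#'   [prediction_error_profile()].
#' @param z_band Positive half-width of the comparison band.
#' @return The negativity ratio (a positive number).
#' @export
negativity_ratio <- function(profile, z_band = 1) {
  stopifnot("`z_band` must be positive" = z_band > 0)
  neg <- abs(profile$mean_eps[profile$z >= -z_band & profile$z < 0])
  pos <- abs(profile$mean_eps[profile$z > 0 & profile$z <= z_band])
  if (length(neg) == 0L || length(pos) == 0L) {
    stop("no situations on one side of the band", call. = FALSE)
  }
  mean(neg) / mean(pos)
}

#' Range asymmetry of prediction-error intensity
#'
#' Average max-minus-min spread of the final-period prediction error over
#' avoidance (`z < 0`) and approach (`z > 0`) situations. In adapted
#' populations the avoidance spread exceeds the approach spread.
#'
#' @param profile A data frame with columns `z`, `min_eps`, `max_eps`.
#' @return A one-row tibble with `spread_negative` and `spread_positive`.
#' @export
intensity_range_asymmetry <- function(profile) {
  spread <- profile$max_eps - profile$min_eps
  tibble::tibble(
    spread_negative = mean(spread[profile$z < 0]),
    spread_positive = mean(spread[profile$z > 0])
  )
}
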