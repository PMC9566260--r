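#' Build the situation grid
#'
#' Situations differ only in how much they can change fitness (`z`) and in
#' how often they occur. The grid places `n_situations` evenly spaced values
#' of `z` inclusively over \[-2, 2\]; the base encounter frequency of each
#' situation is the standard normal density at its `z`, so frequent
#' situations carry small fitness changes and rare situations large ones.
#'
#' @param params An [amm_params()] object (only `n_situations` is used), or
#'   an integer number of situations.
#' @return A tibble of class `amm_situations` with columns `situation`
#'   (1-based index), `z` (fitness change), and `base_frequency` (encounters
#'   per period, unnormalised).
#' @examples
#' grid <- situation_grid(amm_params())
#' head(grid)
#' @export
situation_grid <- function(params = amm_params()) {
  n <- if (is.numeric(params) && length(params) == 1L) {
    as.integer(params)
  } else {
    as_amm_params(params)$n_situations
  }
  if (!is.finite(n) || n < 2L) {
    stop("`n_situations` must be an integer >= 2", call. = FALSE)
  }
  z <- seq(-2, 2, length.out = n)
  tibble::new_tibble(
    list(
      situation = seq_len(n),
      z = z,
      base_frequency = stats::dnorm(z)
    ),
    class = "amm_situations"
  )
}

as_situations <- function(env) {
  if (is.data.frame(env) && all(c("z", "base_frequency") %in% names(env))) {
    return(env)
  }
  stop("`env` must be a situation grid with columns `z` and `base_frequency`",
       call. = FALSE)
}

#' Effort-modified encounter frequency
#'
#' Niche construction: an agent's effort on a situation scales its encounter
#' frequency exponentially, `q = A^effort * base`. Zero effort leaves the
#' base frequency unchanged; positive effort raises it, negative effort
#' lowers it.
#'
#' @param effort Effort value(s), unbounded here (the budget is enforced by
#'   the period update, not by this map).
#' @param base Base frequency(ies), positive.
#' @param A Exponential base, > 1 (default 5).
#' @return Numeric vector of effective frequencies.
#' @examples
#' effective_frequency(0, 0.1)    # 0.1
#' effective_frequency(1, 0.1)    # 0.5
#' effective_frequency(-1, 0.25)  # 0.05
#' @export
effective_frequency <- function(effort, base, A = 5) {
  stopifnot("`base` must be positive" = all(base > 0),
            "`A` must exceed 1" = is.finite(A) && A > 1)
  A^effort * base
}
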