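#' Found a naive population
#'
#' Every instinct and cue value in the first generation is an independent
#' draw from a normal distribution with mean 0 and standard deviation
#' `mutation_sd`: founders carry only the random component of inheritance.
#'
#' @param params An [amm_params()] object.
#' @return An object of class `amm_population`: list with `G` and `V`
#'   (pop_size x n_situations matrices) and `generation` (0 for founders).
#' @export
init_population <- function(params = amm_params()) {
  params <- as_amm_params(params)
  S <- params$pop_size
  n <- params$n_situations
  structure(
    list(
      G = matrix(stats::rnorm(S * n, 0, params$mutation_sd), S, n),
      V = matrix(stats::rnorm(S * n, 0, params$mutation_sd), S, n),
      generation = 0L
    ),
    class = "amm_population"
  )
}

#' Inherit a heritable profile from two parents
#'
#' For each situation, and independently for the instinct and the cue
#' value, the child takes either parent's value with probability one half
#' (free recombination). The chosen value is clamped to
#' `[-inherit_cap, inherit_cap]` and a normal mutation deviate with
#' standard deviation `mutation_sd` is added. Because the noise is applied
#' after the cap, realised values can exceed the cap.
#'
#' @param parent_a,parent_b [heritable_profile()] objects of equal length.
#' @param params An [amm_params()] object.
#' @return A new [heritable_profile()].
#' @export
inherit <- function(parent_a, parent_b, params = amm_params()) {
  params <- as_amm_params(params)
  n <- length(parent_a$G)
  if (length(parent_b$G) != n) {
    stop("parent profiles must have equal length", call. = FALSE)
  }
  cap <- params$inherit_cap
  sd <- params$mutation_sd
  take_a_G <- stats::runif(n) < 0.5
  take_a_V <- stats::runif(n) < 0.5
  G <- ifelse(take_a_G, parent_a$G, parent_b$G)
  V <- ifelse(take_a_V, parent_a$V, parent_b$V)
  G <- pmin(pmax(G, -cap), cap) + stats::rnorm(n, 0, sd)
  V <- pmin(pmax(V, -cap), cap) + stats::rnorm(n, 0, sd)
  heritable_profile(G, V)
}

#' Truncation-selection parent pools
#'
#' The elite pool holds the indices of the top `floor(elite_frac * S)`
#' fitnesses and the mate pool the top `floor(mate_frac * S)`; the elite
#' pool is a subset of the mate pool. Ties are broken by stable index
#' order.
#'
#' @param fitnesses Numeric vector of lifetime fitnesses, one per member.
#' @param params An [amm_params()] object.
#' @return A list with integer vectors `elite` and `mates`.
#' @export
select_parent_pools <- function(fitnesses, params = amm_params()) {
  params <- as_amm_params(params)
  S <- length(fitnesses)
  n_elite <- floor(params$elite_frac * S)
  n_mates <- floor(params$mate_frac * S)
  if (n_elite < 1L || n_mates < 1L) {
    stop("selection fractions leave an empty parent pool", call. = FALSE)
  }
  ord <- order(-fitnesses)  # stable: ties keep index order
  list(elite = ord[seq_len(n_elite)], mates = ord[seq_len(n_mates)])
}

#' Breed the next generation
#'
#' Each of the `pop_size` offspring draws one parent uniformly (with
#' replacement) from the elite pool and one from the mate pool,
#' independently per offspring; self-pairing is possible because the elite
#' pool is contained in the mate pool. Offspring values follow the
#' [inherit()] rule, applied per situation and trait.
#'
#' @param pop An `amm_population`.
#' @param fitnesses Lifetime fitnesses aligned with the population rows.
#' @param params An [amm_params()] object.
#' @return The next `amm_population` (generation index incremented).
#' @export
breed_next_generation <- function(pop, fitnesses, params = amm_params()) {
  params <- as_amm_params(params)
  S <- params$pop_size
  n <- params$n_situations
  stopifnot(nrow(pop$G) == length(fitnesses))
  pools <- select_parent_pools(fitnesses, params)
  pa <- pools$elite[sample.int(length(pools$elite), S, replace = TRUE)]
  pb <- pools$mates[sample.int(length(pools$mates), S, replace = TRUE)]

  cap <- params$inherit_cap
  sd <- params$mutation_sd
  pick_G <- matrix(stats::runif(S * n) < 0.5, S, n)
  pick_V <- matrix(stats::runif(S * n) < 0.5, S, n)
  G <- ifelse(pick_G, pop$G[pa, , drop = FALSE], pop$G[pb, , drop = FALSE])
  V <- ifelse(pick_V, pop$V[pa, , drop = FALSE], pop$V[pb, , drop = FALSE])
  G <- pmin(pmax(G, -cap), cap) + matrix(stats::rnorm(S * n, 0, sd), S, n)
  V <- pmin(pmax(V, -cap), cap) + matrix(stats::rnorm(S * n, 0, sd), S, n)

  structure(
    list(G = G, V = V, generation = pop$generation + 1L,
         parent_a = pa, parent_b = pb),
    class = "amm_population"
  )
}

#' Extract one member's heritable profile
#'
#' @param pop An `amm_population`.
#' @param i Row index of the member.
#' @return An [heritable_profile()].
#' @export
population_member <- function(pop, i) {
  heritable_profile(pop$G[i, ], pop$V[i, ])
}

summarise_generation <- function(pop, res, wellbeing_final) {
  tibble::tibble(
    generation = pop$generation,
    mean_fitness = mean(res$fitness),
    min_fitness = min(res$fitness),
    max_fitness = max(res$fitness),
    mean_final_wellbeing = mean(wellbeing_final)
  )
}

situation_summary_tbl <- function(env, pop, res) {
  col_rng <- function(M, f) apply(M, 2L, f)
  tibble::tibble(
    situation = env$situation,
    z = env$z,
    mean_G = colMeans(pop$G), min_G = col_rng(pop$G, min), max_G = col_rng(pop$G, max),
    mean_V = colMeans(pop$V), min_V = col_rng(pop$V, min), max_V = col_rng(pop$V, max),
    mean_eps = colMeans(res$final_eps),
    min_eps = col_rng(res$final_eps, min),
    max_eps = col_rng(res$final_eps, max),
    mean_outcome_frequency = colMeans(res$final_bq),
    mean_first_outcome_frequency = colMeans(res$first_bq)
  )
}

#' Run the evolutionary simulation
#'
#' The generational loop: evaluate every member's lifetime (fresh naive
#' within-lifetime state each generation; only instincts `G` and cue
#' values `V` are transmitted), summarise the generation, select the
#' truncation parent pools, and breed the next generation. Fully
#' reproducible given the RNG state (call `set.seed()` first or pass
#' `seed`).
#'
#' @param params An [amm_params()] object.
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called.
#' @param engine Lifetime engine, `"cpp"` (default) or `"r"`.
#' @param progress If `TRUE`, print a one-line progress note per 10
#'   generations.
#' @return An object of class `amm_evolution`: list with
#'   \describe{
#'     \item{generations}{tibble: `generation`, `mean_fitness`,
#'       `min_fitness`, `max_fitness`, `mean_final_wellbeing`. Generation 1
#'       is the founding (naive) generation.}
#'     \item{situations}{tibble of final-generation per-situation summaries
#'       (population mean/min/max of `G`, `V`, final-period prediction
#'       error, and mean final/first outcome frequency `b*q`).}
#'     \item{final_population}{the evaluated final `amm_population`.}
#'     \item{final}{final-generation matrices: `fitness`, `wellbeing`
#'       (periods x individuals), `final_eps`, `final_bq`, `first_bq`,
#'       `final_omega` (individuals x situations).}
#'     \item{env, params}{inputs used.}
#'   }
#' @examples
#' params <- amm_params(n_situations = 20, n_periods = 50, pop_size = 30,
#'                      n_generations = 5)
#' evo <- run_generations(params, seed = 1)
#' evo$generations
#' @export
run_generations <- function(params = amm_params(), seed = NULL,
                            engine = c("cpp", "r"), progress = FALSE) {
  engine <- match.arg(engine)
  params <- as_amm_params(params)
  if (!is.null(seed)) set.seed(seed)
  env <- situation_grid(params)
  pop <- init_population(params)

  gen_rows <- vector("list", params$n_generations)
  res <- NULL
  for (g in seq_len(params$n_generations)) {
    res <- evaluate_population(pop, env, params, engine)
    wellbeing_final <- res$wellbeing[params$n_periods, ]
    pop$generation <- g
    gen_rows[[g]] <- summarise_generation(pop, res, wellbeing_final)
    if (progress && g %% 10L == 0L) {
      message(sprintf("generation %d: mean fitness %.2f, mean wellbeing %.3f",
                      g, mean(res$fitness), mean(wellbeing_final)))
    }
    if (g < params$n_generations) {
      pop <- breed_next_generation(pop, res$fitness, params)
    }
  }

  structure(
    list(
      generations = dplyr::bind_rows(gen_rows),
      situations = situation_summary_tbl(env, pop, res),
      final_population = pop,
      final = res,
      env = env,
      params = params,
      seed = seed
    ),
    class = "amm_evolution"
  )
}

# Evaluate all members' lifetimes; returns fitness vector plus the
# population matrices needed by the summaries and metrics.
evaluate_population <- function(pop, env, params, engine = "cpp") {
  if (engine == "cpp") {
    res <- cpp_run_lifetimes(pop$G, pop$V, env$z, env$base_frequency,
                             params, FALSE, FALSE)
    return(res)
  }
  S <- nrow(pop$G)
  n <- ncol(pop$G)
  m <- params$n_periods
  fitness <- numeric(S)
  wellbeing <- matrix(0, m, S)
  first_bq <- final_bq <- final_eps <- final_omega <- matrix(0, S, n)
  for (y in seq_len(S)) {
    life <- run_lifetime(population_member(pop, y), env, params,
                         engine = "r", trace = TRUE)
    fitness[y] <- life$fitness
    wellbeing[, y] <- life$wellbeing
    first <- dplyr::filter(life$trace, .data$period == 1L)
    first_bq[y, ] <- first$b * first$q
    final_bq[y, ] <- life$final_record$b * life$final_record$q
    final_eps[y, ] <- life$final_record$eps
    final_omega[y, ] <- life$final_record$omega
  }
  list(fitness = fitness, wellbeing = wellbeing, first_bq = first_bq,
       final_bq = final_bq, final_eps = final_eps, final_omega = final_omega)
}

#' @export
print.amm_evolution <- function(x, ...) {
  g <- x$generations
  cat("<amm_evolution>\n")
  cat(sprintf("  %d generations x %d individuals x %d periods x %d situations\n",
              x$params$n_generations, x$params$pop_size,
              x$params$n_periods, x$params$n_situations))
  cat(sprintf("  mean fitness: %.2f (gen 1) -> %.2f (gen %d)\n",
              g$mean_fitness[1], g$mean_fitness[nrow(g)], nrow(g)))
  cat(sprintf("  mean final-period wellbeing (last generation): %.3f\n",
              g$mean_final_wellbeing[nrow(g)]))
  invisible(x)
}
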