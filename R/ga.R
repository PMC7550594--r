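#' Fitness of a genome: mean fitness over fresh runs
#'
#' Because a single run is stochastic (fresh environment, beliefs, masks and
#' event draws), fitness is estimated as the mean of `F = alpha - kappa`
#' over `runs_per_eval` independent runs. Its Monte-Carlo variance shrinks
#' proportionally to `1/runs_per_eval`.
#'
#' @param genome A `group_genome`.
#' @param run_config A [run_config()].
#' @param runs_per_eval Number of independent runs averaged.
#' @return A single fitness value.
#' @export
evaluate_fitness <- function(genome, run_config, runs_per_eval = 3L) {
  mean(run_batch(genome, run_config, as.integer(runs_per_eval))$fitness)
}

# uniform per-parameter crossover on raw vectors: each position is taken
# from `va` with probability 1/2, else from `vb`
uniform_crossover <- function(va, vb) {
  take_a <- runif(length(va)) < 0.5
  ifelse(take_a, va, vb)
}

#' Genetic operators on group genomes
#'
#' `crossover_genomes()` applies uniform per-parameter crossover on the
#' flattened parameter vectors (each of the `N^2 + 3N` positions is
#' inherited from either parent with probability 1/2) and repairs the
#' child. `mutate_genome()` independently selects each flattened parameter
#' with probability `mut_rate` and perturbs it additively by a uniform draw
#' on `[-mut_amplitude, mut_amplitude]` (no perturbation ever exceeds the
#' amplitude), then repairs.
#'
#' @param parent_a,parent_b `group_genome`s of the same size.
#' @return A valid `group_genome`.
#' @export
crossover_genomes <- function(parent_a, parent_b) {
  if (parent_a$n_agents != parent_b$n_agents) {
    abort("structural error: parents must have the same number of agents")
  }
  child <- uniform_crossover(genome_flatten(parent_a), genome_flatten(parent_b))
  repair_genome(child, parent_a$n_agents)
}

mutate_vector <- function(v, mut_rate, mut_amplitude) {
  sel <- runif(length(v)) < mut_rate
  n_sel <- sum(sel)
  if (n_sel > 0L) {
    v[sel] <- v[sel] + runif(n_sel, -mut_amplitude, mut_amplitude)
  }
  v
}

#' @rdname crossover_genomes
#' @param genome A `group_genome`.
#' @param mut_rate Per-parameter mutation probability.
#' @param mut_amplitude Maximum perturbation magnitude.
#' @export
mutate_genome <- function(genome, mut_rate = 0.01, mut_amplitude = 0.01) {
  v <- mutate_vector(genome_flatten(genome), mut_rate, mut_amplitude)
  repair_genome(v, genome$n_agents)
}

#' Tournament selection of a parent pair
#'
#' Each parent is the fittest of `tournament_size` population members drawn
#' uniformly with replacement; ties are broken uniformly at random.
#' Tournament selection is robust to the noisy fitness values produced by
#' stochastic runs and needs no fitness scaling.
#'
#' @param fitness_values Numeric vector of population fitness values.
#' @param tournament_size Tournament size (>= 2, capped at the population
#'   size).
#' @return An integer vector of two population indices.
#' @export
select_parents <- function(fitness_values, tournament_size = 2L) {
  npop <- length(fitness_values)
  if (npop == 0L) {
    abort("empty population")
  }
  pick_one <- function() {
    cand <- vapply(seq_len(tournament_size), function(...) draw_index(npop), integer(1))
    f <- fitness_values[cand]
    best <- cand[f == max(f)]
    if (length(best) > 1L) best <- best[draw_index(length(best))]
    best
  }
  c(pick_one(), pick_one())
}

#' General-purpose genetic optimizer
#'
#' The evolutionary engine underlying [optimize_group()], usable for any
#' real-parameter maximization. Per generation: every genome without a
#' cached fitness is evaluated, the `n_elites` fittest are carried over
#' unchanged (fitness cached, so the recorded best is non-decreasing), and
#' the rest of the next generation is produced by tournament selection,
#' uniform crossover, mutation, and repair.
#'
#' @param fitness Function mapping a parameter vector to a single (possibly
#'   stochastic) fitness value; maximized.
#' @param n_params Length of the parameter vector.
#' @param config A [ga_config()].
#' @param init Function `(n_params)` returning one raw initial vector;
#'   defaults to uniform draws on `[0, 1]`.
#' @param repair Function projecting a raw vector onto the feasible set;
#'   defaults to clipping to `[0, 1]`.
#' @return A list of class `ga_result`: `par` (the entrywise average of the
#'   final population, repaired), `population` (final-population matrix, one
#'   row per genome), `fitness` (final-population fitness values), and
#'   `history` (tibble with `generation`, `best_fitness`, `mean_fitness`).
#' @export
#' @examples
#' set.seed(1)
#' res <- ga_optimize(
#'   function(v) -(v - 0.7)^2, 1,
#'   ga_config(population_size = 30, gen_no = 50)
#' )
#' res$par
ga_optimize <- function(fitness, n_params,
                        config = ga_config(),
                        init = function(n) runif(n),
                        repair = function(v) pmin(pmax(v, 0), 1)) {
  npop <- config$population_size
  pop <- t(vapply(seq_len(npop), function(...) repair(init(n_params)),
                  numeric(n_params)))
  if (n_params == 1L) pop <- matrix(pop, ncol = 1L)
  fit <- rep(NA_real_, npop)
  history <- tibble(
    generation = seq_len(config$gen_no),
    best_fitness = NA_real_,
    mean_fitness = NA_real_
  )
  for (gen in seq_len(config$gen_no)) {
    need <- which(is.na(fit))
    for (idx in need) {
      fit[idx] <- fitness(pop[idx, ])
    }
    history$best_fitness[gen] <- max(fit)
    history$mean_fitness[gen] <- mean(fit)
    if (gen == config$gen_no) break
    ord <- order(fit, decreasing = TRUE)
    n_off <- npop - config$n_elites
    new_pop <- matrix(NA_real_, npop, n_params)
    new_fit <- rep(NA_real_, npop)
    if (config$n_elites > 0L) {
      keep <- ord[seq_len(config$n_elites)]
      new_pop[seq_len(config$n_elites), ] <- pop[keep, , drop = FALSE]
      new_fit[seq_len(config$n_elites)] <- fit[keep]
    }
    for (o in seq_len(n_off)) {
      parents <- select_parents(fit, config$tournament_size)
      child <- uniform_crossover(pop[parents[1L], ], pop[parents[2L], ])
      child <- mutate_vector(child, config$mut_rate, config$mut_amplitude)
      new_pop[config$n_elites + o, ] <- repair(child)
    }
    pop <- new_pop
    fit <- new_fit
  }
  structure(
    list(
      par = repair(colMeans(pop)),
      population = pop,
      fitness = fit,
      history = history,
      config = config
    ),
    class = "ga_result"
  )
}

#' Average the chromosomes of a final generation
#'
#' Late GA generations are strongly mixed by crossover, so their members are
#' similar; the optimal group is summarized as the entrywise arithmetic mean
#' of the flattened genomes, repaired back onto the constraint set (row
#' sums are preserved by averaging; repair only guards against numerical
#' noise).
#'
#' @param population A non-empty list of `group_genome`s with common size.
#' @return A valid `group_genome`.
#' @export
average_last_generation <- function(population) {
  if (length(population) == 0L) {
    abort("empty population")
  }
  n <- population[[1L]]$n_agents
  flat <- vapply(population, genome_flatten, numeric(n * n + 3L * n))
  repair_genome(rowMeans(flat), n)
}

#' Evolve an optimal group
#'
#' Runs the genetic algorithm over group genomes: the initial population is
#' drawn uniformly at random and repaired; fitness is the mean `F` of
#' `runs_per_eval` fresh runs under `run_config`; variation is tournament
#' selection, uniform crossover and bounded uniform mutation, with every
#' offspring repaired onto the constraint set. The optimal group is the
#' entrywise average of the final generation.
#'
#' @param run_config A [run_config()]; its `fitness_mode` defines what
#'   "optimal" means (accuracy, consensus, or both).
#' @param ga_config A [ga_config()].
#' @param seed Optional integer seed for full reproducibility.
#' @return A list of class `optimization_result`: `optimal_genome`,
#'   `final_population` (list of `group_genome`s), `history` (per-generation
#'   best and mean fitness), `run_config`, `ga_config`.
#' @seealso [tidy.optimization_result()], [glance.optimization_result()],
#'   [autoplot.optimization_result()]
#' @export
#' @examples
#' cfg <- profile_config("desk", fitness_mode = "consensus", access_ratio = 0.2)
#' \donttest{
#' res <- optimize_group(cfg$run, ga_config(population_size = 20, gen_no = 30), seed = 1)
#' glance(res)
#' }
optimize_group <- function(run_config, ga_config = profile_config("desk")$ga,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- run_config$n_agents
  n_params <- n * n + 3L * n
  k <- run_config$env_size
  m <- mask_size(run_config)
  fitness <- function(v) {
    a <- matrix(v[seq_len(n * n)], nrow = n, byrow = TRUE)
    tr <- matrix(v[n * n + seq_len(3L * n)], ncol = 3L, byrow = TRUE)
    raw <- cpp_run_batch(
      a, tr[, 1L], tr[, 2L], tr[, 3L],
      k, m, run_config$n_rounds, ga_config$runs_per_eval
    )
    alpha_acc <- (raw[, 1L] - raw[, 2L]) / raw[, 1L]
    alpha_cons <- (raw[, 3L] - raw[, 4L]) / raw[, 3L]
    kappa <- mean(tr[, 2L]) * run_config$cost_comm +
      mean(tr[, 3L]) * run_config$cost_obs
    mean(run_alpha(alpha_acc, alpha_cons, run_config$fitness_mode)) - kappa
  }
  repair <- function(v) repair_vector(v, n)
  engine <- ga_optimize(fitness, n_params, ga_config, repair = repair)
  final_population <- lapply(seq_len(nrow(engine$population)), function(i) {
    genome_unflatten(engine$population[i, ], n)
  })
  structure(
    list(
      optimal_genome = genome_unflatten(engine$par, n),
      final_population = final_population,
      history = engine$history,
      run_config = run_config,
      ga_config = ga_config,
      seed = seed
    ),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "<optimization_result: mode %s, H = %.2f, %d generations>\n",
    x$run_config$fitness_mode, x$run_config$access_ratio, nrow(x$history)
  ))
  cat(sprintf(
    "  final best fitness %.4f (mean %.4f)\n",
    x$history$best_fitness[nrow(x$history)],
    x$history$mean_fitness[nrow(x$history)]
  ))
  print(x$optimal_genome)
  invisible(x)
}

#' Tidy methods for optimization results
#'
#' `tidy()` returns the per-generation fitness trajectory; `glance()` a
#' one-row summary of the optimum (final fitness, mean traits of the
#' averaged genome, hierarchy of its materialized network).
#'
#' @param x An `optimization_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.optimization_result <- function(x, ...) {
  x$history
}

#' @rdname tidy.optimization_result
#' @export
glance.optimization_result <- function(x, ...) {
  g <- x$optimal_genome
  tibble(
    fitness_mode = x$run_config$fitness_mode,
    access_ratio = x$run_config$access_ratio,
    n_agents = x$run_config$n_agents,
    generations = nrow(x$history),
    best_fitness = x$history$best_fitness[nrow(x$history)],
    mean_fitness = x$history$mean_fitness[nrow(x$history)],
    mean_s = mean(g$traits$s),
    mean_p_comm = mean(g$traits$p_comm),
    mean_p_obs = mean(g$traits$p_obs),
    hierarchy = network_hierarchy(materialize_network(g))
  )
}

#' Plot a fitness trajectory
#'
#' @param object An `optimization_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.optimization_result <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, -"generation",
    names_to = "statistic", values_to = "fitness"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$fitness,
    colour = .data$statistic
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "generation", y = "fitness F",
      title = sprintf(
        "GA trajectory (%s, H = %.2f)",
        object$run_config$fitness_mode, object$run_config$access_ratio
      )
    )
}
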