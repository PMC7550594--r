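#' Run configuration for a group decision-making simulation
#'
#' Bundles the model parameters of a single simulated decision problem: group
#' size, environment complexity, access ratio, number of rounds, activity
#' costs, and the optimality definition used to score a run.
#'
#' @param n_agents Number of agents `N` (integer, at least 2).
#' @param env_size Number of environment facets `K` (positive integer). The
#'   environment is a vector of `K` independent uniform values on `[0, 1]`;
#'   larger `K` means a more complex decision problem.
#' @param access_ratio Access ratio `H` in `[0, 1]`: each agent can observe a
#'   fixed subset of `round(H * K)` environment facets (half-to-even
#'   rounding, as in [round()]).
#' @param n_rounds Number of rounds `R` per run (positive integer); the
#'   "time" the group has to reach its goal.
#' @param cost_comm Cost of communication per unit of mean communication
#'   activity (non-negative).
#' @param cost_obs Cost of observation per unit of mean observation activity
#'   (non-negative). Observation is typically much costlier than
#'   communication.
#' @param fitness_mode One of `"accuracy"` (score the reduction of the group
#'   error), `"consensus"` (score the reduction of disagreement), or
#'   `"both"` (equal-weight mix of the two).
#' @param resample_masks If `TRUE` (default) access masks are drawn afresh at
#'   every run initialization; if `FALSE` a caller may reuse a fixed
#'   [initialize_run()] state across runs.
#'
#' @return A list of class `run_config`.
#' @seealso [profile_config()] for the named reference parameter sets,
#'   [simulate_run()] for what the configuration drives.
#' @export
#' @examples
#' run_config(n_agents = 5, env_size = 5, access_ratio = 0.4)
run_config <- function(n_agents = 10L,
                       env_size = 10L,
                       access_ratio = 0.5,
                       n_rounds = 50L,
                       cost_comm = 0.05,
                       cost_obs = 0.5,
                       fitness_mode = c("accuracy", "consensus", "both"),
                       resample_masks = TRUE) {
  fitness_mode <- match.arg(fitness_mode)
  check_count <- function(x, name, min) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
      abort(sprintf("`%s` must be a single integer >= %d", name, min))
    }
  }
  check_count(n_agents, "n_agents", 2L)
  check_count(env_size, "env_size", 1L)
  check_count(n_rounds, "n_rounds", 1L)
  if (length(access_ratio) != 1L || !is.finite(access_ratio) ||
      access_ratio < 0 || access_ratio > 1) {
    abort("`access_ratio` must be a single value in [0, 1]")
  }
  for (nm in c("cost_comm", "cost_obs")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0) {
      abort(sprintf("`%s` must be a single non-negative value", nm))
    }
  }
  structure(
    list(
      n_agents = as.integer(n_agents),
      env_size = as.integer(env_size),
      access_ratio = as.numeric(access_ratio),
      n_rounds = as.integer(n_rounds),
      cost_comm = as.numeric(cost_comm),
      cost_obs = as.numeric(cost_obs),
      fitness_mode = fitness_mode,
      resample_masks = isTRUE(resample_masks)
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf(
    "  N = %d agents, K = %d facets, H = %.2f, R = %d rounds\n",
    x$n_agents, x$env_size, x$access_ratio, x$n_rounds
  ))
  cat(sprintf(
    "  costs: comm %.3f, obs %.3f; fitness mode: %s\n",
    x$cost_comm, x$cost_obs, x$fitness_mode
  ))
  invisible(x)
}

#' Genetic-algorithm configuration
#'
#' Hyperparameters of the evolutionary optimizer used by [optimize_group()]
#' and [ga_optimize()].
#'
#' @param population_size Number of candidate genomes per generation.
#' @param mut_rate Per-parameter mutation probability in `[0, 1]`.
#' @param mut_amplitude Half-width of the uniform additive perturbation
#'   applied to a mutated parameter (each perturbation magnitude is at most
#'   `mut_amplitude`).
#' @param gen_no Number of generations.
#' @param runs_per_eval Number of independent runs averaged into one fitness
#'   evaluation (fitness is stochastic; averaging reduces its variance).
#' @param tournament_size Tournament size for parent selection (>= 2).
#' @param n_elites Number of fittest genomes copied unchanged (with cached
#'   fitness) into the next generation; must be smaller than
#'   `population_size`.
#'
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 60L,
                      mut_rate = 0.01,
                      mut_amplitude = 0.01,
                      gen_no = 200L,
                      runs_per_eval = 3L,
                      tournament_size = 2L,
                      n_elites = 1L) {
  stopifnot(
    population_size >= 2, population_size == floor(population_size),
    mut_rate >= 0, mut_rate <= 1, mut_amplitude >= 0,
    gen_no >= 1, gen_no == floor(gen_no),
    runs_per_eval >= 1, tournament_size >= 2,
    n_elites >= 0
  )
  if (n_elites >= population_size) {
    abort("`n_elites` must be smaller than `population_size`")
  }
  structure(
    list(
      population_size = as.integer(population_size),
      mut_rate = as.numeric(mut_rate),
      mut_amplitude = as.numeric(mut_amplitude),
      gen_no = as.integer(gen_no),
      runs_per_eval = as.integer(runs_per_eval),
      tournament_size = as.integer(tournament_size),
      n_elites = as.integer(n_elites)
    ),
    class = "ga_config"
  )
}

#' @export
print.ga_config <- function(x, ...) {
  cat("<ga_config>\n")
  cat(sprintf(
    "  pop %d, %d generations, mut rate %.3g, amplitude %.3g\n",
    x$population_size, x$gen_no, x$mut_rate, x$mut_amplitude
  ))
  cat(sprintf(
    "  %d run(s) per evaluation, tournament size %d, %d elite(s)\n",
    x$runs_per_eval, x$tournament_size, x$n_elites
  ))
  invisible(x)
}

#' Named configuration profiles
#'
#' Two reference bundles of run and GA parameters. `"paper"` is the
#' published reference setting (N = 20, K = 20, R = 100, communication cost
#' 0.05, observation cost 0.5; GA with population 1000, 900 generations,
#' mutation rate and amplitude 0.01) -- a supercomputer-scale workload.
#' `"desk"` is a reduced profile (N = 10, K = 10, R = 50, population 60, 200
#' generations) sized for interactive use and the package's test suite.
#'
#' @param name `"paper"` or `"desk"`.
#' @param ... Overrides applied to the run configuration fields (e.g.
#'   `access_ratio = 0.3`, `fitness_mode = "consensus"`).
#'
#' @return A list with elements `run` ([run_config()]) and `ga`
#'   ([ga_config()]).
#' @export
#' @examples
#' profile_config("desk", fitness_mode = "consensus", access_ratio = 0.2)
profile_config <- function(name = c("desk", "paper"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    paper = list(
      run = list(
        n_agents = 20L, env_size = 20L, access_ratio = 0.5, n_rounds = 100L,
        cost_comm = 0.05, cost_obs = 0.5, fitness_mode = "accuracy"
      ),
      ga = list(
        population_size = 1000L, mut_rate = 0.01, mut_amplitude = 0.01,
        gen_no = 900L, runs_per_eval = 3L
      )
    ),
    desk = list(
      run = list(
        n_agents = 10L, env_size = 10L, access_ratio = 0.5, n_rounds = 50L,
        cost_comm = 0.05, cost_obs = 0.5, fitness_mode = "accuracy"
      ),
      ga = list(
        population_size = 60L, mut_rate = 0.01, mut_amplitude = 0.01,
        gen_no = 200L, runs_per_eval = 3L
      )
    )
  )
  overrides <- list(...)
  run_fields <- names(formals(run_config))
  ga_fields <- names(formals(ga_config))
  bad <- setdiff(names(overrides), c(run_fields, ga_fields))
  if (length(bad)) {
    abort(paste0("unknown profile override(s): ", paste(bad, collapse = ", ")))
  }
  run_args <- modifyList(base$run, overrides[intersect(names(overrides), run_fields)])
  ga_args <- modifyList(base$ga, overrides[intersect(names(overrides), ga_fields)])
  list(
    run = do.call(run_config, run_args),
    ga = do.call(ga_config, ga_args)
  )
}
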