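#' Initialize the state of a run
#'
#' Draws a fresh decision problem: the environment vector (`K` uniforms on
#' `[0, 1]`), the agents' initial belief matrix (`N x K` uniforms), and one
#' access mask per agent -- `round(H * K)` environment indices sampled
#' uniformly without replacement, independently across agents. Agents
#' therefore typically see different facets of the same problem.
#'
#' @param config A [run_config()].
#' @return A list of class `run_state` with elements `environment` (length
#'   `K`), `beliefs` (`N x K` matrix) and `access_masks` (`N x K` logical
#'   matrix; each row has exactly `round(H * K)` `TRUE` entries).
#' @export
#' @examples
#' set.seed(1)
#' st <- initialize_run(run_config(n_agents = 3, env_size = 4, access_ratio = 0.5))
#' rowSums(st$access_masks)
initialize_run <- function(config) {
  n <- config$n_agents
  k <- config$env_size
  m <- mask_size(config)
  environment <- runif(k)
  # column-major fill: agent-within-facet draw order, matching the compiled core
  b <- matrix(runif(n * k), nrow = n)
  masks <- matrix(FALSE, n, k)
  for (i in seq_len(n)) {
    masks[i, sample_mask_indices(k, m)] <- TRUE
  }
  structure(
    list(environment = environment, beliefs = b, access_masks = masks),
    class = "run_state"
  )
}

mask_size <- function(config) {
  as.integer(round(config$access_ratio * config$env_size))
}

#' Group error: mean absolute deviation from the environment
#'
#' The group error is the mean over all `N * K` (agent, facet) pairs of the
#' absolute difference between belief and environment value. It is the
#' accuracy counterpart of [disagreement()]: both average over facets and
#' then agents so the two stay on a comparable scale.
#'
#' @param beliefs `N x K` numeric matrix of beliefs.
#' @param environment Length-`K` numeric environment vector.
#' @return A single non-negative number.
#' @export
#' @examples
#' group_error(rbind(c(0.5, 0.7), c(0.1, 0.5)), c(0.5, 0.5))
group_error <- function(beliefs, environment) {
  beliefs <- as.matrix(beliefs)
  if (length(beliefs) == 0L || length(environment) == 0L) {
    abort("structural error: empty beliefs or environment")
  }
  if (ncol(beliefs) != length(environment)) {
    abort("structural error: beliefs and environment disagree on K")
  }
  mean(abs(sweep(beliefs, 2L, environment)))
}

#' Disagreement: mean across-agent spread of beliefs
#'
#' For each environment facet, the population standard deviation (divide by
#' `N`) of the `N` agents' beliefs about that facet; the disagreement is the
#' mean of these `K` values. The population form keeps the measure
#' well-defined and unbiased-by-convention down to `N = 2`, where a `{0, 1}`
#' split gives exactly 0.5.
#'
#' @param beliefs `N x K` numeric matrix, `N >= 2`.
#' @return A single non-negative number.
#' @export
#' @examples
#' disagreement(rbind(c(0, 0), c(1, 1)))
disagreement <- function(beliefs) {
  beliefs <- as.matrix(beliefs)
  if (nrow(beliefs) < 2L) {
    abort("degenerate group: disagreement needs at least 2 agents")
  }
  col_means <- colMeans(beliefs)
  col_sq <- colMeans(beliefs^2)
  mean(sqrt(pmax(col_sq - col_means^2, 0)))
}

#' One communication event
#'
#' Agent `sender` talks to agent `receiver`: one belief facet `k`, chosen
#' uniformly at random, of the receiver assimilates toward the sender's
#' value by the receiver's suggestibility,
#' `b_jk <- b_jk + s_j * (b_ik - b_jk)`. The sender is never modified; with
#' `s_j = 1` the receiver adopts the sender's value exactly, with
#' `s_j = 0` nothing changes.
#'
#' @param beliefs `N x K` belief matrix.
#' @param sender,receiver Agent indices (1-based), must differ.
#' @param suggestibility The receiver's suggestibility in `[0, 1]`.
#' @return The updated belief matrix.
#' @export
communicate <- function(beliefs, sender, receiver, suggestibility) {
  if (sender == receiver) {
    abort("self-communication: sender and receiver must differ")
  }
  k <- draw_index(ncol(beliefs))
  beliefs[receiver, k] <- beliefs[receiver, k] +
    suggestibility * (beliefs[sender, k] - beliefs[receiver, k])
  beliefs
}

#' One observation event
#'
#' The agent looks up one accessible environment facet, chosen uniformly
#' among the facets its access mask allows, and copies the exact value into
#' its belief vector. With an empty mask (no access, `H = 0`) the call is a
#' silent no-op.
#'
#' @param beliefs `N x K` belief matrix.
#' @param agent Agent index (1-based).
#' @param environment Length-`K` environment vector.
#' @param access_mask Logical length-`K` mask (the agent's row of the access
#'   mask matrix).
#' @return The updated belief matrix.
#' @export
observe <- function(beliefs, agent, environment, access_mask) {
  idx <- which(access_mask)
  m <- length(idx)
  if (m == 0L) {
    return(beliefs)
  }
  k <- idx[draw_index(m)]
  beliefs[agent, k] <- environment[k]
  beliefs
}

#' Advance a run state by one round
#'
#' Agents take turns in a fresh uniform random permutation; updates apply
#' immediately, so agents later in the permutation see earlier updates. On
#' its turn, agent `i` first communicates with probability `p_i_comm`
#' (drawing one receiver from row `i` of the communication matrix and
#' applying [communicate()]), then independently observes with probability
#' `p_i_obs` (applying [observe()]). When both events fire, communication
#' precedes observation within the turn.
#'
#' This is the readable reference implementation of the round dynamics; the
#' compiled core used by [simulate_run()] follows the identical
#' random-draw protocol and is tested to be bit-identical to it.
#'
#' @param state A `run_state` from [initialize_run()].
#' @param genome A `group_genome`.
#' @return The updated `run_state`.
#' @export
step_round <- function(state, genome) {
  n <- genome$n_agents
  beliefs <- state$beliefs
  a <- genome$matrix
  s <- genome$traits$s
  p_comm <- genome$traits$p_comm
  p_obs <- genome$traits$p_obs
  perm <- fy_shuffle(n)
  for (i in perm) {
    if (runif(1L) < p_comm[i]) {
      j <- draw_categorical(a[i, ])
      beliefs <- communicate(beliefs, i, j, s[j])
    }
    if (runif(1L) < p_obs[i]) {
      beliefs <- observe(beliefs, i, state$environment, state$access_masks[i, ])
    }
  }
  state$beliefs <- beliefs
  state
}

#' Activity cost of a group
#'
#' The cost term of the fitness: mean communication activity times the unit
#' cost of communication plus mean observation activity times the unit cost
#' of observation. It depends on the agents' willingness to act, not on the
#' events actually realized in a run.
#'
#' @param traits Trait table (data frame with `p_comm` and `p_obs`) or a
#'   `group_genome`.
#' @param config A [run_config()] supplying the unit costs.
#' @return A single non-negative number.
#' @export
#' @examples
#' activity_cost(uniform_genome(4, 1), run_config(n_agents = 4))
activity_cost <- function(traits, config) {
  if (inherits(traits, "group_genome")) {
    traits <- traits$traits
  }
  mean(traits$p_comm) * config$cost_comm + mean(traits$p_obs) * config$cost_obs
}

run_alpha <- function(alpha_acc, alpha_cons, mode) {
  switch(mode,
    accuracy = alpha_acc,
    consensus = alpha_cons,
    both = 0.5 * alpha_acc + 0.5 * alpha_cons,
    abort(sprintf("unknown fitness mode '%s'", mode))
  )
}

# Core batch driver: n_runs fresh runs through the compiled core, returning
# one row per run with errors, disagreements, performance terms and fitness.
run_batch <- function(genome, config, n_runs) {
  if (genome$n_agents != config$n_agents) {
    abort("structural error: genome and config disagree on the number of agents")
  }
  raw <- cpp_run_batch(
    genome$matrix,
    genome$traits$s, genome$traits$p_comm, genome$traits$p_obs,
    config$env_size, mask_size(config), config$n_rounds, as.integer(n_runs)
  )
  gi <- raw[, 1]
  gf <- raw[, 2]
  di <- raw[, 3]
  df <- raw[, 4]
  if (any(gi == 0) || any(di == 0)) {
    abort("degenerate initialization: zero initial error or disagreement")
  }
  alpha_acc <- (gi - gf) / gi
  alpha_cons <- (di - df) / di
  alpha <- run_alpha(alpha_acc, alpha_cons, config$fitness_mode)
  kappa <- activity_cost(genome, config)
  tibble(
    run = seq_len(n_runs),
    error_init = gi, error_final = gf,
    disagreement_init = di, disagreement_final = df,
    alpha_acc = alpha_acc, alpha_cons = alpha_cons, alpha = alpha,
    cost = kappa, fitness = alpha - kappa
  )
}

#' Simulate one run and score it
#'
#' A run draws a fresh environment, beliefs and access masks, advances the
#' group through `R` rounds of stochastic communication and observation, and
#' scores the outcome. The accuracy performance is the fraction of the
#' initial group error corrected during the run,
#' `alpha_acc = (gamma_init - gamma_final) / gamma_init`; the consensus
#' performance is the corresponding fraction of the initial disagreement
#' removed. The overall performance `alpha` follows the configured fitness
#' mode (accuracy, consensus, or their equal-weight mix) and the fitness is
#' `F = alpha - kappa` with `kappa` the [activity_cost()]. `F` always lies
#' in `[-(cost_comm + cost_obs), 1]`.
#'
#' @param genome A `group_genome`.
#' @param config A [run_config()] with matching `n_agents`.
#' @return A list of class `group_run` with fields `error_init`,
#'   `error_final`, `disagreement_init`, `disagreement_final`, `alpha_acc`,
#'   `alpha_cons`, `alpha`, `cost`, `fitness`, and the `fitness_mode` used.
#' @seealso [simulate_runs()] for replicated runs as a tibble.
#' @export
#' @examples
#' set.seed(7)
#' simulate_run(uniform_genome(5), run_config(n_agents = 5, env_size = 5))
simulate_run <- function(genome, config) {
  row <- run_batch(genome, config, 1L)
  out <- as.list(row[1L, setdiff(names(row), "run")])
  out$fitness_mode <- config$fitness_mode
  structure(out, class = "group_run")
}

#' @export
print.group_run <- function(x, ...) {
  cat(sprintf("<group_run: mode %s>\n", x$fitness_mode))
  cat(sprintf(
    "  error %.4f -> %.4f   disagreement %.4f -> %.4f\n",
    x$error_init, x$error_final, x$disagreement_init, x$disagreement_final
  ))
  cat(sprintf(
    "  alpha_acc %.4f  alpha_cons %.4f  alpha %.4f  cost %.4f  fitness %.4f\n",
    x$alpha_acc, x$alpha_cons, x$alpha, x$cost, x$fitness
  ))
  invisible(x)
}

#' @export
tidy.group_run <- function(x, ...) {
  as_tibble(unclass(x)[c(
    "error_init", "error_final", "disagreement_init", "disagreement_final",
    "alpha_acc", "alpha_cons", "alpha", "cost", "fitness"
  )])
}

#' Replicated runs of one genome
#'
#' @param genome A `group_genome`.
#' @param config A [run_config()].
#' @param replicates Number of independent runs.
#' @return A tibble with one row per replicate (columns as in
#'   [simulate_run()], plus `run`).
#' @export
simulate_runs <- function(genome, config, replicates = 10L) {
  run_batch(genome, config, as.integer(replicates))
}
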