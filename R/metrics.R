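#' Materialize the realized communication network
#'
#' The communication matrix `A` holds conditional partner-choice
#' probabilities; the network that actually carries information weights row
#' `i` by agent `i`'s communication activity: `c_ij = p_i_comm * a_ij`. Row
#' `i` of the result sums to exactly `p_i_comm` (the weighted out-degree of
#' an agent is its communication activity).
#'
#' @param genome A `group_genome`, or a communication matrix (then `traits`
#'   must be supplied).
#' @param traits Optional trait table when `genome` is a bare matrix.
#' @return An `N x N` weight matrix with zero diagonal.
#' @export
#' @examples
#' materialize_network(uniform_genome(3, 0.4))
materialize_network <- function(genome, traits = NULL) {
  if (inherits(genome, "group_genome")) {
    a <- genome$matrix
    p_comm <- genome$traits$p_comm
  } else {
    a <- as.matrix(genome)
    if (is.null(traits)) {
      abort("`traits` is required when `genome` is a bare matrix")
    }
    p_comm <- traits$p_comm
  }
  if (nrow(a) != ncol(a) || length(p_comm) != nrow(a)) {
    abort("structural error: matrix and traits disagree on the number of agents")
  }
  a * p_comm
}

#' Cycle-based hierarchy of a directed network
#'
#' Hierarchy is the fraction of directed edges that do not participate in
#' any cycle. Edges are the ordered pairs with weight above `threshold`. An
#' edge `(u, v)` lies on a cycle exactly when `u` and `v` belong to the same
#' strongly connected component, so the measure is computed from the SCC
#' partition rather than by cycle enumeration. A complete digraph scores 0,
#' any DAG scores 1. A graph with no edges above the threshold is fully
#' degenerate and returns 1 by convention (with a warning).
#'
#' @param weights Square numeric weight matrix.
#' @param threshold Edge-existence cutoff on the weights; the default
#'   `1e-3` treats numerically dead links as absent. Report several
#'   thresholds when weights are the output of a truncated optimization
#'   (see [sweep_optimal_groups()]).
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' w <- matrix(1, 3, 3); diag(w) <- 0
#' network_hierarchy(w) # complete graph: 0
network_hierarchy <- function(weights, threshold = 1e-3) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    abort("structural error: weight matrix must be square")
  }
  if (threshold < 0) {
    abort("`threshold` must be non-negative")
  }
  adj <- weights > threshold
  diag(adj) <- FALSE
  n_edges <- sum(adj)
  if (n_edges == 0L) {
    warn("no edges above threshold; hierarchy degenerate, returning 1")
    return(1)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")$membership
  idx <- which(adj, arr.ind = TRUE)
  acyclic <- sum(comp[idx[, 1]] != comp[idx[, 2]])
  acyclic / n_edges
}

#' Weighted degree summary of a communication network
#'
#' Weighted out-degrees (row sums) measure how much an agent participates
#' in circulating information; in-degrees (column sums) how much it
#' receives. The population standard deviation of the out-degrees is the
#' specialization signal: near 0 all agents participate equally, large
#' values mean a minority carries the circulation.
#'
#' @param weights Square numeric weight matrix (typically from
#'   [materialize_network()]).
#' @param threshold Edge cutoff used for the hierarchy value and edge count.
#' @return A list of class `network_summary`: `hierarchy`, `out_degree`,
#'   `in_degree`, `out_degree_sd`, `n_edges`, `threshold`.
#' @export
degree_summary <- function(weights, threshold = 1e-3) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    abort("structural error: weight matrix must be square")
  }
  out_deg <- rowSums(weights)
  structure(
    list(
      hierarchy = network_hierarchy(weights, threshold),
      out_degree = out_deg,
      in_degree = colSums(weights),
      out_degree_sd = pop_sd(out_deg),
      n_edges = sum(weights > threshold & row(weights) != col(weights)),
      threshold = threshold
    ),
    class = "network_summary"
  )
}

pop_sd <- function(x) {
  sqrt(max(mean(x^2) - mean(x)^2, 0))
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    "<network_summary: %d edges > %.3g, hierarchy %.3f, out-degree sd %.3f>\n",
    x$n_edges, x$threshold, x$hierarchy, x$out_degree_sd
  ))
  invisible(x)
}

#' @export
tidy.network_summary <- function(x, ...) {
  tibble(
    agent = seq_along(x$out_degree),
    out_degree = x$out_degree,
    in_degree = x$in_degree
  )
}

#' @export
glance.network_summary <- function(x, ...) {
  tibble(
    hierarchy = x$hierarchy,
    out_degree_sd = x$out_degree_sd,
    n_edges = x$n_edges,
    threshold = x$threshold
  )
}

#' Histogram of weighted degrees
#'
#' @param object A `network_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.network_summary <- function(object, ...) {
  d <- tidyr::pivot_longer(tidy(object), -"agent",
    names_to = "direction", values_to = "degree"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$degree, fill = .data$direction)) +
    ggplot2::geom_histogram(
      position = "identity", alpha = 0.6,
      bins = 20, boundary = 0
    ) +
    ggplot2::labs(x = "weighted degree", y = "agents")
}

#' Per-agent specialization records
#'
#' Exposes the trait triple `(p_comm, p_obs, s)` of every agent together
#' with the across-agent Pearson correlations of observation activity and
#' suggestibility against communication activity -- the signature of
#' "influencers" (agents that are active both in circulating and gathering
#' information, yet less suggestible). A correlation is reported as `NA`
#' when either variable is constant across agents.
#'
#' @param genome A `group_genome`.
#' @return A list of class `specialization`: `agents` (tibble of per-agent
#'   traits and degrees) and `correlations` (tibble with `pair`,
#'   `estimate`).
#' @export
specialization_scatter <- function(genome) {
  agents <- tidy(genome)
  safe_cor <- function(x, y) {
    if (pop_sd(x) == 0 || pop_sd(y) == 0) {
      return(NA_real_)
    }
    cor(x, y)
  }
  structure(
    list(
      agents = agents,
      correlations = tibble(
        pair = c("p_comm~p_obs", "p_comm~s"),
        estimate = c(
          safe_cor(agents$p_comm, agents$p_obs),
          safe_cor(agents$p_comm, agents$s)
        )
      )
    ),
    class = "specialization"
  )
}

#' @export
print.specialization <- function(x, ...) {
  cat(sprintf("<specialization: %d agents>\n", nrow(x$agents)))
  print(x$correlations)
  invisible(x)
}

#' Specialization scatter plot
#'
#' @param object A `specialization`.
#' @param ... Unused.
#' @return A ggplot of observation activity and suggestibility against
#'   communication activity, one dot per agent.
#' @export
autoplot.specialization <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$agents[, c("p_comm", "p_obs", "s")], -"p_comm",
    names_to = "trait", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$p_comm, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~trait) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "communication activity", y = "trait value")
}

#' Full network summary of a genome
#'
#' Convenience wrapper: materializes the network and summarizes it at one
#' threshold.
#'
#' @param genome A `group_genome`.
#' @param threshold Edge cutoff.
#' @return A `network_summary`.
#' @export
network_summary <- function(genome, threshold = 1e-3) {
  degree_summary(materialize_network(genome), threshold)
}
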