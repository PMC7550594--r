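# Shared fixtures and independent oracles, built in code.

# a small genome with explicit traits; matrix defaults to the uniform full graph
make_genome <- function(n, s = 0.5, p_comm = 0.5, p_obs = 0.5, a = NULL) {
  if (is.null(a)) {
    a <- matrix(1 / (n - 1), n, n)
    diag(a) <- 0
  }
  group_genome(a, data.frame(
    s = rep_len(s, n), p_comm = rep_len(p_comm, n), p_obs = rep_len(p_obs, n)
  ))
}

# Hierarchy oracle: enumerate every simple cycle by depth-first search and
# mark its edges; hierarchy = edges on no cycle / total edges. Exponential,
# for small graphs only; independent of the SCC-based implementation.
oracle_hierarchy <- function(adj) {
  n <- nrow(adj)
  in_cycle <- matrix(FALSE, n, n)
  walk <- function(path) {
    u <- path[length(path)]
    for (v in seq_len(n)) {
      if (!adj[u, v]) next
      if (v == path[1L]) {
        from <- path
        to <- c(path[-1L], v)
        for (e in seq_along(from)) in_cycle[from[e], to[e]] <<- TRUE
      } else if (!(v %in% path)) {
        walk(c(path, v))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  total <- sum(adj)
  if (total == 0L) {
    return(1)
  }
  sum(adj & !in_cycle) / total
}

# Exact expected final group error for the 2-agent, K = 1, R = 1 system with
# suggestibility 1, full access, obtained by enumerating every combination
# of (turn order) x (communicate? observe?) per agent. With s = 1 each
# belief is always an exact copy of one of {initial b1, initial b2, env},
# and E|b_init - env| = 1/3 for independent U(0,1) draws while E|env - env|
# is 0, so the expectation is a finite weighted sum.
oracle_two_agent_gamma <- function(p_comm, p_obs) {
  total <- 0
  for (first in 1:2) {
    order <- if (first == 1L) c(1L, 2L) else c(2L, 1L)
    for (c1 in c(TRUE, FALSE)) {
      for (o1 in c(TRUE, FALSE)) {
        for (c2 in c(TRUE, FALSE)) {
          for (o2 in c(TRUE, FALSE)) {
            prob <- 0.5 *
              (if (c1) p_comm else 1 - p_comm) *
              (if (o1) p_obs else 1 - p_obs) *
              (if (c2) p_comm else 1 - p_comm) *
              (if (o2) p_obs else 1 - p_obs)
            state <- c("B1", "B2")
            comm <- c(c1, c2)
            obs <- c(o1, o2)
            for (i in order) {
              other <- 3L - i
              if (comm[i]) state[other] <- state[i]
              if (obs[i]) state[i] <- "E"
            }
            val <- function(sym) if (sym == "E") 0 else 1 / 3
            total <- total + prob * (val(state[1L]) + val(state[2L])) / 2
          }
        }
      }
    }
  }
  total
}

two_agent_genome <- function(p_comm, p_obs, s = 1) {
  make_genome(2L, s = s, p_comm = p_comm, p_obs = p_obs)
}

# random adjacency matrix on n nodes with edge probability p, no self-loops
random_digraph <- function(n, p = 0.4) {
  adj <- matrix(runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  adj
}
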