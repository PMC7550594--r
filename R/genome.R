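#' Construct a group genome
#'
#' A group genome is the full parameter set describing one candidate group:
#' a row-stochastic communication matrix `A` (entry `a_ij` is the probability
#' that agent `i`, when it communicates, addresses agent `j`; zero diagonal,
#' each row sums to 1) and a trait table `B` with one row per agent holding
#' suggestibility `s`, communication activity `p_comm`, and observation
#' activity `p_obs`, all in `[0, 1]`.
#'
#' @param matrix Numeric `N x N` communication matrix.
#' @param traits Data frame with `N` rows and columns `s`, `p_comm`,
#'   `p_obs` (extra columns are dropped; an `agent` column is ignored).
#' @param validate If `TRUE` (default), reject a genome violating any
#'   invariant.
#'
#' @return An object of class `group_genome` with elements `matrix`,
#'   `traits` (a tibble with columns `agent`, `s`, `p_comm`, `p_obs`) and
#'   `n_agents`.
#' @seealso [validate_genome()], [repair_genome()], [random_genome()],
#'   [uniform_genome()]
#' @export
#' @examples
#' g <- uniform_genome(4)
#' g$traits
group_genome <- function(matrix, traits, validate = TRUE) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix) || nrow(matrix) != ncol(matrix)) {
    abort("`matrix` must be a square numeric matrix")
  }
  n <- nrow(matrix)
  traits <- as.data.frame(traits)
  needed <- c("s", "p_comm", "p_obs")
  if (!all(needed %in% names(traits))) {
    abort("`traits` must have columns s, p_comm, p_obs")
  }
  if (nrow(traits) != n) {
    abort(sprintf("`traits` must have %d rows (one per agent), got %d", n, nrow(traits)))
  }
  dimnames(matrix) <- NULL
  genome <- structure(
    list(
      matrix = matrix,
      traits = tibble(
        agent = seq_len(n),
        s = as.numeric(traits$s),
        p_comm = as.numeric(traits$p_comm),
        p_obs = as.numeric(traits$p_obs)
      ),
      n_agents = n
    ),
    class = "group_genome"
  )
  if (validate) {
    problems <- validate_genome(genome, n)
    if (length(problems)) {
      abort(c("invalid group genome", problems))
    }
  }
  genome
}

#' @export
print.group_genome <- function(x, ...) {
  cat(sprintf("<group_genome: %d agents>\n", x$n_agents))
  cat(sprintf(
    "  mean traits: s = %.3f, p_comm = %.3f, p_obs = %.3f\n",
    mean(x$traits$s), mean(x$traits$p_comm), mean(x$traits$p_obs)
  ))
  invisible(x)
}

#' Tidy a group genome into a per-agent tibble
#'
#' @param x A `group_genome`.
#' @param ... Unused.
#' @return A tibble with one row per agent: traits plus the weighted out- and
#'   in-degrees of the materialized communication network.
#' @export
tidy.group_genome <- function(x, ...) {
  w <- materialize_network(x)
  dplyr::mutate(x$traits,
    out_degree = rowSums(w),
    in_degree = colSums(w)
  )
}

row_sum_tol <- 1e-9

#' List invariant violations of a group genome
#'
#' Checks the communication-matrix constraints (zero diagonal, entries in
#' `[0, 1]`, rows summing to 1 within `1e-9`) and the trait bounds. A shape
#' mismatch with `n_agents` is a structural error and is signalled, not
#' listed.
#'
#' @param genome A `group_genome` (or a bare list with `matrix` and `traits`).
#' @param n_agents Expected number of agents.
#' @return A character vector of violations, empty when all invariants hold.
#' @export
#' @examples
#' validate_genome(uniform_genome(3), 3)
validate_genome <- function(genome, n_agents = genome$n_agents) {
  a <- genome$matrix
  tr <- genome$traits
  if (!is.matrix(a) || nrow(a) != n_agents || ncol(a) != n_agents) {
    abort(sprintf(
      "structural error: communication matrix must be %d x %d",
      n_agents, n_agents
    ))
  }
  if (nrow(tr) != n_agents) {
    abort(sprintf("structural error: trait table must have %d rows", n_agents))
  }
  problems <- character(0)
  bad_diag <- which(abs(diag(a)) > 0)
  for (i in bad_diag) {
    problems <- c(problems, sprintf("nonzero diagonal at %d", i))
  }
  oob <- which(a < 0 | a > 1, arr.ind = TRUE)
  for (r in seq_len(nrow(oob))) {
    problems <- c(problems, sprintf(
      "matrix entry out of [0, 1] at (%d, %d)", oob[r, 1], oob[r, 2]
    ))
  }
  rs <- rowSums(a)
  bad_rows <- which(abs(rs - 1) > row_sum_tol)
  for (i in bad_rows) {
    problems <- c(problems, sprintf("row %d sums to %.6g, not 1", i, rs[i]))
  }
  for (col in c("s", "p_comm", "p_obs")) {
    v <- tr[[col]]
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    for (i in bad) {
      problems <- c(problems, sprintf("trait %s out of [0, 1] for agent %d", col, i))
    }
  }
  problems
}

#' Flatten a genome to a parameter vector, and back
#'
#' The genetic operators act on flat numeric vectors of length
#' `N^2 + 3 N`. The layout is fixed and lossless: the communication matrix in
#' row-major order first, then the traits grouped per agent as
#' `(s, p_comm, p_obs)`.
#'
#' @param genome A `group_genome`.
#' @return `genome_flatten()` returns a numeric vector;
#'   `genome_unflatten()` returns a `group_genome` (unvalidated, so that raw
#'   GA offspring can be represented before [repair_genome()]).
#' @export
#' @examples
#' g <- uniform_genome(3)
#' identical(genome_unflatten(genome_flatten(g), 3)$matrix, g$matrix)
genome_flatten <- function(genome) {
  c(
    as.vector(t(genome$matrix)),
    as.vector(t(cbind(genome$traits$s, genome$traits$p_comm, genome$traits$p_obs)))
  )
}

#' @rdname genome_flatten
#' @param params Numeric vector of length `n_agents^2 + 3 * n_agents`.
#' @param n_agents Number of agents `N`.
#' @export
genome_unflatten <- function(params, n_agents) {
  n <- as.integer(n_agents)
  expected <- n * n + 3L * n
  if (length(params) != expected) {
    abort(sprintf(
      "structural error: parameter vector must have length %d for %d agents, got %d",
      expected, n, length(params)
    ))
  }
  a <- matrix(params[seq_len(n * n)], nrow = n, byrow = TRUE)
  tr <- matrix(params[n * n + seq_len(3L * n)], ncol = 3L, byrow = TRUE)
  structure(
    list(
      matrix = a,
      traits = tibble(
        agent = seq_len(n),
        s = tr[, 1], p_comm = tr[, 2], p_obs = tr[, 3]
      ),
      n_agents = n
    ),
    class = "group_genome"
  )
}

#' Project a raw parameter vector onto the genome constraint set
#'
#' Genetic-algorithm offspring can leave the feasible set; this repair
#' projects them back: every entry is clipped to `[0, 1]`, the diagonal of
#' the communication matrix is forced to zero, and each row is rescaled to
#' sum to 1. A row that is entirely zero after clipping (an agent whose
#' outgoing preferences vanished) is replaced by the uniform off-diagonal row
#' `1/(N-1)`, so each row remains a well-defined distribution over partners.
#' The repair is idempotent.
#'
#' @param raw_params Numeric vector of length `N^2 + 3 N`, or a
#'   `group_genome`.
#' @param n_agents Number of agents `N` (inferred when a genome is passed).
#' @return A valid `group_genome`.
#' @export
#' @examples
#' g <- repair_genome(runif(3^2 + 3 * 3), 3)
#' validate_genome(g, 3)
repair_genome <- function(raw_params, n_agents = NULL) {
  if (inherits(raw_params, "group_genome")) {
    n_agents <- raw_params$n_agents
    raw_params <- genome_flatten(raw_params)
  }
  if (is.null(n_agents)) {
    abort("`n_agents` is required when repairing a bare parameter vector")
  }
  genome_unflatten(repair_vector(raw_params, as.integer(n_agents)), n_agents)
}

# vector-level repair used in the GA hot path (no tibble construction)
repair_vector <- function(v, n) {
  if (length(v) != n * n + 3L * n) {
    abort(sprintf(
      "structural error: parameter vector must have length %d for %d agents",
      n * n + 3L * n, n
    ))
  }
  if (!all(is.finite(v))) {
    abort("numeric error: parameter vector contains non-finite values")
  }
  v <- pmin(pmax(v, 0), 1)
  a <- matrix(v[seq_len(n * n)], nrow = n, byrow = TRUE)
  diag(a) <- 0
  rs <- rowSums(a)
  zero <- rs <= 0
  if (any(zero)) {
    a[zero, ] <- 1 / (n - 1)
    diag(a) <- 0
    rs[zero] <- 1
  }
  # leave rows already within tolerance untouched, so repair is idempotent
  rs[abs(rs - 1) <= row_sum_tol] <- 1
  a <- a / rs
  c(as.vector(t(a)), v[n * n + seq_len(3L * n)])
}

#' Canonical genomes
#'
#' `uniform_genome()` builds the fully connected egalitarian group: the
#' communication matrix is uniform off-diagonal (`1/(N-1)`) and every trait
#' equals `trait_value`. `random_genome()` draws every parameter uniformly on
#' `[0, 1]` and repairs the result; this is how the GA seeds its initial
#' population.
#'
#' @param n_agents Number of agents.
#' @param trait_value Common trait value for `uniform_genome()`.
#' @return A valid `group_genome`.
#' @export
uniform_genome <- function(n_agents, trait_value = 0.5) {
  n <- as.integer(n_agents)
  a <- matrix(1 / (n - 1), n, n)
  diag(a) <- 0
  group_genome(a, tibble(
    s = rep(trait_value, n), p_comm = rep(trait_value, n),
    p_obs = rep(trait_value, n)
  ))
}

#' @rdname uniform_genome
#' @export
random_genome <- function(n_agents) {
  n <- as.integer(n_agents)
  repair_genome(runif(n * n + 3L * n), n)
}

#' Read and write genomes as JSON
#'
#' The on-disk format is a JSON object with fields `matrix` (`N` lists of
#' `N` numbers), `traits` (`N` objects with keys `s`, `p_comm`, `p_obs`) and
#' `n_agents`. The round trip is entrywise exact (numbers are written at
#' full precision).
#'
#' @param genome A `group_genome`.
#' @param path File path.
#' @return `write_genome()` returns `path` invisibly; `read_genome()`
#'   returns a validated `group_genome`.
#' @export
write_genome <- function(genome, path) {
  obj <- list(
    n_agents = genome$n_agents,
    matrix = unname(apply(genome$matrix, 1L, as.numeric, simplify = FALSE)),
    traits = purrr::pmap(
      genome$traits[, c("s", "p_comm", "p_obs")],
      function(s, p_comm, p_obs) list(s = s, p_comm = p_comm, p_obs = p_obs)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  group_genome(obj$matrix, as.data.frame(obj$traits))
}

#' Export the materialized network as an edge list
#'
#' Writes the materialized communication network (`c_ij = p_i_comm * a_ij`)
#' as a plain-text edge list `i j weight` (0-based indices, tab-separated),
#' one line per edge with weight above `threshold`, for consumption by
#' external graph tools.
#'
#' @param genome A `group_genome`.
#' @param path File path.
#' @param threshold Minimum weight for an edge to be written.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(genome, path, threshold = 0) {
  w <- materialize_network(genome)
  idx <- which(w > threshold, arr.ind = TRUE)
  lines <- sprintf(
    "%d\t%d\t%.17g",
    idx[, 1] - 1L, idx[, 2] - 1L, w[idx]
  )
  writeLines(lines[order(idx[, 1], idx[, 2])], path)
  invisible(path)
}
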