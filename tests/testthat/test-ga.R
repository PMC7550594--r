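test_that("a frozen genome evaluates to exactly zero fitness", {
  cfg <- run_config(n_agents = 3, env_size = 3, n_rounds = 5)
  g <- make_genome(3, p_comm = 0, p_obs = 0)
  set.seed(1)
  expect_identical(evaluate_fitness(g, cfg, 1), 0)
  set.seed(1)
  expect_identical(evaluate_fitness(g, cfg, 8), 0)
})

test_that("evaluation with one run equals that run's fitness", {
  cfg <- run_config(n_agents = 4, env_size = 4, n_rounds = 10)
  set.seed(2)
  g <- random_genome(4)
  set.seed(5)
  f <- evaluate_fitness(g, cfg, 1)
  set.seed(5)
  expect_identical(f, simulate_run(g, cfg)$fitness)
})

test_that("fitness variance shrinks with the number of runs averaged", {
  cfg <- run_config(n_agents = 3, env_size = 3, n_rounds = 10)
  set.seed(3)
  g <- random_genome(3)
  vars <- sapply(c(1L, 4L, 16L), function(nr) {
    var(replicate(150, evaluate_fitness(g, cfg, nr)))
  })
  expect_true(vars[2] < vars[1])
  expect_true(vars[3] < vars[2])
  # expected ratio 16; allow wide Monte-Carlo slack
  expect_gt(vars[1] / vars[3], 6)
})

test_that("crossover of identical parents is the identity", {
  set.seed(4)
  g <- random_genome(5)
  child <- crossover_genomes(g, g)
  expect_equal(genome_flatten(child), genome_flatten(g))
})

test_that("each child position is inherited from exactly one parent", {
  set.seed(6)
  pa <- random_genome(4)
  pb <- random_genome(4)
  child <- crossover_genomes(pa, pb)
  # trait positions are untouched by repair, so inheritance is exact there
  for (col in c("s", "p_comm", "p_obs")) {
    expect_true(all(
      child$traits[[col]] == pa$traits[[col]] |
        child$traits[[col]] == pb$traits[[col]]
    ))
  }
  expect_error(crossover_genomes(pa, random_genome(5)), "structural")
})

test_that("crossover picks each parent with probability one half per position", {
  set.seed(7)
  va <- rep(0, 50)
  vb <- rep(1, 50)
  from_a <- rowMeans(replicate(10000, groupmind:::uniform_crossover(va, vb) == 0))
  expect_true(all(abs(from_a - 0.5) < 0.02))
})

test_that("mutation respects rate and amplitude", {
  set.seed(8)
  g <- uniform_genome(4)
  expect_equal(
    genome_flatten(mutate_genome(g, mut_rate = 0, mut_amplitude = 0.01)),
    genome_flatten(g)
  )

  v <- rep(0.5, 460) # the flat length of a 20-agent genome
  counts <- replicate(10000, sum(groupmind:::mutate_vector(v, 0.01, 0.01) != v))
  expect_equal(mean(counts), 4.6, tolerance = 0.1 / 4.6)

  deltas <- replicate(200, max(abs(groupmind:::mutate_vector(v, 0.5, 0.01) - v)))
  expect_true(all(deltas <= 0.01))
})

test_that("tournament selection follows the rank-based closed form", {
  expect_identical(select_parents(c(0.4), 2), c(1L, 1L))

  set.seed(9)
  fit <- runif(5)
  # a tournament much larger than the population almost surely sees the best
  for (rep in 1:20) {
    expect_identical(fit[select_parents(fit, 50)], rep(max(fit), 2))
  }
  fit <- runif(10)

  # size-2 tournament: P(select rank r of n) = (2r - 1) / n^2
  n <- 10L
  best <- which.max(fit)
  hits <- 0L
  draws <- 10000L
  for (rep in seq_len(draws / 2)) {
    hits <- hits + sum(select_parents(fit, 2) == best)
  }
  expect_equal(hits / draws, (2 * n - 1) / n^2, tolerance = 0.02 / 0.19)
})

test_that("with constant fitness and no mutation, alleles only recombine", {
  set.seed(10)
  res <- ga_optimize(
    function(v) 0, 6,
    ga_config(population_size = 20, gen_no = 30, mut_rate = 0, n_elites = 1)
  )
  # neutral drift: every surviving value at a position existed at that
  # position initially is not directly observable here, but the population
  # must remain inside [0, 1] and its grand mean must not drift far
  expect_true(all(res$population >= 0 & res$population <= 1))
  expect_lt(abs(mean(res$population) - 0.5), 0.25)
})

test_that("elitism makes the recorded best fitness non-decreasing", {
  cfg <- run_config(n_agents = 4, env_size = 4, n_rounds = 10, fitness_mode = "both")
  res <- optimize_group(
    cfg, ga_config(population_size = 12, gen_no = 25, n_elites = 1),
    seed = 11
  )
  expect_true(all(diff(res$history$best_fitness) >= 0))
})

test_that("the engine solves a one-parameter quadratic within 50 generations", {
  set.seed(12)
  res <- ga_optimize(
    function(v) -(v - 0.7)^2, 1,
    ga_config(population_size = 30, gen_no = 50, mut_rate = 0.2, mut_amplitude = 0.05)
  )
  expect_equal(unname(res$par), 0.7, tolerance = 0.02 / 0.7)
})

test_that("averaging the last generation preserves validity and fixed points", {
  set.seed(13)
  g <- random_genome(4)
  expect_equal(
    genome_flatten(average_last_generation(list(g, g, g))),
    genome_flatten(g)
  )

  a1 <- rbind(c(0, 1, 0), c(1, 0, 0), c(0.5, 0.5, 0))
  a2 <- rbind(c(0, 0, 1), c(1, 0, 0), c(0.5, 0.5, 0))
  g1 <- make_genome(3, a = a1)
  g2 <- make_genome(3, a = a2)
  avg <- average_last_generation(list(g1, g2))
  expect_equal(avg$matrix[1, ], c(0, 0.5, 0.5))
  expect_identical(validate_genome(avg, 3), character(0))

  pop <- lapply(1:6, function(i) random_genome(5))
  expect_identical(validate_genome(average_last_generation(pop), 5), character(0))
  expect_error(average_last_generation(list()), "empty")
})

test_that("optimization is reproducible and keeps every genome valid", {
  cfg <- run_config(n_agents = 4, env_size = 3, n_rounds = 8)
  ga <- ga_config(population_size = 10, gen_no = 6)
  a <- optimize_group(cfg, ga, seed = 14)
  b <- optimize_group(cfg, ga, seed = 14)
  expect_identical(
    genome_flatten(a$optimal_genome),
    genome_flatten(b$optimal_genome)
  )
  expect_identical(a$history, b$history)
  for (g in a$final_population) {
    expect_identical(validate_genome(g, 4), character(0))
  }
  expect_identical(validate_genome(a$optimal_genome, 4), character(0))
})

test_that("tidy and glance expose the trajectory and the optimum", {
  cfg <- run_config(n_agents = 3, env_size = 3, n_rounds = 5)
  res <- optimize_group(cfg, ga_config(population_size = 8, gen_no = 4), seed = 15)
  td <- tidy(res)
  expect_identical(nrow(td), 4L)
  expect_true(all(is.finite(td$best_fitness)))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("mean_p_comm", "hierarchy", "best_fitness") %in% names(gl)))
})
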