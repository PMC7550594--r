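test_that("group error is the mean absolute belief-environment deviation", {
  env <- c(0.5, 0.5)
  beliefs <- rbind(c(0.5, 0.7), c(0.1, 0.5))
  expect_equal(group_error(beliefs, env), 0.15)
  expect_equal(group_error(rbind(env, env), env), 0)
  expect_equal(group_error(matrix(0, 3, 2), c(1, 1)), 1)
  expect_error(group_error(matrix(0, 0, 0), numeric(0)), "structural")
  expect_error(group_error(matrix(0, 2, 3), c(1, 1)), "structural")
})

test_that("disagreement is the mean per-facet population standard deviation", {
  expect_equal(disagreement(rbind(c(0.3, 0.9), c(0.3, 0.9))), 0)
  expect_equal(disagreement(rbind(c(0, 0), c(1, 1))), 0.5)
  expect_equal(disagreement(cbind(c(0, 0.5, 1))), sqrt(1 / 6))
  expect_error(disagreement(matrix(0.5, 1, 4)), "degenerate")
})

test_that("communication interpolates one facet of the receiver only", {
  beliefs <- rbind(0.6, 0.2) # K = 1, so the chosen facet is deterministic
  set.seed(1)
  expect_equal(communicate(beliefs, 1, 2, 1)[2, 1], 0.6)
  expect_equal(communicate(beliefs, 1, 2, 0)[2, 1], 0.2)
  expect_equal(communicate(beliefs, 1, 2, 0.5)[2, 1], 0.4)
  expect_equal(communicate(beliefs, 1, 2, 0.5)[1, 1], 0.6) # sender untouched
  expect_error(communicate(beliefs, 2, 2, 0.5), "self-communication")

  # with K > 1 exactly one facet changes
  b <- matrix(runif(10), 2, 5)
  out <- communicate(b, 1, 2, 0.7)
  expect_identical(out[1, ], b[1, ])
  expect_equal(sum(out[2, ] != b[2, ]), 1L)
})

test_that("observation copies one accessible facet exactly; empty mask is a no-op", {
  env <- c(0.1, 0.81, 0.3)
  b <- matrix(0.5, 2, 3)
  out <- observe(b, 1, env, c(FALSE, TRUE, FALSE))
  expect_equal(out[1, 2], 0.81)
  expect_identical(out[2, ], b[2, ])
  expect_identical(observe(b, 1, env, rep(FALSE, 3)), b)
})

test_that("an observation never increases the group error", {
  set.seed(21)
  for (rep in 1:50) {
    env <- runif(4)
    b <- matrix(runif(12), 3, 4)
    mask <- runif(4) < 0.5
    out <- observe(b, sample(3, 1), env, mask)
    expect_lte(group_error(out, env), group_error(b, env))
  }
})

test_that("a round with zero activities leaves the state untouched", {
  cfg <- run_config(n_agents = 4, env_size = 5)
  g <- make_genome(4, p_comm = 0, p_obs = 0)
  set.seed(2)
  st <- initialize_run(cfg)
  st2 <- step_round(st, g)
  expect_identical(st2$beliefs, st$beliefs)
})

test_that("mutual full communication with s = 1 and K = 1 reaches consensus in one round", {
  cfg <- run_config(n_agents = 2, env_size = 1)
  g <- make_genome(2, s = 1, p_comm = 1, p_obs = 0)
  set.seed(33)
  for (rep in 1:20) {
    st <- initialize_run(cfg)
    st <- step_round(st, g)
    expect_equal(disagreement(st$beliefs), 0)
  }
})

test_that("per-round event frequency matches the communication activity", {
  # only agent 1 can act, with p_comm = 0.3; a fired event always changes
  # agent 2's row (s = 1, fresh almost-surely-distinct beliefs each round)
  cfg <- run_config(n_agents = 2, env_size = 2, access_ratio = 0)
  g <- make_genome(2, s = 1, p_comm = c(0.3, 0), p_obs = 0)
  set.seed(9)
  fired <- 0L
  n_rounds <- 10000L
  for (r in seq_len(n_rounds)) {
    st <- initialize_run(cfg)
    st2 <- step_round(st, g)
    if (any(st2$beliefs[2, ] != st$beliefs[2, ])) fired <- fired + 1L
  }
  expect_equal(fired / n_rounds, 0.3, tolerance = 0.015 / 0.3)
})

test_that("beliefs stay inside [0, 1] through long runs", {
  set.seed(14)
  cfg <- run_config(n_agents = 5, env_size = 4, access_ratio = 0.5, n_rounds = 200)
  g <- random_genome(5)
  st <- initialize_run(cfg)
  for (r in 1:200) st <- step_round(st, g)
  expect_true(all(st$beliefs >= 0 & st$beliefs <= 1))
})

test_that("the pure-R round dynamics and the compiled core are draw-for-draw identical", {
  for (case in list(
    list(n = 4L, k = 6L, H = 0.5, R = 25L),
    list(n = 3L, k = 1L, H = 1.0, R = 10L),
    list(n = 6L, k = 8L, H = 0.0, R = 15L)
  )) {
    cfg <- run_config(
      n_agents = case$n, env_size = case$k,
      access_ratio = case$H, n_rounds = case$R
    )
    set.seed(77)
    g <- random_genome(case$n)
    seed <- 1000 + case$n
    set.seed(seed)
    st <- initialize_run(cfg)
    gi <- group_error(st$beliefs, st$environment)
    di <- disagreement(st$beliefs)
    for (r in seq_len(case$R)) st <- step_round(st, g)
    gf <- group_error(st$beliefs, st$environment)
    df <- disagreement(st$beliefs)

    set.seed(seed)
    res <- simulate_run(g, cfg)
    expect_equal(res$error_init, gi, tolerance = 1e-12)
    expect_equal(res$error_final, gf, tolerance = 1e-12)
    expect_equal(res$disagreement_init, di, tolerance = 1e-12)
    expect_equal(res$disagreement_final, df, tolerance = 1e-12)
  }
})

test_that("frozen groups score zero performance, zero cost, zero fitness", {
  cfg <- run_config(n_agents = 4, env_size = 3, fitness_mode = "both")
  g <- make_genome(4, p_comm = 0, p_obs = 0)
  set.seed(4)
  res <- simulate_run(g, cfg)
  expect_identical(res$error_final, res$error_init)
  expect_identical(res$disagreement_final, res$disagreement_init)
  expect_identical(res$alpha, 0)
  expect_identical(res$cost, 0)
  expect_identical(res$fitness, 0)
})

test_that("full observation of a single facet solves the problem in one round", {
  # every agent copies the one environment value: perfect accuracy and
  # consensus, fitness 1 minus the observation cost
  cfg <- run_config(
    n_agents = 5, env_size = 1, access_ratio = 1, n_rounds = 1,
    cost_comm = 0.05, cost_obs = 0.5, fitness_mode = "accuracy"
  )
  g <- make_genome(5, p_comm = 0, p_obs = 1)
  set.seed(8)
  res <- simulate_run(g, cfg)
  expect_equal(res$error_final, 0)
  expect_equal(res$disagreement_final, 0)
  expect_equal(res$alpha_acc, 1)
  expect_equal(res$alpha_cons, 1)
  expect_equal(res$cost, 0.5)
  expect_equal(res$fitness, 0.5)
})

test_that("activity cost follows willingness, not realized events", {
  cfg <- run_config(n_agents = 4, cost_comm = 0.05, cost_obs = 0.5)
  expect_equal(activity_cost(make_genome(4, p_comm = 1, p_obs = 1), cfg), 0.55)
  expect_equal(activity_cost(make_genome(4, p_comm = 0, p_obs = 0), cfg), 0)
  expect_equal(activity_cost(make_genome(4, p_comm = 0.5, p_obs = 0), cfg), 0.025)
})

test_that("performance terms are capped at 1 and fitness stays in its interval", {
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    cfg <- run_config(
      n_agents = n, env_size = sample(1:6, 1),
      access_ratio = runif(1), n_rounds = sample(1:30, 1),
      fitness_mode = sample(c("accuracy", "consensus", "both"), 1)
    )
    res <- simulate_run(random_genome(n), cfg)
    expect_lte(res$alpha_acc, 1)
    expect_lte(res$alpha_cons, 1)
    expect_lte(res$fitness, 1)
    expect_equal(res$fitness, res$alpha - res$cost)
    expect_gte(res$cost, 0)
    expect_lte(res$cost, cfg$cost_comm + cfg$cost_obs)
    # the printed fitness interval assumes a non-decaying performance
    # (alpha >= 0), which holds in practice but is not an algebraic guarantee
    if (res$alpha >= 0) {
      expect_gte(res$fitness, -(cfg$cost_comm + cfg$cost_obs))
    }
  }
})

test_that("identical seeds give bit-identical run results", {
  cfg <- run_config(n_agents = 5, env_size = 5, n_rounds = 40)
  set.seed(6)
  g <- random_genome(5)
  set.seed(123)
  a <- simulate_run(g, cfg)
  set.seed(123)
  b <- simulate_run(g, cfg)
  expect_identical(a, b)
})

test_that("forced consensus gives zero disagreement and full consensus performance", {
  cfg <- run_config(n_agents = 5, env_size = 5)
  set.seed(10)
  st <- initialize_run(cfg)
  d_init <- disagreement(st$beliefs)
  forced <- st$beliefs[rep(1L, 5L), ]
  d_final <- disagreement(forced)
  expect_identical(d_final, 0)
  expect_identical((d_init - d_final) / d_init, 1)
})

test_that("simulate_runs returns one tidy row per replicate", {
  cfg <- run_config(n_agents = 3, env_size = 3, n_rounds = 5)
  set.seed(2)
  runs <- simulate_runs(make_genome(3), cfg, replicates = 7)
  expect_s3_class(runs, "tbl_df")
  expect_identical(nrow(runs), 7L)
  expect_true(all(c("alpha_acc", "alpha_cons", "fitness") %in% names(runs)))
})
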