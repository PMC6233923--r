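test_that("table growth without simplification matches the exact counts", {
  sim <- simulate_wf(N = 10, T = 5, simplify_interval = Inf,
                     final_simplify = FALSE, seed = 1)
  expect_equal(num_nodes(sim$tables), 60L)   # N founders + N per generation
  expect_equal(num_edges(sim$tables), 100L)  # 2NT
  expect_equal(sim$samples, 50:59)
  # final generation at time 0, founders at time T
  expect_equal(sim$tables$node_time[sim$samples + 1L], rep(0, 10))
  expect_equal(sim$tables$node_time[1:10], rep(5, 10))
  sort_tables(sim$tables)
  expect_true(validate_tables(sim$tables)$ok)
})

test_that("degenerate simulations collapse correctly", {
  s0 <- simulate_wf(N = 4, T = 0, seed = 2)
  expect_equal(num_nodes(s0$tables), 4L)
  expect_equal(num_edges(s0$tables), 0L)
  expect_true(all(s0$tables$node_is_sample))

  s1 <- simulate_wf(N = 1, T = 10, seed = 2)    # all history is unary
  expect_equal(num_nodes(s1$tables), 1L)
  expect_equal(num_edges(s1$tables), 0L)
})

test_that("record_birth alternates parents across breakpoints", {
  tc <- table_collection(1)
  a <- add_node(tc, 1)
  b <- add_node(tc, 1)
  u <- record_birth(tc, 0, a, b, breakpoints = 0.4)
  ed <- edges(tc)
  expect_equal(nrow(ed), 2L)
  expect_equal(ed$parent, c(a, b))

  u2 <- record_birth(tc, 0, a, b, breakpoints = numeric(0))
  ed2 <- edges(tc)[edges(tc)$child == u2, ]
  expect_equal(nrow(ed2), 1L)
  expect_equal(ed2$parent, a)
  expect_equal(c(ed2$left, ed2$right), c(0, 1))

  u3 <- record_birth(tc, 0, a, b, breakpoints = c(0.2, 0.7))
  ed3 <- edges(tc)[edges(tc)$child == u3, ]
  expect_equal(ed3$parent, c(a, b, a))
  # segments tile [0, L)
  expect_equal(ed3$left, c(0, 0.2, 0.7))
  expect_equal(ed3$right, c(0.2, 0.7, 1))

  expect_error(record_birth(tc, 0, a, b, breakpoints = c(0.7, 0.2)),
               "increasing")
  expect_error(record_birth(tc, 0, a, b, breakpoints = 1.5), "increasing")
})

test_that("final tables are independent of the simplification interval", {
  for (spec in list(c(12, 30), c(7, 18))) {
    N <- spec[1]; T <- spec[2]
    runs <- lapply(c(1, 5, T), function(s) {
      simulate_wf(N = N, T = T, simplify_interval = s, seed = 4242)
    })
    expect_true(tables_equal(runs[[1]]$tables, runs[[2]]$tables))
    expect_true(tables_equal(runs[[1]]$tables, runs[[3]]$tables))
  }
  # with forwards mutations too
  m1 <- simulate_wf(N = 8, T = 20, simplify_interval = 1,
                    forward_mutation_rate = 0.5, seed = 77)
  m2 <- simulate_wf(N = 8, T = 20, simplify_interval = 20,
                    forward_mutation_rate = 0.5, seed = 77)
  expect_true(tables_equal(m1$tables, m2$tables))
})

test_that("checkpoints relabel the population and are idempotent", {
  sim <- simulate_wf(N = 6, T = 12, simplify_interval = Inf,
                     final_simplify = FALSE, seed = 11)
  tc <- copy_tables(sim$tables)
  sort_tables(tc)
  ck <- simplify_checkpoint(tc, sim$samples)
  expect_equal(ck$samples, 0:5)
  expect_equal(sample_ids(ck$tables), 0:5)
  # a second checkpoint with no intervening births is a no-op
  ck2 <- simplify_checkpoint(ck$tables, ck$samples)
  expect_true(tables_equal(ck2$tables, ck$tables))
})

test_that("periodic simplification keeps the resident tables small", {
  sim <- simulate_wf(N = 100, T = 1000, simplify_interval = 10, seed = 3)
  expect_lt(sim$max_edge_rows, 2 * 100 * 1000 / 10)
  expect_true(validate_tables(sim$tables)$ok)
  expect_true(check_fully_coalesced(tree_sequence(sim$tables)))
})

test_that("a simulation seeded with prior history coalesces inside it", {
  # prior: two samples coalescing at time 5
  prior <- table_collection(1)
  add_node(prior, 0, is_sample = TRUE)
  add_node(prior, 0, is_sample = TRUE)
  r <- add_node(prior, 5)
  add_edge(prior, 0, 1, r, 0)
  add_edge(prior, 0, 1, r, 1)
  init <- initialize_from(prior, samples = c(0L, 1L))

  T <- 2L
  deep <- 0L
  reps <- 400L
  for (i in seq_len(reps)) {
    sim <- simulate_wf(N = 2, T = T, simplify_interval = Inf, init = init,
                       seed = 9000 + i)
    ts <- tree_sequence(sim$tables)
    expect_true(check_fully_coalesced(ts))   # the prior guarantees one root
    tree <- tree_at(ts, 0.5)
    root <- 0L + 1L
    while (!is.na(tree$parent[root])) root <- tree$parent[root] + 1L
    age <- ts$node_time[root]
    if (age > T) {
      deep <- deep + 1L
      expect_equal(age, T + 5)               # the prior's root, shifted
    }
  }
  # at one fixed position the two lineages fail to coalesce within T
  # generations with probability (1 - 1/N)^T = 1/4
  p_hat <- deep / reps
  se <- sqrt(0.25 * 0.75 / reps)
  expect_lt(abs(p_hat - 0.25), 3 * se)

  expect_error(simulate_wf(N = 3, T = 2, init = init, seed = 1), "samples")
  # a trivial prior of N contemporary nodes reproduces a plain run
  triv <- table_collection(1)
  for (i in 1:5) add_node(triv, 0, is_sample = TRUE)
  a <- simulate_wf(N = 5, T = 15, init = initialize_from(triv, 0:4),
                   seed = 321)
  b <- simulate_wf(N = 5, T = 15, seed = 321)
  expect_true(tables_equal(a$tables, b$tables))
})

test_that("poisson crossover mode records a variable number of segments", {
  sim <- simulate_wf(N = 10, T = 30, crossovers = "poisson",
                     crossover_rate = 2, simplify_interval = Inf,
                     final_simplify = FALSE, seed = 55)
  expect_gt(num_edges(sim$tables), 2 * 10 * 30 * 0.8)  # ~3 segments per birth
  sort_tables(sim$tables)
  expect_true(validate_tables(sim$tables)$ok)

  clonal <- simulate_wf(N = 6, T = 25, crossovers = "poisson",
                        crossover_rate = 0, seed = 56)
  expect_true(validate_tables(clonal$tables)$ok)
  expect_true(check_fully_coalesced(tree_sequence(clonal$tables)))
})

test_that("forwards-recorded mutations survive simplification on retained material", {
  sim <- simulate_wf(N = 10, T = 80, simplify_interval = 10,
                     forward_mutation_rate = 0.2, seed = 66)
  tc <- sim$tables
  expect_gt(num_mutations(tc), 0L)
  expect_true(validate_tables(tc)$ok)
  ts <- tree_sequence(tc)
  pos <- ts$site_position[ts$mut_site + 1L]
  for (i in seq_along(ts$mut_site)) {
    covering <- which(ts$edge_child == ts$mut_node[i] &
                        ts$edge_left <= pos[i] & pos[i] < ts$edge_right)
    if (length(covering) == 0L) {
      # a forwards mutation that arose above the local MRCA: retained as a
      # fixed difference, so its node must be the root at that position
      tree <- tree_at(ts, pos[i])
      expect_true(is.na(tree$parent[ts$mut_node[i] + 1L]))
      v <- variants(ts)[[ts$mut_site[i] + 1L]]
      expect_length(unique(v$states), 1L)
    } else {
      expect_length(covering, 1L)
    }
  }
})

test_that("mean pairwise coalescence time is N generations", {
  # E[pair TMRCA] in a haploid Wright-Fisher population is exactly N (a
  # geometric waiting time with success probability 1/N); estimated on a
  # grid of positions per replicate
  N <- 50
  reps <- 200
  est <- vapply(seq_len(reps), function(i) {
    sim <- simulate_wf(N = N, T = 20 * N, simplify_interval = 10,
                       seed = 20000 + i)
    ts <- tree_sequence(sim$tables)
    mean(vapply(seq(0.025, 0.975, by = 0.05), function(x) {
      tree <- tree_at(ts, x)
      pair_tmrca_mean(tree, ts)
    }, 0))
  }, 0)
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - N), 3 * se)
})
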