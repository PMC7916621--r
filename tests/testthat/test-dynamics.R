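test_that("one synchronous step from the KRAS-only state activates the derived set", {
  net <- build_cfl1_model()
  s0 <- canonical_initial_state(net)
  expect_identical(sum(s0[biological <- build_cfl1_model()$nodes]), 1L)
  expect_identical(s0[["KRAS"]], 1L)
  s1 <- next_state(net, s0)
  active <- names(s1)[s1 == 1L & names(s1) %in% biological]
  expect_setequal(active, c("KRAS", "PI3K", "TCF7L2", "RHOA", "CDH1",
                            "GSK3B", "RB", "E2F", "Pro-apoptotic proteins"))
})

test_that("KRAS is restored by its constant rule from any state", {
  net <- build_cfl1_model()
  x <- expand_delays(net)
  set.seed(5)
  for (i in 1:10) {
    s <- stats::setNames(sample(0:1, length(x$nodes), TRUE), x$nodes)
    s["KRAS"] <- 0L
    expect_identical(next_state(x, s)[["KRAS"]], 1L)
  }
})

test_that("the canonical trajectory reaches the cancer fixed point", {
  traj <- simulate_network(build_cfl1_model())
  expect_true(traj$resolved)
  expect_identical(traj$cycle_length, 1L)
  final <- traj$states[nrow(traj$states), ]
  expect_true(all(final[cancer_attractor_active] == 1L))
  expect_true(all(final[cancer_attractor_inactive] == 0L))
  # the fixed point maps to itself
  expect_identical(next_state(build_cfl1_model(), final), final)
})

test_that("trajectory landmarks match the transition to cancer", {
  traj <- simulate_network(build_cfl1_model())
  expect_identical(first_activation(traj, "KRAS"), 0L)
  expect_identical(first_activation(traj, "STAT3"), 8L)
  expect_identical(first_activation(traj, "CYCS"), 9L)
  expect_identical(first_activation(traj, "CCND1"), 12L)
  # CYCS is transient: active only at step 9; caspases never fire
  cycs <- unname(which(traj$states[, "CYCS"] == 1L)) - 1L
  expect_identical(cycs, 9L)
  expect_true(all(traj$states[, "Caspases"] == 0L))
  expect_error(first_activation(traj, "NOPE"), "unknown node")
})

test_that("simulation handles fixed points, cycles and unresolved bounds", {
  t1 <- simulate_network(toy_identity(), c(A = 1L), max_steps = 1)
  expect_true(t1$resolved)
  expect_identical(t1$cycle_length, 1L)

  # 2-node oscillator from (0,0): all four states form one cycle
  t2 <- simulate_network(toy_oscillator(), c(A = 0L, B = 0L))
  expect_identical(t2$cycle_length, 4L)
  expect_identical(t2$transient, 0L)

  t3 <- simulate_network(toy_oscillator(), c(A = 0L, B = 0L), max_steps = 2)
  expect_false(t3$resolved)
  expect_identical(t3$cycle_length, NA_integer_)
})

test_that("exact fixed-point enumeration agrees with brute force", {
  net <- build_cfl1_model()
  fp <- fixed_points(net)
  expect_length(fp$attractors, 1L)
  st <- fp$attractors[[1]]$states[1, ]
  expect_identical(unname(st["KRAS"]), 1L)
  expect_true(all(st[cancer_attractor_active] == 1L))

  expect_length(fixed_points(toy_negation())$attractors, 0L)

  for (s in 1:25) {
    net <- random_network(12, k = 3, delay_prob = 0, seed = s)
    fp <- fixed_points(net)
    bf <- brute_force_attractors(net)
    bf_fp <- Filter(function(a) a$length == 1L, bf$attractors)
    expect_setequal(names(fp$attractors),
                    vapply(bf_fp, `[[`, "", "key"))
  }
})

test_that("sampled attractor search is deterministic given the seed", {
  net <- build_cfl1_model()
  a1 <- find_attractors(net, n_starts = 2000, seed = 99)
  a2 <- find_attractors(net, n_starts = 2000, seed = 99)
  expect_identical(write_attractor_set_json(a1), write_attractor_set_json(a2))
  a3 <- find_attractors(net, n_starts = 2000, seed = 100)
  expect_identical(aset_keys(a1), aset_keys(a3))  # same attractors found
})

test_that("wild-type sampling finds the caspase-inactive cancer attractor", {
  aset <- find_attractors(build_cfl1_model(), n_starts = 20000, seed = 3)
  expect_identical(aset$n_unresolved, 0L)
  caspase_off <- vapply(aset$attractors, function(a) {
    all(a$states[, "Caspases"] == 0L)
  }, TRUE)
  expect_true(any(caspase_off))
  basins <- vapply(aset$attractors, `[[`, 0L, "basin")
  expect_identical(sum(basins), 20000L)
})

test_that("every reported attractor cycle is closed under the update", {
  for (s in 1:10) {
    net <- random_network(9, k = 3, delay_prob = 0.2, seed = s + 500)
    aset <- find_attractors(net, n_starts = 3000, seed = s)
    for (a in aset$attractors) {
      for (i in seq_len(a$length)) {
        nxt <- next_state(net, a$states[i, ])
        expect_identical(unname(nxt),
                         unname(a$states[(i %% a$length) + 1L, ]))
      }
    }
  }
})

test_that("basin fractions sum to one and respect symmetry", {
  fr <- basin_fractions(toy_identity(), n_starts = 50000, seed = 2)
  expect_length(fr, 2L)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr[1]), 0.5, tolerance = 0.05)

  fr1 <- basin_fractions(build_cfl1_model(), n_starts = 5000, seed = 8)
  expect_equal(sum(fr1), 1)
})

test_that("trajectory CSV export lays out nodes by rows and steps by columns", {
  traj <- simulate_network(build_cfl1_model())
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  grid <- utils::read.csv(f, check.names = FALSE)
  expect_identical(grid$node, build_cfl1_model()$nodes)
  expect_identical(grid[grid$node == "STAT3", "t8"], 1L)
  expect_identical(grid[grid$node == "STAT3", "t7"], 0L)
  unlink(f)
})
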