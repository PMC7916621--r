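test_that("clamps replace rules by constants without touching the original", {
  net <- build_cfl1_model()
  iv <- intervention(c(STAT3 = 0L))
  inet <- apply_intervention(net, iv)
  expect_identical(inet$rules[["STAT3"]], rx_const(0L))
  expect_length(inet$nodes, 33L)
  expect_false(is_const <- cfl1bn:::is_const_rule(net$rules[["STAT3"]]))

  up <- apply_intervention(net, intervention(c(CFL1 = 1L)))
  expect_identical(up$rules[["CFL1"]], rx_const(1L))

  wt <- apply_intervention(net, intervention())
  expect_identical(wt$rules, net$rules)

  expect_error(apply_intervention(net, intervention(c(NOPE = 0L))),
               "unknown node")
})

test_that("clamped nodes hold their value along every trajectory", {
  net <- build_cfl1_model()
  inet <- apply_intervention(net, intervention(c(AURKA = 0L, CFL1 = 1L)))
  set.seed(17)
  x <- expand_delays(inet)
  for (i in 1:5) {
    init <- stats::setNames(sample(0:1, length(x$nodes), TRUE), x$nodes)
    traj <- simulate_network(x, init)
    expect_true(all(traj$states[-1L, "AURKA"] == 0L))
    expect_true(all(traj$states[-1L, "CFL1"] == 1L))
  }
})

test_that("the composite siRNA knockout yields cell-cycle arrest without apoptosis", {
  iv <- cfl1_sirna_knockout()
  expect_length(iv$clamps, 2L)
  net <- apply_intervention(build_cfl1_model(), iv)
  traj <- simulate_network(net)
  expect_true(traj$resolved)
  expect_identical(traj$cycle_length, 1L)
  final <- traj$states[nrow(traj$states), ]
  expect_true(all(final[c("S-phase", "CCND1", "E2F", "CCNE1", "F-actin_new",
                          "STAT3", "AKT", "Caspases")] == 0L))
  # CYCS never activates under total CFL1 loss
  expect_true(all(traj$states[, "CYCS"] == 0L))
})

test_that("single CFL1 clamp differs from the composite knockout on STAT3", {
  net <- build_cfl1_model()
  stat3 <- net$rules[["STAT3"]]
  lookup <- function(v) function(node, delay) v[[node]]
  # under CFL1:=0 alone, phosphorylated CFL1 still activates STAT3
  v1 <- c("Phosphorylated-CFL1" = 1L, CFL1 = 0L, CD44 = 1L)
  expect_identical(cfl1bn:::eval_rule(stat3, lookup(v1)), 1L)
  # the composite clamp removes both forms
  v2 <- c("Phosphorylated-CFL1" = 0L, CFL1 = 0L, CD44 = 1L)
  expect_identical(cfl1bn:::eval_rule(stat3, lookup(v2)), 0L)
})

test_that("the intervention universe matches the combinatorial count", {
  net <- build_cfl1_model()
  u2 <- enumerate_interventions(net, max_size = 2)
  expect_length(u2, 2048L)
  u1 <- enumerate_interventions(net, max_size = 1)
  expect_length(u1, 64L)
  # independent closed form: 2n singles + 4 C(n,2) pairs over n = 32
  n <- length(setdiff(net$nodes, "Caspases"))
  expect_identical(length(u2), as.integer(2L * n + 4L * choose(n, 2)))
  # no intervention touches the caspase readout
  expect_false(any(vapply(u2, function(iv) {
    "Caspases" %in% names(iv$clamps)
  }, TRUE)))
  # all distinct
  expect_identical(anyDuplicated(vapply(u2, `[[`, "", "label")), 0L)

  toy <- toy_constant_chain()
  expect_length(enumerate_interventions(toy, max_size = 1, exclude = NULL), 6L)
})

test_that("apoptosis verdicts match the model biology", {
  net <- build_cfl1_model()
  r <- induces_apoptosis(net, intervention(c(CD44 = 0L)), n_starts = 5000,
                         seed = 1)
  expect_identical(r$verdict, "full")
  expect_identical(r$fraction, 1)

  # CFL1 alone cannot induce apoptosis: CYCS requires CFL1
  r <- induces_apoptosis(net, intervention(c(CFL1 = 0L)), n_starts = 5000,
                         seed = 1)
  expect_false(r$verdict == "full")
  expect_identical(r$fraction, 0)

  # wild type: no apoptotic attractor
  r <- induces_apoptosis(net, intervention(), n_starts = 5000, seed = 1)
  expect_identical(r$verdict, "none")
})

test_that("attractor phenotype classification follows the marker nodes", {
  net <- build_cfl1_model()
  wt <- simulate_network(net)
  fp <- fixed_points(net)$attractors[[1]]
  ph <- classify_attractor(fp)
  expect_true(ph[["proliferation"]])
  expect_true(ph[["migration"]])
  expect_false(ph[["apoptosis"]])
  expect_false(ph[["arrest"]])

  sir <- apply_intervention(net, cfl1_sirna_knockout())
  a <- fixed_points(sir)$attractors
  calls <- lapply(a, classify_attractor)
  arrest <- vapply(calls, `[[`, TRUE, "arrest")
  expect_true(any(arrest))

  stat3 <- apply_intervention(net, intervention(c(STAT3 = 0L)))
  for (at in find_attractors(stat3, 3000, seed = 2)$attractors) {
    expect_true(classify_attractor(at)[["apoptosis"]])
  }
})

test_that("screening reports are reproducible byte for byte", {
  net <- build_cfl1_model()
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  r1 <- screen_interventions(net, max_size = 1, n_starts = 400, seed = 7)
  r2 <- screen_interventions(net, max_size = 1, n_starts = 400, seed = 7)
  write_screening_report(r1, json = f1)
  write_screening_report(r2, json = f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  # full verdicts imply basin fraction 1 (monotone consistency)
  full <- r1$results$verdict == "full"
  expect_true(all(r1$results$caspase_basin_fraction[full] == 1))
})
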