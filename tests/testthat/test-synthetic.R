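test_that("expression generation is a pure function of its spec", {
  a <- synth_expression(c("X", "Y"), n_per_class = 6, delta = 1, sigma = 1,
                        replicates = c(tumor_01 = 3), seed = 9)
  b <- synth_expression(c("X", "Y"), n_per_class = 6, delta = 1, sigma = 1,
                        replicates = c(tumor_01 = 3), seed = 9)
  expect_identical(a$values, b$values)
  expect_identical(a$labels, b$labels)
  expect_identical(a$replicate_groups, b$replicate_groups)
  # replicate columns exist and share a group
  expect_identical(sum(a$replicate_groups == "tumor_01", na.rm = TRUE), 3L)
})

test_that("null-shift matrices have near-equal class means", {
  m <- synth_expression(paste0("g", 1:5), n_per_class = 100, delta = 0,
                        sigma = 1, seed = 4)
  diffs <- rowMeans(m$values[, m$labels == "tumor"]) -
           rowMeans(m$values[, m$labels == "normal"])
  expect_true(all(abs(diffs) < 4 / sqrt(100)))
})

test_that("strong shifts separate classes in nearly every seeded repetition", {
  hits <- vapply(1:200, function(s) {
    m <- synth_expression("G", n_per_class = 20, delta = 5, sigma = 1,
                          seed = s)
    isTRUE(all.equal(roc_threshold(m$values["G", ], m$labels)$j, 1))
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("random networks are reproducible and respect their spec", {
  a <- random_network(10, k = 3, seed = 31)
  b <- random_network(10, k = 3, seed = 31)
  expect_identical(write_network(a), write_network(b))
  expect_length(a$nodes, 10L)
  s <- network_summary(a)
  expect_true(all(s$regulators <= 3L))
  # delay-free generation expands to itself
  expect_identical(nrow(expand_delays(a)$registers), 0L)
  d <- random_network(8, k = 2, delay_prob = 1, seed = 5)
  expect_gt(nrow(expand_delays(d)$registers), 0L)
})

test_that("brute-force oracle handles canonical small cases", {
  bf <- brute_force_attractors(toy_oscillator())
  expect_length(bf$attractors, 1L)
  expect_identical(bf$attractors[[1]]$length, 4L)
  expect_identical(bf$attractors[[1]]$basin, 4L)

  bf <- brute_force_attractors(toy_identity())
  expect_length(bf$attractors, 2L)
  expect_identical(vapply(bf$attractors, `[[`, 0L, "basin"), c(`0` = 1L, `1` = 1L))

  expect_error(brute_force_attractors(build_cfl1_model()), "2\\^38")
})

test_that("sampled plus exact enumeration matches brute force on random networks", {
  # delay-free corpus
  for (s in 1:40) {
    net <- random_network(10, k = 3, delay_prob = 0, seed = s)
    bf <- brute_force_attractors(net)
    sm <- find_attractors(net, n_starts = 10240, seed = s + 1000)
    expect_identical(aset_keys(sm), aset_keys(bf))
  }
  # delayed corpus, sampling the full expanded state space
  for (s in 1:10) {
    net <- random_network(8, k = 2, delay_prob = 0.3, seed = s)
    nb <- length(expand_delays(net)$nodes)
    bf <- brute_force_attractors(net)
    sm <- find_attractors(net, n_starts = 2^nb * 10, seed = s + 2000,
                          register_init = "random")
    expect_identical(aset_keys(sm), aset_keys(bf))
  }
})
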