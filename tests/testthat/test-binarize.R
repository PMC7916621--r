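mk_expr <- function(values, labels, genes = "G") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, paste0("s", seq_along(values))))
  labeled_expression(m, labels)
}

test_that("replicate averaging collapses groups to per-gene means", {
  vals <- matrix(c(2, 4, 6, 10), 1, 4,
                 dimnames = list("G", c("a1", "a2", "a3", "b")))
  m <- labeled_expression(vals, c("tumor", "tumor", "tumor", "normal"),
                          c("grpA", "grpA", "grpA", NA))
  avg <- average_replicates(m)
  expect_identical(ncol(avg$values), 2L)
  expect_identical(avg$values[["G", "a1"]], 4)
  expect_identical(unname(avg$labels), c("tumor", "normal"))
  # idempotent
  expect_identical(average_replicates(avg)$values, avg$values)
})

test_that("averaging is the identity when all groups are singletons", {
  vals <- matrix(1:4, 1, 4, dimnames = list("G", paste0("s", 1:4)))
  m <- labeled_expression(vals + 0, rep(c("tumor", "normal"), 2),
                          rep(NA_character_, 4))
  expect_identical(average_replicates(m)$values, m$values)
})

test_that("a replicate group mixing classes is an error", {
  vals <- matrix(c(1, 2), 1, 2, dimnames = list("G", c("x", "y")))
  m <- labeled_expression(vals, c("tumor", "normal"), c("g", "g"))
  expect_error(average_replicates(m), "mixes class labels")
})

test_that("ROC threshold separates perfectly separable classes", {
  r <- roc_threshold(c(1, 2, 3, 7, 8, 9),
                     c(rep("normal", 3), rep("tumor", 3)))
  expect_gt(r$threshold, 3)
  expect_lt(r$threshold, 7)
  expect_identical(r$j, 1)
  expect_identical(r$auc, 1)
  expect_identical(r$direction, "up")
})

test_that("direction follows the labels, not the magnitude", {
  # same data, labels swapped: tumors are now the low class
  r <- roc_threshold(c(1, 2, 3, 7, 8, 9),
                     c(rep("tumor", 3), rep("normal", 3)))
  expect_identical(r$j, 1)
  expect_identical(r$direction, "down")
  # calls remain "active above threshold": all tumors inactive
  expect_true(all(c(1, 2, 3) <= r$threshold))
})

test_that("Youden maximization scans midpoint cutpoints with a low tie-break", {
  # exhaustive-scan oracle: cutpoints {2, 3.5, 4.5, 5.5, 7}, J maximal (2/3)
  # at 3.5 and 5.5; tie-break -> 3.5 with sens 1 and spec 2/3
  r <- roc_threshold(c(1, 3, 5, 4, 6, 8),
                     c(rep("normal", 3), rep("tumor", 3)))
  expect_identical(r$threshold, 3.5)
  expect_equal(r$j, 2 / 3)
  expect_identical(r$sensitivity, 1)
  expect_equal(r$specificity, 2 / 3)
})

test_that("thresholds and AUC agree with an independent ROC implementation", {
  set.seed(42)
  for (i in 1:20) {
    vals <- stats::rnorm(30, mean = rep(c(0, 1.2), times = c(14, 16)))
    labels <- rep(c("normal", "tumor"), times = c(14, 16))
    r <- roc_threshold(vals, labels)
    pr <- pROC::roc(labels, vals, levels = c("normal", "tumor"),
                    direction = "auto", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)))
    best <- pROC::coords(pr, "best", best.method = "youden",
                         transpose = FALSE)
    # pROC may return several equally good cutpoints; ours must be among them
    expect_true(any(abs(best$threshold - r$threshold) < 1e-9))
    expect_equal(r$j, max(best$sensitivity + best$specificity - 1),
                 tolerance = 1e-9)
  }
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(roc_threshold(1:4, rep("tumor", 4)), "both classes")
  r <- roc_threshold(rep(2, 4), c("tumor", "tumor", "normal", "normal"))
  expect_true(r$degenerate)
  expect_true(is.na(r$threshold))
})

test_that("calls are invariant under strictly increasing transforms", {
  set.seed(7)
  for (i in 1:25) {
    n <- 12
    vals <- stats::rnorm(2 * n, mean = rep(c(0, stats::runif(1, 0, 2)),
                                           each = n))
    labels <- rep(c("normal", "tumor"), each = n)
    m1 <- mk_expr(vals, labels)
    m2 <- mk_expr(exp(vals), labels)           # strictly increasing
    m3 <- mk_expr(vals^3 + 5 * vals, labels)   # strictly increasing, signed
    b1 <- binarize_matrix(m1)
    expect_identical(b1$calls, binarize_matrix(m2)$calls)
    expect_identical(b1$calls, binarize_matrix(m3)$calls)
  }
})

test_that("strong tumor shifts give perfect calls; null shifts stay near half", {
  m <- synth_expression(c("AURKA", "TCF7L2"), n_per_class = 20, delta = 8,
                        sigma = 1, seed = 123)
  b <- binarize_matrix(m)
  expect_identical(b$thresholds$j, c(1, 1))
  expect_identical(b$thresholds$sensitivity, c(1, 1))
  expect_identical(b$thresholds$specificity, c(1, 1))
  expect_identical(b$thresholds$tumor_active_fraction, c(1, 1))

  taf <- vapply(1:200, function(s) {
    m <- synth_expression("G", n_per_class = 25, delta = 0, sigma = 1,
                          seed = s)
    binarize_matrix(m)$thresholds$tumor_active_fraction
  }, 0)
  expect_equal(mean(taf), 0.5, tolerance = 0.1)
})

test_that("threshold recovers the midpoint between class means", {
  mu0 <- 6; delta <- 2
  thr <- vapply(1:100, function(s) {
    m <- synth_expression("G", n_per_class = 150, delta = delta, sigma = 1,
                          mu0 = mu0, seed = s)
    roc_threshold(m$values["G", ], m$labels)$threshold
  }, 0)
  se <- stats::sd(thr) / sqrt(length(thr))
  expect_lt(abs(mean(thr) - (mu0 + delta / 2)), 3 * se + 0.05)
})

test_that("binarize_matrix validates its gene list and reports fractions", {
  m <- synth_expression(c("A", "B"), n_per_class = 10, delta = c(4, 0),
                        sigma = 1, seed = 2)
  expect_error(binarize_matrix(m, c("A", "ZZZ")), "ZZZ")
  b <- binarize_matrix(m, "A")
  expect_identical(rownames(b$calls), "A")
  expect_identical(b$thresholds$tumor_active_fraction, 1)
})
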