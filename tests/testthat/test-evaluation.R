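test_that("ARI agrees with brute-force pair enumeration and is label-invariant", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1)

  set.seed(51)
  for (rep in 1:10) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b), tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  }

  # independent cross-check against an established implementation
  if (requireNamespace("mclust", quietly = TRUE)) {
    set.seed(52)
    a <- sample(1:5, 60, replace = TRUE)
    b <- sample(1:2, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }

  # named alignment
  a <- setNames(c(1, 1, 2), c("x", "y", "z"))
  b <- setNames(c(2, 1, 1), c("z", "x", "y"))
  expect_equal(adjusted_rand_index(a, b), 1)
  expect_error(adjusted_rand_index(a, setNames(1:3, c("x", "y", "w"))),
               class = "nemo_input_error")
})

test_that("logrank test matches hand-computed observed-vs-expected arithmetic", {
  # 6 samples, groups (1,1,1,2,2,2), times 1..6, third sample censored.
  # Event-time table (group-1 at risk / total at risk):
  #   t=1: d=1, n1=3, n=6 -> E1 += 0.5,  V += 1*(3/6)*(3/6)*(6-1)/(6-1)... = 0.25
  #   t=2: d=1, n1=2, n=5 -> E1 += 0.4,  V += (2/5)*(3/5) = 0.24
  #   t=4,5,6: n1=0, no contribution
  # O1 = 2, E1 = 0.9, V = 0.49, chi2 = (2 - 0.9)^2 / 0.49
  time <- 1:6
  event <- c(1, 1, 0, 1, 1, 1)
  g <- c(1, 1, 1, 2, 2, 2)
  lr <- logrank_test(time, event, g)
  expect_equal(lr$statistic, (2 - 0.9)^2 / 0.49, tolerance = 1e-10)
  expect_identical(lr$df, 1)
  expect_equal(lr$p_value, pchisq((2 - 0.9)^2 / 0.49, 1, lower.tail = FALSE))

  # exchangeable groups: identical survival in both arms
  lr0 <- logrank_test(rep(c(1, 3, 7), 2), rep(c(1, 1, 0), 2), rep(1:2, each = 3))
  expect_lt(lr0$statistic, 1e-10)

  # strong stochastic ordering
  lr1 <- logrank_test(c(1:20, 101:120), rep(1, 40), rep(1:2, each = 20))
  expect_gt(lr1$statistic, 20)
  expect_lt(lr1$p_value, 1e-4)

  # rank-based: doubling all times changes nothing
  set.seed(53)
  tt <- rexp(30); ee <- rbinom(30, 1, 0.7); gg <- sample(1:3, 30, replace = TRUE)
  expect_equal(logrank_test(tt, ee, gg)$statistic,
               logrank_test(2 * tt, ee, gg)$statistic, tolerance = 1e-10)
  # and invariant to group relabeling
  expect_equal(logrank_test(tt, ee, gg)$statistic,
               logrank_test(tt, ee, 4 - gg)$statistic, tolerance = 1e-10)

  expect_error(logrank_test(1:4, rep(1, 4), rep(1, 4)), class = "nemo_input_error")
  expect_error(logrank_test(1:4, rep(0, 4), rep(1:2, 2)), class = "nemo_input_error")
})

test_that("chi-square enrichment statistic matches textbook arithmetic", {
  param <- rep(c("x", "y"), each = 10)
  labels <- rep(1:2, each = 10)
  res <- empirical_enrichment(data.frame(p = param), labels, n_perm = 50, seed = 1)
  expect_equal(res$statistic, 20)  # 2x2 table [[10,0],[0,10]]
  expect_identical(res$type, "discrete")
})

test_that("a parameter duplicating the labels attains the minimal empirical p", {
  labels <- setNames(rep(1:2, each = 15), paste0("s", 1:30))
  clin <- data.frame(dup = rep(c("A", "B"), each = 15),
                     row.names = names(labels))
  res <- empirical_enrichment(clin, labels, n_perm = 1000, seed = 2)
  expect_equal(res$p_value, 1 / 1001)
})

test_that("empirical p-values are calibrated under independence", {
  set.seed(54)
  labels <- sample(1:3, 60, replace = TRUE)
  clin <- as.data.frame(matrix(rnorm(60 * 50), nrow = 60))
  res <- empirical_enrichment(clin, labels, n_perm = 200, seed = 3)
  expect_identical(nrow(res), 50L)
  expect_identical(unique(res$type), "numeric")
  expect_gte(mean(res$p_value > 0.05), 0.8)
  expect_true(all(res$p_value >= 1 / 201))
})

test_that("degenerate clinical parameters are skipped with a warning", {
  labels <- setNames(rep(1:2, each = 5), paste0("s", 1:10))
  clin <- data.frame(const = rep("A", 10), ok = rep(c("A", "B"), 5),
                     row.names = names(labels))
  expect_warning(res <- empirical_enrichment(clin, labels, n_perm = 20, seed = 1),
                 "constant")
  expect_identical(res$parameter, "ok")
})

test_that("Kruskal-Wallis path is invariant to monotone transforms", {
  set.seed(55)
  labels <- rep(1:3, each = 10)
  x <- rnorm(30) + labels
  clin1 <- data.frame(v = x)
  clin2 <- data.frame(v = exp(x))
  r1 <- empirical_enrichment(clin1, labels, n_perm = 100, seed = 4)
  r2 <- empirical_enrichment(clin2, labels, n_perm = 100, seed = 4)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value)
})
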