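test_that("squared distances match hand arithmetic and brute force", {
  x <- matrix(c(0, 1, 3), nrow = 1, dimnames = list("f1", c("a", "b", "c")))
  expect_equal(unname(pairwise_sqdist(x)),
               matrix(c(0, 1, 9, 1, 0, 4, 9, 4, 0), 3, 3))

  # duplicated sample columns give zero off-diagonal distance
  xd <- cbind(x, d = x[, "b", drop = FALSE])
  colnames(xd) <- c("a", "b", "c", "d")
  expect_equal(pairwise_sqdist(xd)["b", "d"], 0)

  set.seed(11)
  xr <- random_omic(6, 10)
  d2 <- pairwise_sqdist(xr)
  expect_lt(max(abs(d2 - oracle_sqdist(xr))), 1e-10)
  expect_identical(d2, t(d2))
  expect_true(all(diag(d2) == 0) && all(d2 >= 0))
})

test_that("knn sets have exact size, exclude self, and match a full sort", {
  x <- matrix(c(0, 1, 3), nrow = 1, dimnames = list("f1", c("a", "b", "c")))
  d2 <- pairwise_sqdist(x)
  nn <- knn_index(d2, 1)
  expect_equal(as.vector(nn$neighbors), c(2L, 1L, 2L))

  # k = n - 1: complete neighbourhoods
  nn2 <- knn_index(d2, 2)
  for (i in 1:3) expect_setequal(nn2$neighbors[, i], setdiff(1:3, i))

  set.seed(12)
  xr <- random_omic(12, 4)
  d2r <- pairwise_sqdist(xr)
  nn3 <- knn_index(d2r, 3)
  ref <- oracle_knn(d2r, 3)
  for (i in 1:12) {
    expect_equal(nn3$neighbors[, i], ref[[i]])
    expect_false(i %in% nn3$neighbors[, i])
  }
  expect_equal(nn3$mean_sq_dist,
               sapply(1:12, function(i) mean(d2r[i, ref[[i]]])))

  expect_error(knn_index(d2, 3), class = "nemo_parameter_error")
  expect_error(knn_index(d2, 0), class = "nemo_parameter_error")
})

test_that("local scales average the three squared-distance terms", {
  x <- matrix(c(0, 1, 3), nrow = 1, dimnames = list("f1", c("a", "b", "c")))
  d2 <- pairwise_sqdist(x)
  nn <- knn_index(d2, 1)
  s2 <- local_scale(d2, nn)
  expect_equal(s2["a", "b"], 1)
  expect_equal(s2["a", "c"], (1 + 4 + 9) / 3)
  expect_equal(s2["b", "c"], (1 + 4 + 4) / 3)

  # degenerate: identical samples floor at epsilon
  xz <- matrix(0, nrow = 2, ncol = 4,
               dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  d2z <- pairwise_sqdist(xz)
  nnz <- knn_index(d2z, 2)
  expect_message(s2z <- local_scale(d2z, nnz), "floored")
  expect_true(all(s2z == 1e-12))

  set.seed(13)
  xr <- random_omic(9, 5)
  d2r <- pairwise_sqdist(xr)
  nnr <- knn_index(d2r, 3)
  expect_lt(max(abs(local_scale(d2r, nnr) -
                    oracle_sigma2(d2r, oracle_knn(d2r, 3)))), 1e-10)
})

test_that("RBF similarity uses the printed prefactor and stays symmetric", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2)
  s2 <- matrix(1, 2, 2)
  s <- rbf_affinity(d2, s2)
  expect_equal(s[1, 2], exp(-0.5) / (2 * pi))
  expect_equal(s[1, 1], 1 / (2 * pi))             # d2 = 0 case
  s_big <- rbf_affinity(d2 * 0, s2 * 2)
  expect_equal(s_big[1, 1], (1 / (2 * pi)) / sqrt(2))  # prefactor algebra

  # density variant
  sd_ <- rbf_affinity(d2, s2, prefactor = "density")
  expect_equal(sd_[1, 2], exp(-0.5) / sqrt(2 * pi))

  expect_error(rbf_affinity(d2, matrix(0, 2, 2)), class = "nemo_input_error")
})

test_that("relative similarity matches hand evaluation and brute force", {
  x <- matrix(c(0, 1, 3), nrow = 1, dimnames = list("f1", c("a", "b", "c")))
  d2 <- pairwise_sqdist(x)
  nn <- knn_index(d2, 1)
  rs <- relative_similarity(rbf_affinity(d2, local_scale(d2, nn)), nn)
  expect_equal(rs["a", "b"], 2)  # mutual nearest neighbours
  expect_equal(rs["b", "c"], 1)  # one-directional neighbourhood
  expect_equal(rs["a", "c"], 0)
  expect_true(all(diag(rs) == 0))

  set.seed(14)
  xr <- random_omic(15, 6)
  rs_v <- omic_relative_similarity(xr, k = 4)
  expect_lt(max(abs(rs_v - oracle_omic_rs(xr, 4))), 1e-10)
})

test_that("RS decomposes as A + t(A) with neighbourhood-stochastic rows", {
  set.seed(15)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    k <- sample(seq_len(n - 1), 1)
    x <- random_omic(n, sample(1:10, 1))
    d2 <- pairwise_sqdist(x)
    nn <- knn_index(d2, k)
    s <- rbf_affinity(d2, local_scale(d2, nn))
    rs <- relative_similarity(s, nn)
    expect_lt(max(abs(rs - t(rs))), 1e-12)
    # rebuild the row-stochastic part independently and check rs = A + t(A)
    a <- matrix(0, n, n)
    for (i in seq_len(n))
      a[i, nn$neighbors[, i]] <- s[i, nn$neighbors[, i]] /
        sum(s[i, nn$neighbors[, i]])
    expect_equal(rowSums(a), rep(1, n))
    expect_lt(max(abs(rs - (a + t(a)))), 1e-12)
    # support: rs nonzero iff neighbour relation in either direction
    member <- matrix(FALSE, n, n)
    member[cbind(rep(seq_len(n), each = k), as.vector(nn$neighbors))] <- TRUE
    expect_identical(unname(rs != 0), member | t(member))
  }
})

test_that("neighbourhood support is invariant to feature rescaling", {
  set.seed(16)
  x <- random_omic(10, 7)
  d2a <- pairwise_sqdist(x)
  d2b <- pairwise_sqdist(3.7 * x)
  expect_lt(max(abs(d2b - 3.7^2 * d2a)), 1e-8)
  nna <- knn_index(d2a, 3)
  nnb <- knn_index(d2b, 3)
  expect_identical(nna$neighbors, nnb$neighbors)
  s2a <- local_scale(d2a, nna)
  s2b <- local_scale(d2b, nnb)
  expect_lt(max(abs(s2b - 3.7^2 * s2a)), 1e-8)
})

test_that("choose_k follows the samples-over-clusters rule with clamping", {
  expect_identical(choose_k(300, 2), 150L)
  expect_identical(choose_k(300), 50L)
  expect_identical(choose_k(100), 16L)
  expect_identical(choose_k(5), 1L)          # floor(5/6) clamps up to 1
  expect_identical(choose_k(4, 2), 2L)
  expect_identical(choose_k(6, 1), 5L)       # clamp to n - 1
  expect_error(choose_k(100, 0), class = "nemo_parameter_error")
})

test_that("invalid omic matrices are rejected with context", {
  x <- matrix(c(1, NA, 3, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(omic_relative_similarity(x, k = 1), class = "nemo_input_error")
  xd <- matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "a")))
  expect_error(omic_relative_similarity(xd, k = 1), class = "nemo_input_error")
  x1 <- matrix(1:2, 2, 1, dimnames = list(NULL, "a"))
  expect_error(omic_relative_similarity(x1, k = 1), class = "nemo_input_error")
})
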