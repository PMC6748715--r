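# Naive reference implementations used as independent oracles. All are
# deliberately written as scalar double loops over the defining formulas,
# sharing no code with the package internals.

oracle_sqdist <- function(x) {
  n <- ncol(x)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d2[i, j] <- sum((x[, i] - x[, j])^2)
  d2
}

oracle_knn <- function(d2, k) {
  n <- ncol(d2)
  lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    others[order(d2[i, others], others)][seq_len(k)]
  })
}

oracle_sigma2 <- function(d2, nbrs, eps = 1e-12) {
  n <- ncol(d2)
  k <- length(nbrs[[1]])
  s2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mi <- sum(d2[i, nbrs[[i]]]) / k
    mj <- sum(d2[j, nbrs[[j]]]) / k
    s2[i, j] <- max((mi + mj + d2[i, j]) / 3, eps)
  }
  s2
}

oracle_similarity <- function(d2, s2) {
  n <- ncol(d2)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    s[i, j] <- exp(-d2[i, j] / (2 * s2[i, j])) / (2 * pi * sqrt(s2[i, j]))
  s
}

oracle_rs <- function(s, nbrs) {
  n <- ncol(s)
  rs <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    t1 <- if (j %in% nbrs[[i]]) s[i, j] / sum(s[i, nbrs[[i]]]) else 0
    t2 <- if (i %in% nbrs[[j]]) s[i, j] / sum(s[nbrs[[j]], j]) else 0
    rs[i, j] <- t1 + t2
  }
  rs
}

# full chain for one omic at given k
oracle_omic_rs <- function(x, k) {
  d2 <- oracle_sqdist(x)
  nbrs <- oracle_knn(d2, k)
  s2 <- oracle_sigma2(d2, nbrs)
  s <- oracle_similarity(d2, s2)
  rs <- oracle_rs(s, nbrs)
  dimnames(rs) <- list(colnames(x), colnames(x))
  rs
}

# per-pair averaging over the omics observed for both samples
oracle_ars <- function(rs_list, union_ids) {
  n <- length(union_ids)
  ars <- matrix(0, n, n, dimnames = list(union_ids, union_ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    vals <- c()
    for (rs in rs_list) {
      ids <- colnames(rs)
      pi <- match(union_ids[i], ids)
      pj <- match(union_ids[j], ids)
      if (!is.na(pi) && !is.na(pj)) vals <- c(vals, rs[pi, pj])
    }
    ars[i, j] <- mean(vals)
  }
  ars
}

# adjusted Rand index by explicit enumeration of all sample pairs
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
}

# regenerate the cluster centers of nemo_simulate from its declared contract
# (centers are the first draw under the seed)
with_seed_helper <- function(seed, n_features, n_clusters, spread) {
  set.seed(seed)
  matrix(rnorm(n_features * n_clusters, sd = spread), nrow = n_features)
}

random_omic <- function(n, p, ids = paste0("s", seq_len(n))) {
  matrix(rnorm(p * n), nrow = p, dimnames = list(paste0("f", seq_len(p)), ids))
}

# block-diagonal affinity: c blocks of size m with unit within-block weight
# (zero diagonal) and `noise` between blocks
block_affinity <- function(c_blocks, m, noise = 0) {
  n <- c_blocks * m
  w <- matrix(noise, n, n)
  for (b in seq_len(c_blocks)) {
    idx <- ((b - 1) * m + 1):(b * m)
    w[idx, idx] <- 1
  }
  diag(w) <- 0
  dimnames(w) <- list(paste0("s", 1:n), paste0("s", 1:n))
  w
}
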