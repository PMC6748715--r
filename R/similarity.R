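#' Pairwise squared Euclidean distances between samples
#'
#' Computes the full matrix of squared Euclidean distances between the
#' columns (samples) of a features-by-samples omic matrix.
#'
#' @param x Numeric matrix, features in rows, samples in columns. Column
#'   names, if present, are carried to the result.
#' @return Symmetric \code{n x n} matrix of squared distances with zero
#'   diagonal, where \code{n = ncol(x)}.
#' @examples
#' x <- matrix(c(0, 1, 3), nrow = 1)
#' pairwise_sqdist(x)
#' @export
pairwise_sqdist <- function(x) {
  x <- validate_omic(x, require_ids = FALSE)
  sq <- colSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * crossprod(x)
  # guard tiny negative round-off, enforce exact symmetry and zero diagonal
  d2[d2 < 0] <- 0
  d2 <- (d2 + t(d2)) / 2
  diag(d2) <- 0
  dimnames(d2) <- list(colnames(x), colnames(x))
  d2
}

validate_omic <- function(x, require_ids = TRUE, name = "omic") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop_input(sprintf("%s must be a numeric matrix (features x samples)", name))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop_input(sprintf(
      "%s has a missing value at feature %d, sample %d; missing data must be whole-sample omic absence (drop the sample's column), never NA cells",
      name, bad[1], bad[2]))
  }
  if (ncol(x) < 2) stop_input(sprintf("%s needs at least 2 samples", name))
  if (nrow(x) < 1) stop_input(sprintf("%s needs at least 1 feature", name))
  if (require_ids) {
    ids <- colnames(x)
    if (is.null(ids)) stop_input(sprintf("%s must carry sample IDs as column names", name))
    if (anyDuplicated(ids))
      stop_input(sprintf("%s has duplicated sample IDs: %s", name,
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  x
}

#' k-nearest-neighbour index of a distance matrix
#'
#' For each sample, finds its \code{k} nearest other samples (self excluded)
#' under the supplied squared-distance matrix, together with the mean squared
#' distance to those neighbours. Ties are broken by ascending sample index so
#' results are identical across platforms.
#'
#' @param d2 Symmetric squared-distance matrix as returned by
#'   \code{\link{pairwise_sqdist}}.
#' @param k Neighbourhood size, an integer in \code{[1, n - 1]}.
#' @return A list of class \code{"nemo_knn"} with elements \code{k},
#'   \code{neighbors} (a \code{k x n} integer matrix; column \code{i} holds the
#'   neighbour indices of sample \code{i} in order of increasing distance) and
#'   \code{mean_sq_dist} (length-\code{n} vector).
#' @export
knn_index <- function(d2, k) {
  n <- ncol(d2)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n - 1L)
    stop_param(sprintf("k must be an integer in [1, %d], got %s", n - 1L, format(k)))
  nbrs <- matrix(0L, nrow = k, ncol = n)
  msd <- numeric(n)
  idx <- seq_len(n)
  for (i in idx) {
    d <- d2[i, ]
    d[i] <- Inf
    ord <- order(d, idx)   # stable: ties resolved by ascending sample index
    nbrs[, i] <- ord[seq_len(k)]
    msd[i] <- sum(d[nbrs[, i]]) / k
  }
  structure(list(k = k, neighbors = nbrs, mean_sq_dist = msd,
                 sample_ids = colnames(d2)),
            class = "nemo_knn")
}

#' Local scaling factors for the similarity kernel
#'
#' The local scale for a sample pair averages three squared distances: each
#' sample's mean squared distance to its k nearest neighbours, and the squared
#' distance between the two samples. It adapts the kernel bandwidth to the
#' local sampling density.
#'
#' @param d2 Squared-distance matrix.
#' @param nn \code{"nemo_knn"} index built from \code{d2}.
#' @param eps Strictly positive floor applied entrywise; duplicated samples
#'   would otherwise give a zero scale. A message is emitted when the floor
#'   triggers.
#' @return Symmetric matrix of local scales \code{sigma^2}, all entries
#'   \code{>= eps}.
#' @export
local_scale <- function(d2, nn, eps = 1e-12) {
  m <- nn$mean_sq_dist
  sigma2 <- (outer(m, m, "+") + d2) / 3
  low <- sigma2 < eps
  if (any(low)) {
    message(sprintf("local_scale: %d entries below %.1e floored (duplicate or near-duplicate samples)",
                    sum(low), eps))
    sigma2[low] <- eps
  }
  dimnames(sigma2) <- dimnames(d2)
  sigma2
}

#' Locally-scaled RBF similarity matrix
#'
#' Similarity between samples i and j is
#' \deqn{S(i,j) = \frac{1}{2\pi\sigma_{ij}} \exp\!\left(-\frac{d^2(i,j)}{2\sigma_{ij}^2}\right)}
#' with \eqn{\sigma_{ij} = \sqrt{\sigma_{ij}^2}} the pairwise local scale.
#'
#' @param d2 Squared-distance matrix.
#' @param sigma2 Local-scale matrix from \code{\link{local_scale}}.
#' @param prefactor \code{"2pi"} (default) uses the \eqn{1/(2\pi\sigma)}
#'   normalisation; \code{"density"} uses the Gaussian-density constant
#'   \eqn{1/(\sqrt{2\pi}\sigma)}. The choice cancels in the relative
#'   similarity whenever scales are locally comparable, but both are exposed.
#' @return Symmetric positive similarity matrix.
#' @export
rbf_affinity <- function(d2, sigma2, prefactor = c("2pi", "density")) {
  prefactor <- match.arg(prefactor)
  if (!all(dim(d2) == dim(sigma2)))
    stop_input("d2 and sigma2 must have identical dimensions")
  if (any(sigma2 <= 0)) stop_input("sigma2 must be strictly positive")
  sig <- sqrt(sigma2)
  pref <- if (prefactor == "2pi") 1 / (2 * pi * sig) else 1 / (sqrt(2 * pi) * sig)
  s <- pref * exp(-d2 / (2 * sigma2))
  s <- (s + t(s)) / 2
  dimnames(s) <- dimnames(d2)
  s
}

#' Relative similarity within k-nearest-neighbour sets
#'
#' Renormalises a similarity matrix within each sample's neighbourhood:
#' \deqn{RS(i,j) = \frac{S(i,j)}{\sum_{r \in \eta_i} S(i,r)} I(j \in \eta_i)
#'              + \frac{S(i,j)}{\sum_{r \in \eta_j} S(r,j)} I(i \in \eta_j)}
#' The result is symmetric with zero diagonal, and decomposes as
#' \code{A + t(A)} where each row of \code{A} sums to exactly 1 over the
#' sample's neighbourhood — the rows of \code{A} are transition distributions
#' of a random walk restricted to nearest neighbours, which is what makes
#' relative similarities comparable across omics with different value
#' distributions.
#'
#' @param s Similarity matrix from \code{\link{rbf_affinity}}.
#' @param nn \code{"nemo_knn"} index over the same samples.
#' @return Symmetric nonnegative matrix \code{RS} with zero diagonal;
#'   \code{RS[i, j]} is nonzero only if \code{j} is a neighbour of \code{i} or
#'   vice versa.
#' @export
relative_similarity <- function(s, nn) {
  n <- ncol(s)
  if (ncol(nn$neighbors) != n)
    stop_input("similarity matrix and neighbour index cover different sample sets")
  mask <- matrix(FALSE, n, n)
  mask[cbind(rep(seq_len(n), each = nn$k), as.vector(nn$neighbors))] <- TRUE
  sn <- s * mask
  denom <- rowSums(sn)
  if (any(denom <= 0))
    stop_numerical("zero neighbour-sum denominator in relative similarity")
  a <- sn / denom
  rs <- a + t(a)
  dimnames(rs) <- dimnames(s)
  rs
}

#' Default neighbourhood size
#'
#' The neighbourhood size is the expected cluster size: \code{floor(n /
#' n_clusters)} when the number of clusters is known, and \code{floor(n / 6)}
#' otherwise — 6 being a crude typical cluster count for cancer cohorts. The
#' result is clamped to \code{[1, n - 1]}.
#'
#' @param n_samples Number of samples in the omic.
#' @param n_clusters Optional known number of clusters.
#' @return Integer neighbourhood size.
#' @examples
#' choose_k(300, 2)   # 150
#' choose_k(300)      # 50
#' @export
choose_k <- function(n_samples, n_clusters = NULL) {
  if (n_samples < 2) stop_param("need at least 2 samples")
  if (!is.null(n_clusters)) {
    if (n_clusters < 1) stop_param("n_clusters must be >= 1")
    k <- floor(n_samples / n_clusters)
  } else {
    k <- floor(n_samples / 6)
  }
  as.integer(min(max(k, 1), n_samples - 1))
}

#' Per-omic relative similarity in one call
#'
#' Convenience chain: squared distances, k-nearest neighbours, local scales,
#' RBF similarity, neighbourhood renormalisation.
#'
#' @inheritParams pairwise_sqdist
#' @param k Neighbourhood size; defaults to \code{\link{choose_k}} of the
#'   omic's sample count.
#' @param n_clusters Optional cluster count used only to pick the default
#'   \code{k}.
#' @inheritParams rbf_affinity
#' @param scale_features If \code{TRUE}, z-score each feature first (off by
#'   default; inputs are assumed preprocessed).
#' @return Relative-similarity matrix with sample IDs as dimnames.
#' @export
omic_relative_similarity <- function(x, k = NULL, n_clusters = NULL,
                                     prefactor = c("2pi", "density"),
                                     scale_features = FALSE) {
  x <- validate_omic(x)
  if (scale_features) {
    sds <- apply(x, 1, stats::sd)
    sds[sds == 0] <- 1
    x <- (x - rowMeans(x)) / sds
  }
  if (is.null(k)) k <- choose_k(ncol(x), n_clusters)
  d2 <- pairwise_sqdist(x)
  nn <- knn_index(d2, k)
  sigma2 <- local_scale(d2, nn)
  s <- rbf_affinity(d2, sigma2, prefactor = match.arg(prefactor))
  relative_similarity(s, nn)
}
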