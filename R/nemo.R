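#' Neighbourhood-based multi-omics clustering
#'
#' Clusters a multi-omic cohort in three phases. First, each omic is reduced
#' to a relative-similarity network: a locally-scaled RBF similarity
#' renormalised within every sample's k-nearest-neighbour set
#' (\code{\link{omic_relative_similarity}}). Second, the per-omic networks
#' are averaged into one integrated network — over all omics when every
#' sample has every omic, or over only the omics observed for each sample
#' pair when the dataset is partial (\code{\link{integrate_partial}}); no
#' imputation is performed, but every sample pair must share at least one
#' omic. Third, the integrated network is partitioned by normalised-Laplacian
#' spectral clustering, with the number of clusters chosen by a weighted
#' eigengap rule unless supplied (\code{\link{num_clusters_eigengap}}).
#'
#' @param omics A list of numeric omic matrices, each features x samples
#'   with sample IDs as column names. Sample sets may differ between omics
#'   (whole-sample absence); within a matrix no cell may be \code{NA}.
#' @param n_clusters Optional number of clusters. When missing it is chosen
#'   by the weighted eigengap rule; when given it also sets the default
#'   neighbourhood size to \code{floor(n_l / n_clusters)} per omic.
#' @param k Optional neighbourhood size override applied to every omic; by
#'   default each omic uses \code{\link{choose_k}} of its own sample count.
#'   An explicit \code{k} wins over the \code{n_clusters}-derived default.
#' @param max_clusters Upper bound of the eigengap search range (default 15).
#' @param seed RNG seed for the k-means stage (default 1); the fit is fully
#'   deterministic given inputs and seed.
#' @param prefactor Kernel prefactor convention, see
#'   \code{\link{rbf_affinity}}.
#' @param scale_features Z-score features within each omic before computing
#'   distances (default \code{FALSE}; inputs are assumed preprocessed).
#' @return An object of class \code{"nemo"}: a list with \code{labels}
#'   (named integer cluster assignment over the union of samples),
#'   \code{n_clusters}, \code{k} (per-omic neighbourhood sizes),
#'   \code{eigenvalues} (ascending Laplacian spectrum used for model
#'   selection), \code{ars} (integrated network), \code{coverage} (per-pair
#'   omic counts), \code{partial} flag, \code{n_samples} per omic,
#'   \code{seed} and \code{call}.
#' @examples
#' sim <- nemo_simulate(center_spread = 5, samples_per_cluster = 30,
#'                      seed = 7)
#' fit <- nemo(sim$omics, seed = 7)
#' table(fit$labels, sim$labels)
#' @seealso \code{\link{nemo_simulate}}, \code{\link{adjusted_rand_index}},
#'   \code{\link{logrank_test}}
#' @export
nemo <- function(omics, n_clusters = NULL, k = NULL, max_clusters = 15,
                 seed = 1, prefactor = c("2pi", "density"),
                 scale_features = FALSE) {
  cl <- match.call()
  prefactor <- match.arg(prefactor)
  if (!is.list(omics) || length(omics) == 0)
    stop_input("omics must be a non-empty list of matrices")
  if (is.null(names(omics)) || any(names(omics) == ""))
    names(omics) <- paste0("omic", seq_along(omics))
  omics <- mapply(validate_omic, omics, name = names(omics), SIMPLIFY = FALSE)
  if (!is.null(n_clusters) && n_clusters < 2)
    stop_param("n_clusters must be >= 2")

  union_ids <- union_sample_ids(omics)
  n <- length(union_ids)
  partial <- any(vapply(omics, ncol, 0L) != n)

  ks <- vapply(omics, function(x) {
    nl <- ncol(x)
    if (!is.null(k)) as.integer(min(max(k, 1), nl - 1))
    else choose_k(nl, n_clusters)
  }, integer(1))

  rs_list <- mapply(function(x, kl) {
    omic_relative_similarity(x, k = kl, prefactor = prefactor,
                             scale_features = scale_features)
  }, omics, ks, SIMPLIFY = FALSE)

  if (partial) {
    net <- integrate_partial(rs_list, union_ids)
  } else {
    aligned <- lapply(rs_list, function(r) {
      i <- match(union_ids, colnames(r))
      r[i, i, drop = FALSE]
    })
    net <- integrate_full(aligned)
  }
  cov <- attr(net, "coverage")
  ars <- net
  attr(ars, "coverage") <- NULL

  spectrum <- laplacian_spectrum(ars)
  c_used <- if (is.null(n_clusters))
    num_clusters_eigengap(spectrum, max_clusters = max_clusters)
  else as.integer(n_clusters)

  labels <- spectral_cluster(ars, c_used, seed = seed, spectrum = spectrum)

  structure(list(labels = labels,
                 n_clusters = c_used,
                 n_clusters_given = !is.null(n_clusters),
                 k = ks,
                 eigenvalues = spectrum$values,
                 ars = ars,
                 coverage = cov,
                 partial = partial,
                 n_samples = vapply(omics, ncol, 0L),
                 n_features = vapply(omics, nrow, 0L),
                 seed = seed,
                 call = cl),
            class = "nemo")
}

#' @export
print.nemo <- function(x, ...) {
  cat("Neighbourhood-based multi-omics clustering\n")
  cat(sprintf("  %d omics, %d samples (%s data)\n",
              length(x$n_samples), length(x$labels),
              if (x$partial) "partial" else "full"))
  cat(sprintf("  clusters: %d (%s); k per omic: %s; seed: %s\n",
              x$n_clusters,
              if (x$n_clusters_given) "user-supplied" else "weighted eigengap",
              paste(x$k, collapse = ", "), format(x$seed)))
  sizes <- table(x$labels)
  cat("  cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.nemo <- function(object, ...) {
  gaps <- diff(object$eigenvalues)
  structure(list(fit = object,
                 cluster_sizes = table(object$labels),
                 leading_eigenvalues = utils::head(object$eigenvalues, 10),
                 eigengap_at_c = gaps[object$n_clusters],
                 mean_coverage = mean(object$coverage[upper.tri(object$coverage)])),
            class = "summary.nemo")
}

#' @export
print.summary.nemo <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean pairwise omic coverage: %.2f\n", x$mean_coverage))
  cat(sprintf("  eigengap at c=%d: %.4f\n", x$fit$n_clusters, x$eigengap_at_c))
  cat("  leading Laplacian eigenvalues:\n   ",
      paste(formatC(x$leading_eigenvalues, digits = 4, format = "f"),
            collapse = " "), "\n")
  invisible(x)
}

#' Eigenvalue diagnostics plot for a nemo fit
#'
#' Plots the leading ascending eigenvalues of the integrated network's
#' normalised Laplacian and the weighted eigengap score over the model
#' search range; the chosen number of clusters is highlighted.
#'
#' @param x A \code{"nemo"} fit.
#' @param n_show How many leading eigenvalues to show.
#' @param ... Passed to \code{plot}.
#' @export
plot.nemo <- function(x, n_show = 20, ...) {
  vals <- x$eigenvalues
  m <- min(n_show, length(vals))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_len(m), vals[seq_len(m)], xlab = "index",
                 ylab = "Laplacian eigenvalue",
                 main = "Spectrum (ascending)", ...)
  graphics::abline(v = x$n_clusters + 0.5, lty = 2)
  hi <- min(length(vals) - 1, m)
  ii <- 2:hi
  score <- (vals[ii + 1] - vals[ii]) * ii
  graphics::plot(ii, score, type = "h", xlab = "candidate clusters",
                 ylab = "weighted eigengap", main = "Model selection")
  graphics::points(x$n_clusters, score[match(x$n_clusters, ii)], pch = 19)
  invisible(x)
}

#' @export
as.data.frame.nemo <- function(x, ...) {
  data.frame(sample_id = names(x$labels), cluster = unname(x$labels),
             stringsAsFactors = FALSE)
}
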