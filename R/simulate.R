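#' Simulate a multi-omic dataset with shared cluster structure
#'
#' Generates Gaussian clusters observed through several noisy omics. A base
#' features-by-samples matrix is drawn as cluster centers plus multivariate
#' normal noise; each signal omic is the base matrix plus independent
#' per-omic normal noise, so all signal omics share the same underlying
#' clustering.
#'
#' @param n_clusters Number of clusters (default 2).
#' @param samples_per_cluster Samples per cluster (default 100).
#' @param n_features Features per omic (default 50).
#' @param n_omics Number of signal omics (default 2).
#' @param center_spread Standard deviation of the per-feature cluster-center
#'   draws (default 1); larger values separate the clusters further.
#' @param base_noise_sd Standard deviation of the shared within-cluster
#'   noise around the centers (default 1).
#' @param omic_noise_sd Standard deviation of the independent per-omic noise
#'   (default 1); may be a vector of length \code{n_omics}.
#' @param seed RNG seed; the generator is a pure function of its arguments
#'   and the seed.
#' @return Object of class \code{"nemo_sim"}: list with \code{omics} (named
#'   list of matrices, sample IDs \code{s1..sn}), \code{labels} (named
#'   true-cluster vector over all samples), \code{mask} (per-omic character
#'   vectors of removed samples, empty until \code{\link{mask_partial}}),
#'   and \code{params}.
#' @export
nemo_simulate <- function(n_clusters = 2, samples_per_cluster = 100,
                          n_features = 50, n_omics = 2,
                          center_spread = 1, base_noise_sd = 1,
                          omic_noise_sd = 1, seed = 1) {
  if (n_clusters < 2) stop_param("n_clusters must be >= 2")
  if (any(c(center_spread, base_noise_sd, omic_noise_sd) <= 0))
    stop_param("spread and noise standard deviations must be positive")
  omic_noise_sd <- rep_len(omic_noise_sd, n_omics)
  n <- n_clusters * samples_per_cluster
  labels <- rep(seq_len(n_clusters), each = samples_per_cluster)
  ids <- paste0("s", seq_len(n))
  names(labels) <- ids
  with_seed(seed, {
    centers <- matrix(stats::rnorm(n_features * n_clusters, sd = center_spread),
                      nrow = n_features)
    base <- centers[, labels, drop = FALSE] +
      matrix(stats::rnorm(n_features * n, sd = base_noise_sd), nrow = n_features)
    omics <- lapply(seq_len(n_omics), function(l) {
      m <- base + matrix(stats::rnorm(n_features * n, sd = omic_noise_sd[l]),
                         nrow = n_features)
      dimnames(m) <- list(paste0("f", seq_len(n_features)), ids)
      m
    })
    names(omics) <- paste0("omic", seq_len(n_omics))
    structure(list(omics = omics, labels = labels,
                   mask = stats::setNames(rep(list(character(0)), n_omics),
                                          names(omics)),
                   params = list(n_clusters = n_clusters,
                                 samples_per_cluster = samples_per_cluster,
                                 n_features = n_features, n_omics = n_omics,
                                 center_spread = center_spread,
                                 base_noise_sd = base_noise_sd,
                                 omic_noise_sd = omic_noise_sd, seed = seed)),
              class = "nemo_sim")
  })
}

#' Append an uninformative pure-noise omic
#'
#' Adds an omic of i.i.d. Gaussian noise with identical distribution in all
#' clusters, covering every sample — it carries no cluster signal by
#' construction.
#'
#' @param ds A \code{"nemo_sim"} dataset.
#' @param n_features Number of noise features (default 50).
#' @param sd Noise standard deviation (default 1).
#' @param seed RNG seed for the noise draw.
#' @return The dataset with one more omic appended.
#' @export
add_noise_omic <- function(ds, n_features = 50, sd = 1, seed = 1) {
  stopifnot(inherits(ds, "nemo_sim"))
  ids <- names(ds$labels)
  m <- with_seed(seed,
    matrix(stats::rnorm(n_features * length(ids), sd = sd),
           nrow = n_features, dimnames = list(paste0("nf", seq_len(n_features)), ids)))
  nm <- paste0("omic", length(ds$omics) + 1)
  ds$omics[[nm]] <- m
  ds$mask[[nm]] <- character(0)
  ds$params$noise_omic <- list(n_features = n_features, sd = sd, seed = seed)
  ds
}

#' Remove a fraction of samples from one omic
#'
#' Simulates a partial dataset by dropping whole sample columns from one
#' omic: \code{round(theta * n)} samples (half-up) are chosen uniformly at
#' random and removed from that omic only. Retained columns are untouched.
#'
#' @param ds A \code{"nemo_sim"} dataset.
#' @param omic Index or name of the omic to mask (default 2).
#' @param theta Fraction of samples to remove, in \code{[0, 1)}.
#' @param seed RNG seed for the sample draw.
#' @return The dataset with the omic reduced and \code{mask} recording the
#'   removed sample IDs. Errors if masking would leave some sample pair with
#'   no shared omic.
#' @export
mask_partial <- function(ds, omic = 2, theta, seed = 1) {
  stopifnot(inherits(ds, "nemo_sim"))
  if (theta < 0 || theta >= 1) stop_param("theta must be in [0, 1)")
  if (theta == 0) return(ds)
  x <- ds$omics[[omic]]
  n <- ncol(x)
  n_drop <- floor(theta * n + 0.5)
  if (n_drop == 0) return(ds)
  if (n_drop >= n) stop_param("theta removes every sample from the omic")
  drop_ids <- with_seed(seed, sample(colnames(x), n_drop))
  ds$omics[[omic]] <- x[, setdiff(colnames(x), drop_ids), drop = FALSE]
  ds$mask[[omic]] <- sort(drop_ids)
  pair_coverage(lapply(ds$omics, colnames), names(ds$labels))
  ds
}

#' @export
print.nemo_sim <- function(x, ...) {
  cat(sprintf("Simulated multi-omic dataset: %d clusters x %d samples, %d omics\n",
              x$params$n_clusters,
              x$params$samples_per_cluster * x$params$n_clusters,
              length(x$omics)))
  for (nm in names(x$omics)) {
    cat(sprintf("  %s: %d features x %d samples%s\n", nm,
                nrow(x$omics[[nm]]), ncol(x$omics[[nm]]),
                if (length(x$mask[[nm]])) sprintf(" (%d masked)", length(x$mask[[nm]])) else ""))
  }
  invisible(x)
}

#' Missingness sweep: clustering accuracy as a function of theta
#'
#' Runs the full generate / mask / cluster / score protocol over a grid of
#' missingness fractions. For each of \code{n_datasets} independently
#' generated datasets and each \code{theta}, \code{n_repeats} random masks
#' are drawn, the masked dataset is clustered, and the adjusted Rand index
#' against the generating labels is recorded.
#'
#' @param thetas Missingness fractions (default \code{seq(0, 0.8, 0.2)}).
#' @param n_datasets Independent datasets per setting (default 10).
#' @param n_repeats Random masks per dataset and theta (default 10).
#' @param noise_omic Append an uninformative third omic (default
#'   \code{FALSE}).
#' @param n_clusters_known Pass the generating cluster count to
#'   \code{\link{nemo}} — fixing both the partition size and the
#'   neighbourhood size \code{k = n_l / n_clusters} (default \code{TRUE}).
#' @param masked_omic Which omic loses samples (default 2).
#' @param seed Master seed; dataset, mask and clustering seeds are derived
#'   from it deterministically.
#' @param ... Passed to \code{\link{nemo_simulate}} (cluster count, sizes,
#'   spreads, noise).
#' @return Data frame with columns \code{theta}, \code{mean_ari},
#'   \code{sd_ari}, \code{n_runs}.
#' @export
theta_sweep <- function(thetas = seq(0, 0.8, by = 0.2), n_datasets = 10,
                        n_repeats = 10, noise_omic = FALSE,
                        n_clusters_known = TRUE, masked_omic = 2,
                        seed = 1, ...) {
  if (any(thetas < 0 | thetas > 0.9)) stop_param("thetas must lie in [0, 0.9]")
  sim_args <- list(...)
  res <- lapply(thetas, function(th) {
    aris <- numeric(0)
    for (d in seq_len(n_datasets)) {
      ds <- do.call(nemo_simulate,
                    c(list(seed = derive_seed(seed, 1, d)), sim_args))
      if (noise_omic) ds <- add_noise_omic(ds, seed = derive_seed(seed, 2, d))
      nc <- if (n_clusters_known) ds$params$n_clusters else NULL
      for (r in seq_len(n_repeats)) {
        masked <- mask_partial(ds, omic = masked_omic, theta = th,
                               seed = derive_seed(seed, 3, d, r))
        fit <- nemo(masked$omics, n_clusters = nc,
                    seed = derive_seed(seed, 4, d, r))
        aris <- c(aris, adjusted_rand_index(fit$labels, masked$labels))
      }
    }
    data.frame(theta = th, mean_ari = mean(aris), sd_ari = stats::sd(aris),
               n_runs = length(aris))
  })
  do.call(rbind, res)
}
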