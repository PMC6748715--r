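#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement between two clusterings, corrected for chance
#' agreement under the hypergeometric model: 1 for identical partitions (up
#' to relabeling), about 0 for independent ones.
#'
#' @param a,b Cluster assignments over the same samples: factors or vectors.
#'   If both are named, they are aligned by name and must cover the same
#'   sample set.
#' @return The adjusted Rand index, a number \code{<= 1}.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop_input("the two assignments cover different sample sets")
    b <- b[names(a)]
  }
  if (length(a) != length(b))
    stop_input("assignments have different lengths and no names to align by")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  npairs <- choose(sum(tab), 2)
  expected <- ai * bj / npairs
  maxindex <- (ai + bj) / 2
  if (maxindex == expected) return(1)  # both partitions trivial
  (nij - expected) / (maxindex - expected)
}

#' Multi-group logrank test of survival differences between clusters
#'
#' Compares right-censored survival across cluster labels with the
#' c-group logrank (Mantel-Haenszel) test, chi-square distributed with
#' \code{c - 1} degrees of freedom under the null.
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicator: 1 = event observed, 0 = censored.
#' @param labels Cluster assignment, same length/samples as \code{time}. If
#'   all three are named they are aligned by name.
#' @return List with \code{statistic}, \code{df} and \code{p_value}.
#' @export
logrank_test <- function(time, event, labels) {
  if (!is.null(names(time)) && !is.null(names(labels))) {
    if (!setequal(names(time), names(labels)))
      stop_input("survival records and labels cover different samples")
    labels <- labels[names(time)]
    if (!is.null(names(event))) event <- event[names(time)]
  }
  if (any(time < 0)) stop_input("survival times must be nonnegative")
  if (!all(event %in% c(0, 1))) stop_input("event must be 0 (censored) or 1")
  g <- factor(labels)
  if (nlevels(g) < 2) stop_input("need at least 2 non-empty groups")
  if (sum(event) < 1) stop_input("need at least one observed event")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- length(sd_$n) - 1
  list(statistic = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE))
}

enrichment_statistic <- function(param, labels, type) {
  if (type == "discrete") {
    tab <- table(param, labels)
    suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  } else {
    unname(stats::kruskal.test(param, g = factor(labels))$statistic)
  }
}

#' Permutation-based enrichment of clinical parameters in clusters
#'
#' Tests each clinical parameter for association with the cluster labels —
#' chi-square test of independence for discrete parameters, Kruskal-Wallis
#' for numeric ones. Because the asymptotic chi-square approximation of both
#' statistics overstates significance on clustered cohorts, p-values are
#' estimated empirically: cluster labels are permuted \code{n_perm} times
#' with the parameter fixed, and the empirical p-value is
#' \code{(1 + #permutations with statistic >= observed) / (1 + n_perm)}
#' (add-one corrected, so it is never 0 and never below
#' \code{1/(n_perm + 1)}).
#'
#' @param clinical Data frame of per-sample parameters; row names (or a
#'   \code{sample_id} column) identify samples. Character/factor/logical
#'   columns are treated as discrete, numeric columns as numeric; override
#'   with \code{types}.
#' @param labels Named cluster assignment covering the clinical samples.
#' @param types Optional character vector (\code{"discrete"} or
#'   \code{"numeric"}) named by parameter.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return Data frame with one row per tested parameter: \code{parameter},
#'   \code{type}, \code{statistic}, \code{p_value}, \code{n_used},
#'   \code{n_perm}. Constant parameters are skipped with a warning.
#' @export
empirical_enrichment <- function(clinical, labels, types = NULL,
                                 n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop_param("n_perm must be >= 1")
  if ("sample_id" %in% names(clinical)) {
    rownames(clinical) <- clinical$sample_id
    clinical$sample_id <- NULL
  }
  ids <- rownames(clinical)
  if (is.null(names(labels)) || is.null(ids)) {
    if (nrow(clinical) != length(labels))
      stop_input("clinical table and labels differ in size and carry no sample IDs")
  } else {
    keep <- intersect(ids, names(labels))
    if (length(keep) < 2) stop_input("clinical table and labels share too few samples")
    clinical <- clinical[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  out <- vector("list", ncol(clinical))
  for (j in seq_len(ncol(clinical))) {
    pname <- names(clinical)[j]
    x <- clinical[[j]]
    type <- if (!is.null(types) && pname %in% names(types)) types[[pname]]
            else if (is.numeric(x)) "numeric" else "discrete"
    ok <- !is.na(x)
    xo <- x[ok]; lo <- labels[ok]
    if (length(unique(xo)) < 2) {
      warning(sprintf("parameter '%s' is constant; skipped", pname))
      next
    }
    obs <- enrichment_statistic(xo, lo, type)
    exceed <- with_seed(derive_seed(seed, j), {
      sum(vapply(seq_len(n_perm), function(p) {
        enrichment_statistic(xo, sample(lo), type) >= obs
      }, logical(1)))
    })
    out[[j]] <- data.frame(parameter = pname, type = type,
                           statistic = obs,
                           p_value = (1 + exceed) / (1 + n_perm),
                           n_used = length(xo), n_perm = n_perm,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(parameter = character(), type = character(),
                      statistic = numeric(), p_value = numeric(),
                      n_used = integer(), n_perm = integer())
  rownames(res) <- NULL
  res
}
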