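#' Ordered union of sample IDs across omics
#'
#' Samples are ordered by first appearance across the omics in input order;
#' every matrix is re-indexed to this ordering before integration.
#'
#' @param omics List of omic matrices with sample IDs as column names.
#' @return Character vector of unique sample IDs.
#' @export
union_sample_ids <- function(omics) {
  ids <- unlist(lapply(omics, colnames), use.names = FALSE)
  if (is.null(ids)) stop_input("omics must carry sample IDs as column names")
  unique(ids)
}

#' Per-pair omic coverage
#'
#' Counts, for every sample pair, the number of omics in which both samples
#' were measured. Integration of partial data requires every pair to share at
#' least one omic; this holds in particular whenever one omic covers the
#' whole cohort.
#'
#' @param sample_sets List with one character vector of sample IDs per omic.
#' @param union_ids Ordered union of IDs; computed if missing.
#' @return Symmetric integer matrix of coverage counts (diagonal = number of
#'   omics covering each sample). Raises a precondition error naming an
#'   uncovered pair if one exists.
#' @export
pair_coverage <- function(sample_sets, union_ids = NULL) {
  if (length(sample_sets) == 0) stop_input("no omics supplied")
  if (is.null(union_ids)) union_ids <- unique(unlist(sample_sets, use.names = FALSE))
  n <- length(union_ids)
  cov <- matrix(0L, n, n, dimnames = list(union_ids, union_ids))
  for (ids in sample_sets) {
    member <- as.integer(union_ids %in% ids)
    cov <- cov + outer(member, member)
  }
  off <- cov
  diag(off) <- 1L
  if (any(off == 0L)) {
    bad <- which(off == 0L, arr.ind = TRUE)[1, ]
    stop_precondition(sprintf(
      "samples '%s' and '%s' share no omic; every sample pair must be measured together in at least one omic",
      union_ids[bad[1]], union_ids[bad[2]]))
  }
  cov
}

#' Average relative similarity over omics (full data)
#'
#' With every omic covering the same samples, the integrated network is the
#' plain entrywise mean of the per-omic relative-similarity matrices. Each
#' relative-similarity matrix is a sum of random-walk transition
#' distributions, so the average is a mixture of those distributions.
#'
#' @param rs_list List of relative-similarity matrices over identical sample
#'   sets and ordering.
#' @return The averaged matrix, with an integer \code{"coverage"} attribute
#'   (constant at the number of omics).
#' @export
integrate_full <- function(rs_list) {
  if (length(rs_list) == 0) stop_input("no relative-similarity matrices supplied")
  ref <- colnames(rs_list[[1]])
  for (rs in rs_list) {
    if (!identical(colnames(rs), ref))
      stop_input("all relative-similarity matrices must cover identical samples in identical order; use integrate_partial for partial data")
  }
  ars <- Reduce(`+`, rs_list) / length(rs_list)
  cov <- matrix(length(rs_list), nrow(ars), ncol(ars), dimnames = dimnames(ars))
  structure(ars, coverage = cov)
}

#' Average relative similarity over observed omics (partial data)
#'
#' Each entry is averaged only over the omics in which both samples of the
#' pair were measured, so samples missing entire omics participate without
#' imputation.
#'
#' @param rs_list List of relative-similarity matrices, each indexed by its
#'   own omic's sample IDs (dimnames required).
#' @param union_ids Ordered union of sample IDs; defaults to first-appearance
#'   order across the matrices.
#' @return Integrated matrix over \code{union_ids} with a \code{"coverage"}
#'   attribute counting contributing omics per pair.
#' @export
integrate_partial <- function(rs_list, union_ids = NULL) {
  if (length(rs_list) == 0) stop_input("no relative-similarity matrices supplied")
  sets <- lapply(rs_list, colnames)
  if (any(vapply(sets, is.null, logical(1))))
    stop_input("every relative-similarity matrix needs sample IDs as dimnames")
  if (is.null(union_ids)) union_ids <- unique(unlist(sets, use.names = FALSE))
  cov <- pair_coverage(sets, union_ids)
  n <- length(union_ids)
  acc <- matrix(0, n, n, dimnames = list(union_ids, union_ids))
  for (rs in rs_list) {
    pos <- match(colnames(rs), union_ids)
    acc[pos, pos] <- acc[pos, pos] + rs
  }
  denom <- cov
  diag(denom) <- 1L   # diagonal is structurally zero; avoid 0/0
  ars <- acc / denom
  diag(ars) <- 0
  structure(ars, coverage = cov)
}
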