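#' Read an omic matrix from delimited text
#'
#' Expects features in rows and samples in columns: first row sample IDs,
#' first column feature IDs. The delimiter is auto-detected between tab and
#' comma unless forced.
#'
#' @param path Path to the file.
#' @param sep Delimiter; \code{NULL} (default) auto-detects.
#' @return Numeric matrix with feature row names and sample column names.
#' @export
read_omic_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_input(sprintf("%s: need a feature-ID column plus at least one sample", path))
  feat <- as.character(df[[1]])
  ids <- colnames(df)[-1]
  if (anyDuplicated(ids))
    stop_input(sprintf("%s: duplicate sample IDs: %s", path,
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    num <- matrix(suppressWarnings(as.numeric(m)), nrow = nrow(m))
    bad <- which(is.na(num), arr.ind = TRUE)
    ctx <- if (length(bad)) sprintf(" (first at feature '%s', sample '%s')",
                                    feat[bad[1, 1]], ids[bad[1, 2]]) else ""
    stop_input(sprintf("%s: non-numeric entries%s", path, ctx))
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_input(sprintf(
      "%s: missing value at feature '%s', sample '%s'; partial data means whole-sample omic absence — drop the sample's column instead of writing NA",
      path, feat[bad[1]], ids[bad[2]]))
  }
  if (nrow(m) == 0) stop_input(sprintf("%s: empty matrix", path))
  rownames(m) <- feat
  m
}

#' Write an omic matrix as delimited text
#'
#' Inverse of \code{\link{read_omic_table}}: features in rows, header row of
#' sample IDs, first column of feature IDs.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param sep Delimiter (default tab).
#' @export
write_omic_table <- function(x, path, sep = "\t") {
  df <- data.frame(feature = rownames(x) %||% paste0("f", seq_len(nrow(x))),
                   x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster assignment
#'
#' Writes a two-column TSV (\code{sample_id}, \code{cluster}). Clusters are
#' renumbered 1..c contiguously in order of first appearance so output label
#' values are stable regardless of internal numbering.
#'
#' @param labels A \code{"nemo"} fit or a named cluster vector.
#' @param path Output path.
#' @export
write_assignment <- function(labels, path) {
  if (inherits(labels, "nemo")) labels <- labels$labels
  if (is.null(names(labels))) stop_input("labels must be named by sample ID")
  relab <- match(labels, unique(labels))
  df <- data.frame(sample_id = names(labels), cluster = relab,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cluster assignment written by \code{\link{write_assignment}}
#' @param path Path to the two-column TSV.
#' @return Named integer vector of cluster labels.
#' @export
read_assignment <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$cluster), df$sample_id)
}

#' Read a survival table
#'
#' Expects a delimited file with columns \code{sample_id}, \code{time},
#' \code{event} (header required; extra columns ignored).
#'
#' @param path Path to the file.
#' @return Data frame with those three columns; \code{time} nonnegative,
#'   \code{event} in \{0, 1\}.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop_input(sprintf("%s: survival table needs columns %s", path,
                       paste(need, collapse = ", ")))
  if (any(df$time < 0)) stop_input("survival times must be nonnegative")
  if (!all(df$event %in% c(0, 1))) stop_input("event must be 0 or 1")
  df[, need]
}

#' Read a clinical-parameter table
#'
#' Delimited file with a \code{sample_id} column; remaining columns are the
#' parameters. Columns that parse as numbers are treated as numeric
#' parameters, everything else as discrete — override per column with the
#' \code{types} argument of \code{\link{empirical_enrichment}}.
#'
#' @param path Path to the file.
#' @return Data frame with sample IDs as row names.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop_input(sprintf("%s: clinical table needs a sample_id column", path))
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  df
}
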