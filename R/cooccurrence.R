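#' Filter samples by read depth and ASVs by prevalence
#'
#' Samples whose total read count falls below `min_reads_per_sample` are
#' removed first; then ASVs present (count > 0) in fewer than
#' `ceiling(min_prevalence_fraction * n_remaining_samples)` samples are
#' removed. The fractional prevalence threshold is converted to an integer
#' minimum with `ceiling()`, mirroring the usual "at least x% of samples"
#' reading of amplicon-survey filters.
#'
#' @param table A [sample_table()].
#' @param min_reads_per_sample Minimum total reads a sample must have.
#' @param min_prevalence_fraction Fraction of (retained) samples an ASV must
#'   appear in, in `[0, 1]`.
#' @return A new, filtered [sample_table()]; the input is untouched.
#' @examples
#' m <- matrix(c(50, 50, 3000, 3000, 4000, 3000), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("S", 1:3), c("A", "B")))
#' filter_table(sample_table(m), min_reads_per_sample = 5000,
#'              min_prevalence_fraction = 0)
#' @export
filter_table <- function(table, min_reads_per_sample = 0,
                         min_prevalence_fraction = 0) {
  stopifnot(inherits(table, "sample_table"))
  if (min_reads_per_sample < 0 || min_prevalence_fraction < 0 ||
      min_prevalence_fraction > 1) {
    stop("thresholds must be non-negative (prevalence fraction in [0, 1])",
         call. = FALSE)
  }
  keep_s <- rowSums(table$counts) >= min_reads_per_sample
  if (!any(keep_s)) stop("empty result: no sample passes the read-depth filter", call. = FALSE)
  counts <- table$counts[keep_s, , drop = FALSE]
  min_n <- ceiling(min_prevalence_fraction * nrow(counts))
  keep_a <- colSums(counts > 0) >= min_n
  if (!any(keep_a)) stop("empty result: no ASV passes the prevalence filter", call. = FALSE)
  counts <- counts[, keep_a, drop = FALSE]
  sample_table(
    counts,
    metadata = if (!is.null(table$metadata)) table$metadata[keep_s, , drop = FALSE],
    labels = if (!is.null(table$labels)) table$labels[keep_s]
  )
}

#' Binarize a count table to presence/absence
#'
#' @param table A [sample_table()].
#' @return A binary samples x ASVs matrix; entry 1 iff the count is > 0.
#' @export
to_presence <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  m <- (table$counts > 0) * 1
  dimnames(m) <- dimnames(table$counts)
  m
}

#' Build the ASV-ASV co-occurrence matrix
#'
#' Two ASVs co-occur when they are detected in the same sample. `X[i, j]`
#' counts the samples containing both `i` and `j` (i != j); the diagonal is
#' set to 0 as self-pairs carry no relational signal. `occ[i]` is the number
#' of samples containing ASV `i`.
#'
#' @param presence Binary samples x ASVs matrix (see [to_presence()]).
#' @param binarize If `TRUE`, reduce `X` to 0/1 (pair co-occurred at least
#'   once) instead of the default graded shared-sample counts. The graded
#'   counts are what the weighting function of the embedding objective
#'   expects; the binary variant is kept for sensitivity analyses.
#' @return An object of class `cooccurrence`: list with symmetric integer
#'   matrix `X`, occurrence vector `occ`, and `n_samples`.
#' @export
build_cooccurrence <- function(presence, binarize = FALSE) {
  if (!is.matrix(presence) || !all(presence %in% c(0, 1))) {
    stop("`presence` must be a binary samples x ASVs matrix", call. = FALSE)
  }
  X <- crossprod(presence)
  diag(X) <- 0
  if (binarize) X <- (X > 0) * 1
  occ <- colSums(presence)
  structure(
    list(X = X, occ = occ, n_samples = nrow(presence)),
    class = "cooccurrence"
  )
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat(sprintf("<cooccurrence> %d ASVs over %d samples, %d co-occurring pairs\n",
              ncol(x$X), x$n_samples, sum(x$X[upper.tri(x$X)] > 0)))
  invisible(x)
}

#' Conditional co-occurrence probability P(j | i)
#'
#' The probability of co-occurrence of ASV `j` with ASV `i`, defined as the
#' number of samples containing both divided by the number of occurrences of
#' `i`. Note `P(j|i) != P(i|j)` in general.
#'
#' @param cooc A [build_cooccurrence()] result.
#' @param i,j ASV indices or IDs.
#' @return A single probability.
#' @export
cooccurrence_probability <- function(cooc, i, j) {
  stopifnot(inherits(cooc, "cooccurrence"))
  if (is.character(i)) i <- match(i, colnames(cooc$X))
  if (is.character(j)) j <- match(j, colnames(cooc$X))
  if (is.na(i) || is.na(j)) stop("unknown ASV", call. = FALSE)
  if (cooc$occ[i] == 0) {
    stop("P(j|i) undefined: ASV ", colnames(cooc$X)[i], " never occurs", call. = FALSE)
  }
  unname(cooc$X[i, j] / cooc$occ[i])
}

#' Serialize a co-occurrence matrix as sparse triplets
#'
#' Writes the upper triangle of nonzero co-occurrence counts as a TSV with
#' columns `asv_i`, `asv_j`, `count`, preceded by the per-ASV occurrence
#' counts (rows with `asv_j` = `"."` hold `occ`).
#'
#' @param cooc A `cooccurrence` object.
#' @param path File path.
#' @return `path` invisibly; `read_cooccurrence()` returns a `cooccurrence`.
#' @export
write_cooccurrence <- function(cooc, path) {
  stopifnot(inherits(cooc, "cooccurrence"))
  up <- which(upper.tri(cooc$X) & cooc$X > 0, arr.ind = TRUE)
  ids <- colnames(cooc$X)
  df <- rbind(
    data.frame(asv_i = ids, asv_j = ".", count = cooc$occ),
    data.frame(asv_i = ids[up[, 1]], asv_j = ids[up[, 2]], count = cooc$X[up])
  )
  attr_line <- sprintf("# n_samples=%d", cooc$n_samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cooccurrence
#' @export
read_cooccurrence <- function(path) {
  first <- readLines(path, n = 1)
  n_samples <- as.integer(sub("# n_samples=", "", first, fixed = TRUE))
  df <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
  occ_rows <- df$asv_j == "."
  ids <- df$asv_i[occ_rows]
  occ <- stats::setNames(df$count[occ_rows], ids)
  X <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  tr <- df[!occ_rows, , drop = FALSE]
  X[cbind(match(tr$asv_i, ids), match(tr$asv_j, ids))] <- tr$count
  X[cbind(match(tr$asv_j, ids), match(tr$asv_i, ids))] <- tr$count
  structure(list(X = X, occ = occ, n_samples = n_samples), class = "cooccurrence")
}
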