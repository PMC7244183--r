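#' Inverse hyperbolic sine normalization
#'
#' Replaces every count `x` by `asinh(x) = log(x + sqrt(x^2 + 1))`, a
#' log-like variance stabilizer that mimics `log(2x)` for large `x` but is
#' defined (and equal to 0) at 0, so zero counts need no pseudocount.
#'
#' @param table A [sample_table()] with non-negative counts.
#' @return A [sample_table()] with real-valued normalized entries; metadata
#'   and labels are carried through.
#' @export
asinh_normalize <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  if (any(table$counts < 0)) stop("counts must be non-negative", call. = FALSE)
  out <- table
  out$counts <- asinh(table$counts)
  out
}

#' Match query ASVs to embedding ASVs by sequence identity
#'
#' Each query sequence is locally aligned (Smith-Waterman, match +1,
#' mismatch -2) against candidate reference sequences sharing at least one
#' exact k-mer (default k = 11). The best hit is kept when its percent
#' identity (matches / alignment length) reaches `min_identity` and its
#' Karlin-Altschul e-value (K = 0.41, lambda = 1.28, search space = query
#' length x total reference length) is below `max_evalue`. Ties are broken
#' by higher identity, then lower e-value, then lexicographically smallest
#' reference ID. Queries with no admissible hit are dropped.
#'
#' The identity threshold is a closed bound (`identity >= min_identity`), so
#' `min_identity = 100` admits exact matches.
#'
#' @param query,reference Named character vectors of nucleotide sequences
#'   (see [read_fasta()]).
#' @param min_identity Percent identity threshold in `[0, 100]`; 99 is the
#'   usual cross-study ASV matching threshold (97 and 100 are common
#'   sensitivity settings).
#' @param max_evalue E-value ceiling (strict bound), default `1e-29`.
#' @param k Prescreen k-mer length.
#' @return An object of class `asv_match`: a tibble with columns
#'   `query_id`, `reference_id`, `identity`, `evalue`, with the unmatched
#'   query IDs in `attr(, "dropped")`.
#' @export
match_asvs <- function(query, reference, min_identity = 99,
                       max_evalue = 1e-29, k = 11) {
  if (length(query) == 0 || length(reference) == 0) {
    stop("query and reference sets must be non-empty", call. = FALSE)
  }
  stopifnot(!is.null(names(query)), !is.null(names(reference)))
  ref_kmers <- lapply(reference, seq_kmers, k = k)
  total_ref_len <- sum(nchar(reference))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  rows <- vector("list", length(query))
  for (qi in seq_along(query)) {
    qk <- seq_kmers(query[[qi]], k)
    cand <- which(vapply(ref_kmers, function(rk) any(qk %in% rk), logical(1)))
    if (length(cand) == 0) next
    aln <- Biostrings::pairwiseAlignment(
      pattern = rep(Biostrings::DNAStringSet(query[qi]), length(cand)),
      subject = Biostrings::DNAStringSet(reference[cand]),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2
    )
    identity <- 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    evalue <- 0.41 * nchar(query[[qi]]) * total_ref_len *
      exp(-1.28 * Biostrings::score(aln))
    ok <- identity >= min_identity & evalue < max_evalue
    if (!any(ok)) next
    ord <- order(-identity[ok], evalue[ok], names(reference)[cand][ok])[1]
    hit <- which(ok)[ord]
    rows[[qi]] <- tibble::tibble(
      query_id = names(query)[qi],
      reference_id = names(reference)[cand][hit],
      identity = identity[hit], evalue = evalue[hit]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(query_id = character(), reference_id = character(),
                          identity = numeric(), evalue = numeric())
  }
  attr(out, "dropped") <- setdiff(names(query), out$query_id)
  class(out) <- c("asv_match", class(out))
  out
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1))
}

#' Project a sample table into property space
#'
#' Computes the dot product between the (normalized) sample-by-ASV table and
#' the ASV-by-property transformation matrix: a sample's value for property
#' `p` is the abundance-weighted sum of the property-`p` values of its ASVs.
#' When a [match_asvs()] result is supplied, query columns are first mapped
#' to their matched embedding ASVs; unmatched query columns are dropped, and
#' embedding ASVs absent from the query contribute zero.
#'
#' @param table A [sample_table()], normally after [asinh_normalize()]
#'   (projection of raw counts is possible but not the default analysis
#'   path).
#' @param embedding An [asv_embedding()].
#' @param match Optional `asv_match`; `NULL` matches columns to embedding
#'   rows by identical ASV ID.
#' @return A samples x properties matrix of class `property_table`.
#' @export
project_to_properties <- function(table, embedding, match = NULL) {
  stopifnot(inherits(table, "sample_table"), inherits(embedding, "asv_embedding"))
  if (is.null(match)) {
    common <- intersect(asv_ids(table), rownames(embedding))
    qcols <- common
    erows <- common
  } else {
    keep <- match$query_id %in% asv_ids(table) &
      match$reference_id %in% rownames(embedding)
    qcols <- match$query_id[keep]
    erows <- match$reference_id[keep]
  }
  if (length(qcols) == 0) {
    stop("no overlap with embedding space: zero matched ASVs", call. = FALSE)
  }
  vals <- table$counts[, qcols, drop = FALSE] %*%
    unclass(embedding)[erows, , drop = FALSE]
  property_table(vals)
}

property_table <- function(vals) {
  stopifnot(is.matrix(vals), !is.null(rownames(vals)), !is.null(colnames(vals)))
  if (any(!is.finite(vals))) stop("property table contains non-finite values", call. = FALSE)
  class(vals) <- c("property_table", class(matrix()))
  vals
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table> %d samples x %d properties\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Convert a property table to a tibble
#'
#' @param x A `property_table`.
#' @param ... Unused.
#' @return A tibble with a `sample_id` column and one column per property.
#' @method as_tibble property_table
#' @export
as_tibble.property_table <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "sample_id")
}

#' Read / write a property table as TSV
#'
#' Samples as rows (first column `sample_id`), property IDs in the header;
#' values round-trip at full double precision.
#'
#' @param props A `property_table` (see [project_to_properties()]).
#' @param path File path.
#' @return `read_property_table()` returns a `property_table`.
#' @export
write_property_table <- function(props, path) {
  m <- unclass(props)
  vals <- matrix(sprintf("%.17g", m), nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(sample_id = rownames(m), vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_property_table
#' @export
read_property_table <- function(path) {
  property_table(read_id_matrix(path, what = "property table"))
}

#' PCA projection of a sample table
#'
#' Centers the (normalized) counts and projects samples onto the top right
#' singular vectors, the classical variance-maximizing ordination used as a
#' baseline against the co-occurrence embedding. The rotation matrix
#' (ASV x component) is retained so components can be interpreted exactly
#' like embedding properties.
#'
#' @param table A [sample_table()], normally after [asinh_normalize()].
#' @param n_components Number of components, at most
#'   `min(n_samples - 1, n_asvs)`.
#' @return An object of class `pca_projection`: list with `scores` (a
#'   `property_table` with columns `PC1..PCk`), `rotation`, `center` and
#'   `sdev`.
#' @export
pca_transform <- function(table, n_components) {
  stopifnot(inherits(table, "sample_table"))
  n_max <- min(nrow(table$counts) - 1L, ncol(table$counts))
  if (n_components > n_max) {
    stop(sprintf("n_components = %d exceeds min(samples - 1, ASVs) = %d",
                 n_components, n_max), call. = FALSE)
  }
  pc <- stats::prcomp(table$counts, center = TRUE, scale. = FALSE,
                      rank. = n_components)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  structure(
    list(scores = property_table(scores),
         rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
         center = pc$center, sdev = pc$sdev),
    class = "pca_projection"
  )
}

#' @export
print.pca_projection <- function(x, ...) {
  pct <- 100 * sum(x$sdev[seq_len(ncol(x$scores))]^2) / sum(x$sdev^2)
  cat(sprintf("<pca_projection> %d samples x %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores), pct))
  invisible(x)
}
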