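#' Construct a sample-by-ASV table
#'
#' The central container of the package: a numeric matrix of read counts with
#' samples as rows and amplicon sequence variants (ASVs) as columns, plus
#' optional per-sample metadata covariates and a binary phenotype label
#' (1 = case).
#'
#' @param counts Numeric matrix, samples x ASVs, with unique row and column
#'   names. All entries must be finite and non-negative. Integer counts are
#'   expected on input tables; real values are allowed so that normalized
#'   tables remain first-class `sample_table` objects.
#' @param metadata Optional data frame of per-sample numeric covariates.
#'   Must have one row per sample, in the same order as `rownames(counts)`
#'   (or a `sample_id` column used to align).
#' @param labels Optional per-sample phenotype, a vector of 0/1 values named
#'   by sample ID (or unnamed, in sample order). 1 is the case class.
#' @return An object of class `sample_table`.
#' @examples
#' m <- matrix(c(0, 3, 1, 2, 0, 5), nrow = 2,
#'             dimnames = list(c("S1", "S2"), c("A", "B", "C")))
#' sample_table(m)
#' @export
sample_table <- function(counts, metadata = NULL, labels = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have sample row names and ASV column names", call. = FALSE)
  }
  dup_s <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_s) > 0) {
    stop("duplicate sample ID: ", dup_s[1], call. = FALSE)
  }
  dup_a <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_a) > 0) {
    stop("duplicate ASV ID: ", dup_a[1], call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0)
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(counts)) + 1
    j <- ((bad[1] - 1) %/% nrow(counts)) + 1
    stop(sprintf(
      "invalid count %s at row %d (sample '%s'), column %d (ASV '%s')",
      format(counts[bad[1]]), i, rownames(counts)[i], j, colnames(counts)[j]
    ), call. = FALSE)
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if ("sample_id" %in% names(metadata)) {
      if (!all(rownames(counts) %in% metadata$sample_id)) {
        stop("metadata is missing samples present in the count table", call. = FALSE)
      }
      metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
      metadata$sample_id <- NULL
      rownames(metadata) <- rownames(counts)
    } else if (nrow(metadata) != nrow(counts)) {
      stop("metadata must have one row per sample", call. = FALSE)
    }
  }
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      if (!all(rownames(counts) %in% names(labels))) {
        stop("labels must cover every sample", call. = FALSE)
      }
      labels <- labels[rownames(counts)]
    } else if (length(labels) != nrow(counts)) {
      stop("labels must cover every sample", call. = FALSE)
    }
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) {
      stop("labels must be 0/1 (1 = case)", call. = FALSE)
    }
    names(labels) <- rownames(counts)
  }
  structure(
    list(counts = counts, metadata = metadata, labels = labels),
    class = "sample_table"
  )
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf(
    "<sample_table> %d samples x %d ASVs%s%s\n",
    nrow(x$counts), ncol(x$counts),
    if (!is.null(x$metadata)) sprintf(", %d covariates", ncol(x$metadata)) else "",
    if (!is.null(x$labels)) sprintf(", labels (%d cases)", sum(x$labels)) else ""
  ))
  invisible(x)
}

#' @export
dim.sample_table <- function(x) dim(x$counts)

#' Sample and ASV identifiers of a table
#'
#' @param table A [sample_table()].
#' @return Character vector of IDs.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
asv_ids <- function(table) colnames(table$counts)

#' Convert a sample table to a long tibble
#'
#' @param x A [sample_table()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `asv_id`, `count`.
#' @method as_tibble sample_table
#' @export
as_tibble.sample_table <- function(x, ...) {
  tibble::as_tibble(x$counts, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "asv_id", values_to = "count")
}

#' Read a sample-by-ASV count table
#'
#' Reads TSV (tab-separated, header row, first column holds IDs) or BIOM
#' tables into a validated [sample_table()]. For TSV input the `orientation`
#' argument states whether rows are samples or ASVs; the returned table is
#' always samples-as-rows, input ordering preserved. BIOM files carry their
#' own convention (rows are observations, i.e. ASVs), so `orientation` is
#' ignored for them.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom"`.
#' @param orientation `"samples_as_rows"` (default) or `"asvs_as_rows"`.
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path,
                              format = c("tsv", "biom"),
                              orientation = c("samples_as_rows", "asvs_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))   # observations (ASVs) x samples
    counts <- t(m)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("table must have an ID column and at least one data column", call. = FALSE)
    ids <- as.character(df[[1]])
    dup <- ids[duplicated(ids)]
    if (length(dup) > 0) stop("duplicate ID in first column: ", dup[1], call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    dupc <- colnames(m)[duplicated(colnames(m))]
    if (length(dupc) > 0) stop("duplicate ID in header: ", dupc[1], call. = FALSE)
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))))[1]
      i <- ((bad - 1) %% nrow(m)) + 1
      j <- ((bad - 1) %/% nrow(m)) + 1
      stop(sprintf("non-numeric count at data row %d, column '%s'", i, colnames(m)[j]),
           call. = FALSE)
    }
    rownames(m) <- ids
    neg <- which(m < 0)
    if (length(neg) > 0) {
      i <- ((neg[1] - 1) %% nrow(m)) + 1
      j <- ((neg[1] - 1) %/% nrow(m)) + 1
      stop(sprintf("negative count %s at row '%s', column '%s'",
                   format(m[neg[1]]), rownames(m)[i], colnames(m)[j]),
           call. = FALSE)
    }
    counts <- if (orientation == "asvs_as_rows") t(m) else m
  }
  sample_table(counts)
}

#' Write a sample table as TSV
#'
#' @param table A [sample_table()].
#' @param path Output path. Samples are rows; the first column (`sample_id`)
#'   holds sample IDs and the header holds ASV IDs.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  write_id_matrix(table$counts, path, id_name = "sample_id")
}

write_id_matrix <- function(m, path, id_name) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_id_matrix <- function(path, what = "matrix") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("empty ", what, " file: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header))) {
    stop(sprintf("%s file '%s': row %d has %d fields but header has %d",
                 what, path, which(nfield != length(header))[1],
                 nfield[nfield != length(header)][1], length(header)),
         call. = FALSE)
  }
  ids <- vapply(body, `[`, character(1), 1)
  vals <- vapply(body, function(r) as.numeric(r[-1]), numeric(length(header) - 1))
  m <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = length(header) - 1)
  dimnames(m) <- list(ids, header[-1])
  m
}

#' Read a FASTA file of ASV representative sequences
#'
#' IDs are the first whitespace-delimited token of each header line;
#' sequences are uppercased. Duplicate IDs and empty sequences are errors.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector (ASV ID -> sequence over A/C/G/T/N).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate FASTA ID: ", dup[1], call. = FALSE)
  seqs <- toupper(as.character(ss))
  empty <- ids[nchar(seqs) == 0]
  if (length(empty) > 0) stop("empty sequence for FASTA record: ", empty[1], call. = FALSE)
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Construct an ASV-by-property embedding matrix
#'
#' The learned transformation matrix: each row places one ASV in property
#' space. Multiplying a (normalized) sample-by-ASV table by this matrix
#' yields per-sample property profiles.
#'
#' @param values Numeric matrix, ASVs x properties, finite entries, with ASV
#'   row names. Property columns are labelled `P1..Pk` if unnamed.
#' @return A matrix of class `asv_embedding`.
#' @export
asv_embedding <- function(values) {
  if (!is.matrix(values) || !is.numeric(values) || nrow(values) == 0 || ncol(values) == 0) {
    stop("embedding must be a non-empty numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values))) stop("embedding must have ASV row names", call. = FALSE)
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0) stop("duplicate ASV ID in embedding: ", dup[1], call. = FALSE)
  if (any(!is.finite(values))) stop("embedding contains non-finite values", call. = FALSE)
  if (is.null(colnames(values))) colnames(values) <- paste0("P", seq_len(ncol(values)))
  class(values) <- c("asv_embedding", class(matrix()))
  values
}

#' @export
print.asv_embedding <- function(x, ...) {
  cat(sprintf("<asv_embedding> %d ASVs x %d properties\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Write / read an embedding matrix as TSV
#'
#' Round-trips at full double precision: the first column holds ASV IDs, the
#' header holds property IDs, values are written with 17 significant digits.
#'
#' @param embedding An [asv_embedding()].
#' @param path File path.
#' @return `write_embedding()` returns `path` invisibly; `read_embedding()`
#'   returns an [asv_embedding()].
#' @export
write_embedding <- function(embedding, path) {
  embedding <- asv_embedding(unclass(embedding))
  m <- matrix(sprintf("%.17g", unclass(embedding)), nrow = nrow(embedding),
              dimnames = dimnames(embedding))
  df <- data.frame(asv_id = rownames(embedding), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  asv_embedding(read_id_matrix(path, what = "embedding"))
}

#' Read / write a binary ASV-by-pathway presence table
#'
#' Rows are ASVs, columns metabolic pathway IDs (e.g. `ko00983`); entries
#' are 1 when the pathway is present in the ASV's nearest sequenced genome
#' and 0 otherwise.
#'
#' @param path File path (TSV; first column ASV IDs, header pathway IDs).
#' @param pathways Binary ASV x pathway matrix with dimnames.
#' @return `read_pathway_table()` returns a binary matrix.
#' @export
read_pathway_table <- function(path) {
  m <- read_id_matrix(path, what = "pathway table")
  validate_pathway_table(m)
}

#' @rdname read_pathway_table
#' @export
write_pathway_table <- function(pathways, path) {
  validate_pathway_table(pathways)
  write_id_matrix(pathways, path, id_name = "asv_id")
}

validate_pathway_table <- function(m) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    stop("pathway table must be a matrix with ASV row names and pathway column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("pathway table has duplicate IDs", call. = FALSE)
  }
  if (!all(m %in% c(0, 1))) stop("pathway table entries must be 0/1", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Read per-sample phenotype labels (and optional patient grouping)
#'
#' Expects a TSV with a `sample_id` column, a binary `label` column
#' (1 = case) and optionally a `patient_id` column used for grouped
#' train/test splits.
#'
#' @param path File path.
#' @return A tibble with columns `sample_id`, `label` and, when present,
#'   `patient_id`.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("labels file must have 'sample_id' and 'label' columns", call. = FALSE)
  }
  if (!all(df$label %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  tibble::as_tibble(df)
}
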