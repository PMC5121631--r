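#' Construct and validate an OTU count table
#'
#' An OTU table is a non-negative integer matrix of sequence read counts with
#' samples as rows and OTUs as columns, carried around as a classed matrix so
#' that every stage can validate its input cheaply. Row and column names are
#' the sample and OTU identifiers and must be unique.
#'
#' @param counts numeric matrix of non-negative integers.
#' @param sample_ids,otu_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return an `otu_table`: an integer matrix with class `c("otu_table",
#'   "matrix", "array")`.
#' @examples
#' x <- otu_table(matrix(c(5L, 0L, 0L, 3L), 2, 2,
#'                dimnames = list(c("s1", "s2"), c("OTU1", "OTU2"))))
#' x
#' @export
otu_table <- function(counts, sample_ids = NULL, otu_ids = NULL) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(otu_ids)) colnames(counts) <- otu_ids
  storage.mode(counts) <- "integer"
  x <- structure(counts, class = c("otu_table", "matrix", "array"))
  validate_otu_table(x)
  x
}

#' Validate an OTU table
#'
#' Checks identifier uniqueness, non-negative integral counts and presence of
#' dimnames; called by every consumer of an `otu_table`.
#'
#' @param x object to validate.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_otu_table <- function(x) {
  if (!inherits(x, "otu_table")) stop("not an otu_table")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("otu_table must carry sample and OTU identifiers")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x)) stop("otu_table contains missing counts")
  if (any(x < 0)) stop("otu_table contains negative counts")
  invisible(x)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs, %d reads\n",
              nrow(x), ncol(x), sum(x)))
  cat(sprintf("  non-zero cells: %d (%.1f%%)\n", sum(x > 0),
              100 * mean(x > 0)))
  invisible(x)
}

#' Read an OTU count table from a tab-separated file
#'
#' The expected layout is one header row and one leading identifier column:
#' with `orientation = "samples_rows"` (the community-ecology convention and
#' the default) rows are samples and columns OTUs, first header cell
#' `sample_id`; `"otus_rows"` reads the transposed layout (first header cell
#' `otu_id`) and transposes it back.
#'
#' @param path file path.
#' @param orientation `"samples_rows"` or `"otus_rows"`.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, orientation = c("samples_rows", "otus_rows")) {
  orientation <- match.arg(orientation)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    stop("duplicate identifiers in header of ", path, ": ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, colClasses = "character",
                   fill = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]]))
    stop("duplicate identifiers in first column of ", path, ": ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num)) {
    bad <- vals[is.na(num)][1]
    stop("non-numeric count '", bad, "' in ", path)
  }
  if (any(num < 0)) stop("negative count in ", path)
  if (any(num != round(num))) stop("non-integer count in ", path)
  m <- matrix(as.integer(num), nrow = nrow(vals),
              dimnames = list(df[[1]], colnames(df)[-1]))
  if (orientation == "otus_rows") m <- t(m)
  otu_table(m)
}

#' Write an OTU count table to a tab-separated file
#'
#' Writes the canonical interchange layout read back by [read_otu_table]:
#' UTF-8 TSV, no quoting, `.` decimal, leading column headed `sample_id`.
#' The write is byte-stable: writing, reading and re-writing a table yields
#' an identical file.
#'
#' @param x an [otu_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  validate_otu_table(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(r) paste(r, collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Restrict an OTU table to the samples described in a metadata table
#'
#' Returns the table restricted to samples present in both inputs, re-ordered
#' to follow the metadata; samples present in only one input are dropped with
#' a message. The operation is idempotent.
#'
#' @param x an [otu_table].
#' @param meta a metadata data frame (see [read_metadata]).
#' @return an [otu_table] with rows in metadata order.
#' @export
align_samples <- function(x, meta) {
  validate_otu_table(x)
  validate_metadata(meta)
  keep <- intersect(meta$sample_id, rownames(x))
  if (length(keep) == 0) stop("no samples shared between table and metadata")
  dropped <- c(setdiff(rownames(x), keep), setdiff(meta$sample_id, keep))
  if (length(dropped) > 0)
    message("align_samples: dropping ", length(dropped), " unmatched sample(s): ",
            paste(dropped, collapse = ", "))
  otu_table(unclass(x)[keep, , drop = FALSE])
}
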