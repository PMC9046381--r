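#' Construct an OTU table
#'
#' An OTU table is a numeric samples-by-taxa matrix with unique row (sample)
#' and column (taxon) names. Raw tables hold non-negative integer read
#' counts; normalized tables (e.g. after [tmm_normalize()]) hold non-negative
#' reals and carry `normalized = TRUE`.
#'
#' Samples whose row sums are zero carry no information for any downstream
#' stage and are dropped with a warning.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   dimnames.
#' @param normalized logical flag; `TRUE` marks real-valued normalized
#'   abundances rather than raw counts.
#' @return an `otu_table`: the validated matrix with class `otu_table` and
#'   attribute `normalized`.
#' @export
otu_table <- function(counts, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample rownames and taxon colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d all-zero sample(s): %s", sum(empty),
                    paste(rownames(counts)[empty], collapse = ", ")))
    counts <- counts[!empty, , drop = FALSE]
  }
  if (nrow(counts) == 0) stop("no non-empty samples remain")
  structure(counts, class = c("otu_table", class(counts)),
            normalized = isTRUE(normalized))
}

as_otu_matrix <- function(table) {
  if (inherits(table, "otu_table")) return(unclass_otu(table))
  if (is.matrix(table) && is.numeric(table)) return(table)
  stop("expected an otu_table or a numeric matrix")
}

unclass_otu <- function(x) {
  attr(x, "normalized") <- NULL
  class(x) <- setdiff(class(x), "otu_table")
  x
}

is_normalized <- function(table) isTRUE(attr(table, "normalized"))

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d taxa (%s)\n", nrow(x), ncol(x),
              if (is_normalized(x)) "normalized" else "raw counts"))
  cat(sprintf("  total reads: %s; median sample depth: %s\n",
              format(sum(x), big.mark = ","),
              format(stats::median(rowSums(x)))))
  invisible(x)
}

#' Read an OTU table from TSV
#'
#' Reads a tab-separated table with one header row and one leading id
#' column. The file may be oriented either way; `rows_are` states what the
#' file's rows hold and the result is always samples-by-taxa.
#'
#' @param path path to a TSV file.
#' @param rows_are `"samples"` (default) or `"taxa"`.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, rows_are = c("samples", "taxa")) {
  rows_are <- match.arg(rows_are)
  raw <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                   ids[bad[1, 1]], colnames(raw)[-1][bad[1, 2]], path))
    }
    stop("non-numeric cells in ", path)
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (rows_are == "taxa") mat <- t(mat)
  tbl <- otu_table(mat)
  ca_log("read_otu_table: %d samples x %d taxa from %s",
         nrow(tbl), ncol(tbl), path)
  tbl
}

#' Write an OTU table to TSV
#'
#' Inverse of [read_otu_table()]: cell values round-trip exactly.
#'
#' @param table an [otu_table()] or numeric matrix (samples x taxa).
#' @param path output file path.
#' @param id_column header for the leading sample-id column.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, id_column = "sample_id") {
  mat <- as_otu_matrix(table)
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                   rownames(mat), as.data.frame(mat))
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to within-sample relative abundances
#'
#' @param table an [otu_table()] or matrix.
#' @return matrix whose rows sum to 1.
#' @export
relative_abundance <- function(table) {
  mat <- as_otu_matrix(table)
  tot <- rowSums(mat)
  if (any(tot == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(mat)[tot == 0], collapse = ", "))
  }
  sweep(mat, 1, tot, "/")
}
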