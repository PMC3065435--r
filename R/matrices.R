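#' Labelled matrix containers
#'
#' The pipeline works on two labelled matrix types: a binary *map matrix*
#' (mRNAs in rows, miRNAs in columns; entry \[j, i\] is 1 iff miRNA i is
#' predicted to target mRNA j) and an *expression matrix* (entities in rows,
#' conditions in columns, entries are log2 fold-changes against a reference
#' condition). Both are plain base matrices with unique dimnames, validated
#' on construction; everything downstream of them returns tibbles.
#'
#' @param values numeric matrix.
#' @param row_ids,col_ids character labels; default taken from `dimnames`.
#' @return the validated matrix with class `map_matrix` or `expr_matrix`
#'   prepended.
#' @name matrices
NULL

#' @rdname matrices
#' @export
map_matrix <- function(values, row_ids = rownames(values),
                       col_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(row_ids) || is.null(col_ids)) {
    abort("a map matrix needs both row (mRNA) and column (miRNA) labels")
  }
  dimnames(values) <- list(row_ids, col_ids)
  validate_labels(values)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    abort("a map matrix must have at least one row and one column")
  }
  if (!all(values %in% c(0, 1))) {
    abort("map matrix entries must all be 0 or 1")
  }
  storage.mode(values) <- "double"
  class(values) <- c("map_matrix", class(values))
  values
}

#' @rdname matrices
#' @export
expression_matrix <- function(values, row_ids = rownames(values),
                              col_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(row_ids)) abort("an expression matrix needs row labels")
  if (is.null(col_ids)) col_ids <- paste0("cond_", seq_len(ncol(values)))
  dimnames(values) <- list(row_ids, col_ids)
  validate_labels(values)
  if (ncol(values) < 1L) abort("at least one condition column is required")
  if (!all(is.finite(values))) {
    abort("expression matrix entries must be finite")
  }
  storage.mode(values) <- "double"
  class(values) <- c("expr_matrix", class(values))
  values
}

validate_labels <- function(m) {
  rn <- rownames(m)
  cn <- colnames(m)
  if (anyDuplicated(rn)) {
    abort(paste0("duplicate row labels: ",
                 paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  }
  if (anyDuplicated(cn)) {
    abort(paste0("duplicate column labels: ",
                 paste(unique(cn[duplicated(cn)]), collapse = ", ")))
  }
  invisible(m)
}

#' Read a labelled matrix from tab-separated text
#'
#' The file dialect is a header row of column labels, a first column of row
#' labels, and a corner cell that is present but ignored. `kind = "map"`
#' additionally validates that every entry is 0 or 1.
#'
#' @param path file path.
#' @param kind `"map"` or `"expression"`.
#' @return a [map_matrix()] or [expression_matrix()].
#' @export
read_matrix <- function(path, kind = c("map", "expression")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort(paste0("no data rows in ", path))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    abort(paste0("ragged rows in ", path, ": widths ",
                 paste(unique(widths), collapse = ", ")))
  }
  header <- cells[[1L]]
  col_ids <- header[-1L]
  body <- cells[-1L]
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  # coercion NAs are caught below with a clearer message
  vals <- suppressWarnings(
    vapply(body, function(x) as.numeric(x[-1L]), numeric(length(col_ids))))
  vals <- matrix(vals, ncol = length(col_ids), byrow = TRUE,
                 dimnames = list(row_ids, col_ids))
  if (anyNA(vals)) abort(paste0("non-numeric entries in ", path))
  if (kind == "map") map_matrix(vals) else expression_matrix(vals)
}

#' Write a labelled matrix as tab-separated text
#'
#' Inverse of [read_matrix()]: values are written at full precision so that
#' a read/write round trip reproduces the matrix bit-exactly.
#'
#' @param x a labelled matrix.
#' @param path output file path.
#' @param corner label for the ignored corner cell.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, corner = "id") {
  header <- paste(c(corner, colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(j) {
    paste(c(rownames(x)[j],
            format(unclass(x)[j, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Transpose a map matrix, swapping the mRNA and miRNA roles
#'
#' The miRNA-side clustering uses the same machinery on the transposed map
#' (miRNAs in rows, their binary target profiles in columns).
#'
#' @param map a [map_matrix()].
#' @return a [map_matrix()] of shape X x Y.
#' @export
transpose_map <- function(map) {
  stopifnot(inherits(map, "map_matrix"))
  map_matrix(t(unclass(map)))
}

#' Restrict a map matrix and an expression matrix to shared entities
#'
#' Guided clustering and the association step need the map and expression
#' inputs row-aligned (or map-column/expression-row aligned for the miRNA
#' side). Identifiers absent from either input are dropped with a warning.
#'
#' @param map a [map_matrix()].
#' @param expr an [expression_matrix()].
#' @param axis `"rows"` to align map rows (mRNAs) with `expr` rows,
#'   `"cols"` to align map columns (miRNAs) with `expr` rows.
#' @return a list with elements `map` and `expr`, both restricted to the
#'   intersection of identifiers, in the map's order.
#' @export
align_entities <- function(map, expr, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  map_ids <- if (axis == "rows") rownames(map) else colnames(map)
  shared <- intersect(map_ids, rownames(expr))
  if (length(shared) == 0L) {
    abort("no shared identifiers between map and expression inputs")
  }
  dropped <- c(setdiff(map_ids, shared), setdiff(rownames(expr), shared))
  if (length(dropped) > 0L) {
    warn(paste0(length(dropped), " identifier(s) dropped during alignment: ",
                paste(utils::head(dropped, 10L), collapse = ", "),
                if (length(dropped) > 10L) ", ..." else ""))
  }
  map_out <- if (axis == "rows") {
    map_matrix(unclass(map)[shared, , drop = FALSE])
  } else {
    map_matrix(unclass(map)[, shared, drop = FALSE])
  }
  expr_out <- expression_matrix(unclass(expr)[shared, , drop = FALSE])
  list(map = map_out, expr = expr_out)
}

#' @export
print.map_matrix <- function(x, ...) {
  cat(sprintf("miRNA-mRNA map matrix: %d mRNAs x %d miRNAs, density %.3f\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d entities x %d conditions\n",
              nrow(x), ncol(x)))
  invisible(x)
}
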