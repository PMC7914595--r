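#' Construct an expression table
#'
#' An expression table holds one organism's measurements of one expression
#' variable from one source dataset, as a named vector of non-negative values
#' keyed by gene identifier.  Units are per-dataset arbitrary; downstream
#' analysis consumes only the relative order of values.
#'
#' @param values Named numeric vector, gene ID -> value.  `NA` marks a
#'   missing measurement.
#' @param organism Organism identifier.
#' @param variable One of `r paste(SIXVP_VARIABLES, collapse = ", ")`.
#' @param source_id Free-text label for the source dataset.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(values, organism, variable, source_id = "unnamed") {
  variable <- match_variable(variable)
  if (length(values) < 1L) {
    stop("an expression table needs at least one gene", call. = FALSE)
  }
  if (is.null(names(values)) || anyNA(names(values)) || any(names(values) == "")) {
    stop("values must be named by gene ID", call. = FALSE)
  }
  if (anyDuplicated(names(values))) {
    stop("gene IDs must be unique within a table", call. = FALSE)
  }
  nm <- names(values)
  values <- as.double(values)
  names(values) <- nm
  if (any(is.infinite(values))) {
    stop("values must be finite or NA", call. = FALSE)
  }
  structure(
    list(
      organism = as.character(organism),
      variable = variable,
      source_id = as.character(source_id),
      values = values
    ),
    names = c("organism", "variable", "source_id", "values"),
    class = "expression_table"
  )
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf(
    "expression_table: %s / %s [%s], %d genes (%d missing)\n",
    x$organism, x$variable, x$source_id,
    length(x$values), sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
length.expression_table <- function(x) length(x$values)

#' Read a two-column expression table from a TSV file
#'
#' Expects tab-delimited lines of `gene-ID<TAB>value` with an optional header
#' line.  Non-numeric values become missing (`NA`).  Duplicate gene IDs are
#' collapsed by a configurable rule (default: arithmetic mean, with a
#' warning), which also serves as the isoform-grouping rule when several
#' isoform rows share a collapsed gene name.
#'
#' @param path Path to the file.
#' @param organism,variable,source_id Metadata; see [expression_table()].
#' @param collapse How to collapse duplicate gene IDs: `"mean"`, `"max"` or
#'   `"sum"`.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, organism, variable,
                                  source_id = basename(path),
                                  collapse = c("mean", "max", "sum")) {
  collapse <- match.arg(collapse)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop(sprintf("empty expression file: %s", path), call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop(sprintf(
      "malformed expression file %s: line %d has %d fields (expected 2)",
      path, which(nf != 2L)[1L], nf[which(nf != 2L)[1L]]
    ), call. = FALSE)
  }
  genes <- vapply(fields, `[[`, character(1), 1L)
  raw <- vapply(fields, `[[`, character(1), 2L)
  vals <- suppressWarnings(as.numeric(raw))
  ## a non-numeric second field on line 1 is taken as a header
  if (is.na(vals[1L]) && !raw[1L] %in% c("NA", "NaN", "")) {
    genes <- genes[-1L]
    vals <- vals[-1L]
  }
  if (length(genes) == 0L) {
    stop(sprintf("no data rows in expression file: %s", path), call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    warning(sprintf(
      "%d duplicate gene IDs in %s collapsed by %s",
      sum(duplicated(genes)), path, collapse
    ), call. = FALSE)
    fun <- switch(collapse, mean = mean, max = max, sum = sum)
    agg <- tapply(vals, genes, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else fun(v)
    })
    vals <- as.numeric(agg)
    genes <- names(agg)
  }
  names(vals) <- genes
  expression_table(vals, organism = organism, variable = variable,
                   source_id = source_id)
}

#' Write an expression table as two-column TSV
#'
#' @param table An [expression_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  vals <- ifelse(is.na(table$values), "NA",
                 formatC(table$values, format = "g", digits = 15))
  writeLines(paste(names(table$values), vals, sep = "\t"), con = path)
  invisible(path)
}

#' Assemble a six-variable matrix from per-variable tables
#'
#' Builds the genes x variables matrix that downstream ranking, clustering
#' and regression consume.  The columns follow the fixed order
#' TR, RS, RA, TLRi, PS, PA; genes missing from a variable's table get `NA`
#' in that column.
#'
#' @param tables Named list of [expression_table()]s; names (or table
#'   `variable` fields) must identify the six variables.  Variables may be
#'   absent (their column is all-`NA`), but at least one is required.
#' @param organism Organism label; defaults to the first table's.
#' @return A numeric matrix of class `sixvp_matrix` with gene rownames,
#'   columns `SIXVP_VARIABLES`, and an `organism` attribute.
#' @export
six_variable_matrix <- function(tables, organism = NULL) {
  stopifnot(length(tables) >= 1L)
  vars <- vapply(tables, function(t) t$variable, character(1))
  if (anyDuplicated(vars)) {
    stop("at most one table per variable", call. = FALSE)
  }
  if (is.null(organism)) organism <- tables[[1L]]$organism
  genes <- sort(unique(unlist(lapply(tables, function(t) names(t$values)))))
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(SIXVP_VARIABLES),
              dimnames = list(genes, SIXVP_VARIABLES))
  for (t in tables) {
    m[names(t$values), t$variable] <- t$values
  }
  structure(m, organism = organism, class = c("sixvp_matrix", "matrix", "array"))
}

#' @export
print.sixvp_matrix <- function(x, ...) {
  cat(sprintf("sixvp_matrix: %s, %d genes x %d variables (%.1f%% missing)\n",
              attr(x, "organism") %||% "?", nrow(x), ncol(x),
              100 * mean(is.na(x))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_sixvp_matrix <- function(m, organism = attr(m, "organism") %||% "unknown") {
  stopifnot(is.matrix(m), identical(colnames(m), SIXVP_VARIABLES))
  structure(m, organism = organism, class = c("sixvp_matrix", "matrix", "array"))
}

#' Read and write six-variable matrices as TSV
#'
#' The on-disk form is a TSV with a `gene` column followed by the six
#' variable columns in canonical order; `NA` marks missing cells.
#'
#' @param path File path.
#' @param organism Organism label for the returned matrix.
#' @return For `read_sixvp_matrix`, a `sixvp_matrix`.
#' @export
read_sixvp_matrix <- function(path, organism = "unknown") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(colnames(df), c("gene", SIXVP_VARIABLES))) {
    stop("expected columns: gene, ", paste(SIXVP_VARIABLES, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, SIXVP_VARIABLES])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  as_sixvp_matrix(m, organism)
}

#' @rdname read_sixvp_matrix
#' @param matrix A `sixvp_matrix`.
#' @export
write_sixvp_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
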