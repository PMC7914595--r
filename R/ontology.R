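#' Construct a GO graph from term and edge lists
#'
#' The graph is a DAG of ontology terms with child-to-parent `is_a` (and,
#' optionally, `part_of`) links, split across the three GO namespaces.  Roots
#' are the terms without parents in their namespace.
#'
#' @param terms Data frame with columns `id`, `name`, `namespace` (one of
#'   `"BP"`, `"CC"`, `"MF"`).
#' @param parents Named list mapping each term ID to a character vector of
#'   parent term IDs (possibly empty).
#' @return Object of class `go_graph` with elements `terms`, `parents`,
#'   `children`, `roots` and a precomputed `ancestors` list (each term's
#'   ancestor set, self included).
#' @export
go_graph <- function(terms, parents) {
  stopifnot(is.data.frame(terms), all(c("id", "namespace") %in% colnames(terms)))
  if (!"name" %in% colnames(terms)) terms$name <- terms$id
  if (anyDuplicated(terms$id)) stop("duplicate term IDs", call. = FALSE)
  bad <- setdiff(terms$namespace, c("BP", "CC", "MF"))
  if (length(bad)) stop("unknown namespace: ", paste(bad, collapse = ", "), call. = FALSE)
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) {
    p <- intersect(unique(p %||% character(0)), terms$id)
    p
  })
  ## topological check + ancestor closure
  anc <- topo_ancestors(terms$id, parents)
  children <- invert_edges(parents)
  roots <- terms$id[lengths(parents) == 0L]
  structure(
    list(terms = terms[, c("id", "name", "namespace")], parents = parents,
         children = children, roots = roots, ancestors = anc),
    class = "go_graph"
  )
}

## Kahn topological order; errors on cycles, then closes ancestor sets.
topo_ancestors <- function(ids, parents) {
  n_parents <- lengths(parents)
  children <- invert_edges(parents)
  indeg <- n_parents
  queue <- ids[indeg == 0L]
  order <- character(0)
  indeg_map <- stats::setNames(indeg, ids)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]] %||% character(0)) {
      indeg_map[[ch]] <- indeg_map[[ch]] - 1L
      if (indeg_map[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(ids)) {
    cyc <- setdiff(ids, order)
    stop("cycle detected in ontology involving: ",
         paste(utils::head(cyc, 5L), collapse = ", "), call. = FALSE)
  }
  anc <- vector("list", length(ids))
  names(anc) <- ids
  for (v in order) {
    up <- parents[[v]]
    anc[[v]] <- unique(c(v, unlist(anc[up], use.names = FALSE)))
  }
  anc
}

invert_edges <- function(parents) {
  out <- lapply(parents, function(x) character(0))
  for (child in names(parents)) {
    for (p in parents[[child]]) out[[p]] <- c(out[[p]], child)
  }
  out
}

#' @export
print.go_graph <- function(x, ...) {
  cat(sprintf("go_graph: %d terms (%s), %d roots\n", nrow(x$terms),
              paste(sprintf("%s=%d", names(table(x$terms$namespace)),
                            table(x$terms$namespace)), collapse = ", "),
              length(x$roots)))
  invisible(x)
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas (`id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`), skips obsolete terms, and returns a validated
#' DAG.  By GOSemSim-style convention `part_of` edges are treated as parent
#' links for propagation; switch off with `part_of = FALSE`.
#'
#' @param path Path to the OBO file.
#' @param part_of Treat `relationship: part_of` as a parent edge.
#' @return A [go_graph()].
#' @export
read_obo <- function(path, part_of = TRUE) {
  lines <- readLines(path, warn = FALSE)
  ns_map <- c(biological_process = "BP", cellular_component = "CC",
              molecular_function = "MF", BP = "BP", CC = "CC", MF = "MF")
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas in ", path, call. = FALSE)
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list()
  for (i in seq_along(stanza_starts)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    ## stop the stanza at the next [Typedef]/[Term] header within bounds
    hdr <- grep("^\\[", block)
    if (length(hdr) > 1L) block <- block[seq_len(hdr[2L] - 1L)]
    get1 <- function(key) {
      m <- grep(paste0("^", key, ": "), block, value = TRUE)
      if (length(m) == 0L) return(NA_character_)
      sub(paste0("^", key, ": "), "", m[1L])
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    ns_raw <- get1("namespace")
    ns <- if (!is.na(ns_raw) && ns_raw %in% names(ns_map)) ns_map[[ns_raw]] else NA_character_
    if (is.na(ns)) next
    isa <- sub(" !.*$", "", sub("^is_a: ", "", grep("^is_a: ", block, value = TRUE)))
    po <- character(0)
    if (part_of) {
      rel <- grep("^relationship: part_of ", block, value = TRUE)
      po <- sub(" !.*$", "", sub("^relationship: part_of ", "", rel))
    }
    ids <- c(ids, id)
    nm <- get1("name")
    nms <- c(nms, if (is.na(nm)) id else nm)
    nss <- c(nss, ns)
    parents[[id]] <- unique(c(isa, po))
  }
  go_graph(data.frame(id = ids, name = nms, namespace = nss,
                      stringsAsFactors = FALSE),
           parents)
}

#' Write a go_graph as a minimal OBO 1.2 file
#'
#' Emits `[Term]` stanzas with `id`, `name`, `namespace` and `is_a` lines;
#' all parent links are written as `is_a` (sufficient for round-tripping
#' graphs built by this package).
#'
#' @param graph A [go_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "go_graph"))
  ns_long <- c(BP = "biological_process", CC = "cellular_component",
               MF = "molecular_function")
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    out <- c(out, "[Term]",
             paste0("id: ", id),
             paste0("name: ", graph$terms$name[i]),
             paste0("namespace: ", ns_long[[graph$terms$namespace[i]]]),
             paste0("is_a: ", graph$parents[[id]]),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Build an annotation set over a GO graph
#'
#' @param direct Named list, term ID -> character vector of gene IDs directly
#'   annotated to the term.
#' @param graph A [go_graph()]; terms absent from it are rejected.
#' @return Object of class `annotation_set` with `direct`, `propagated`
#'   (closed under ancestor propagation) and `universe` (all annotated genes).
#' @export
annotation_set <- function(direct, graph) {
  stopifnot(inherits(graph, "go_graph"))
  unknown <- setdiff(names(direct), graph$terms$id)
  if (length(unknown)) {
    stop("unknown term IDs: ", paste(utils::head(unknown, 5L), collapse = ", "),
         call. = FALSE)
  }
  direct <- lapply(direct, function(g) sort(unique(as.character(g))))
  propagated <- stats::setNames(
    vector("list", nrow(graph$terms)), graph$terms$id)
  for (t in graph$terms$id) propagated[[t]] <- character(0)
  for (t in names(direct)) {
    for (a in graph$ancestors[[t]]) {
      propagated[[a]] <- c(propagated[[a]], direct[[t]])
    }
  }
  propagated <- lapply(propagated, function(g) sort(unique(g)))
  structure(
    list(direct = direct, propagated = propagated,
         universe = sort(unique(unlist(direct, use.names = FALSE) %||% character(0)))),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes, %d directly annotated terms\n",
              length(x$universe), length(x$direct)))
  invisible(x)
}

#' Read gene-to-term annotations
#'
#' Accepts either a plain two-column TSV (`gene-ID<TAB>term-ID`) or GAF 2.x
#' (17-column, `!` comment lines; gene from column 2, term from column 5,
#' rows with a `NOT` qualifier dropped).  Unknown terms are skipped with a
#' warning, or rejected in strict mode.
#'
#' @param path Path to the annotation file.
#' @param graph A [go_graph()].
#' @param strict Error (rather than warn) on term IDs absent from `graph`.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, graph, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0L) {
    return(annotation_set(list(), graph))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf >= 15L)) {            # GAF 2.x
    qual <- vapply(fields, `[[`, character(1), 4L)
    keep <- !grepl("NOT", qual, fixed = TRUE)
    genes <- vapply(fields, `[[`, character(1), 2L)[keep]
    terms <- vapply(fields, `[[`, character(1), 5L)[keep]
  } else if (all(nf == 2L)) {      # plain two-column
    genes <- vapply(fields, `[[`, character(1), 1L)
    terms <- vapply(fields, `[[`, character(1), 2L)
  } else {
    stop("annotation file must be 2-column TSV or GAF 2.x: ", path, call. = FALSE)
  }
  known <- terms %in% graph$terms$id
  if (any(!known)) {
    msg <- sprintf("%d annotations to unknown terms in %s", sum(!known), path)
    if (strict) stop(msg, call. = FALSE)
    warning(msg, ", skipped", call. = FALSE)
    genes <- genes[known]; terms <- terms[known]
  }
  annotation_set(split(genes, terms), graph)
}

#' Write annotations as two-column TSV
#'
#' @param annotations An [annotation_set()].
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  rows <- unlist(lapply(names(annotations$direct), function(t) {
    paste(annotations$direct[[t]], t, sep = "\t")
  }), use.names = FALSE)
  writeLines(rows %||% character(0), path)
  invisible(path)
}
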