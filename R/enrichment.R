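#' One-sided hypergeometric over-representation p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance that a random
#' cluster of `n` genes drawn from a universe of `N` would contain at least
#' `k` of the `K` genes carrying the term.
#'
#' @param k Observed overlap between cluster and term.
#' @param K Term size in the universe.
#' @param n Cluster size.
#' @param N Universe size.
#' @return The upper-tail p-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone-enforced and capped at 1, in the
#' input order.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric GO enrichment of gene clusters
#'
#' Tests every BP and CC term of the annotation set for over-representation
#' in each cluster, against the universe of clustered genes (the background
#' against which clusters were formed).  Terms with zero overlap are kept
#' with p = 1 so the FDR denominator is reproducible; adjustment is applied
#' per namespace across all clusters.
#'
#' @param clusters Named list of gene ID vectors.
#' @param annotations An [annotation_set()] (propagated sets are used).
#' @param graph The [go_graph()] the annotations refer to.
#' @param namespaces Ontology namespaces to test.
#' @param universe Background gene set; defaults to the union of the
#'   clustered genes.
#' @return Data frame of `enrichment_record`s: `cluster_id`, `term_id`,
#'   `namespace`, `k`, `K`, `n`, `N`, `p`, `p_adj`.
#' @export
enrich_clusters <- function(clusters, annotations, graph,
                            namespaces = c("BP", "CC"), universe = NULL) {
  stopifnot(inherits(annotations, "annotation_set"), inherits(graph, "go_graph"))
  if (is.null(universe)) universe <- sort(unique(unlist(clusters)))
  universe <- intersect(universe, annotations$universe)
  N <- length(universe)
  if (N == 0L) stop("empty annotated universe", call. = FALSE)
  terms <- graph$terms$id[graph$terms$namespace %in% namespaces]
  term_genes <- lapply(annotations$propagated[terms],
                       function(g) intersect(g, universe))
  keep <- lengths(term_genes) >= 1L
  terms <- terms[keep]
  term_genes <- term_genes[keep]
  ns <- stats::setNames(graph$terms$namespace, graph$terms$id)[terms]
  rows <- list()
  for (cl in names(clusters)) {
    cg <- intersect(clusters[[cl]], universe)
    n <- length(cg)
    if (n == 0L) next
    k <- vapply(term_genes, function(tg) length(intersect(tg, cg)), integer(1))
    K <- lengths(term_genes)
    p <- mapply(hypergeom_test, k = k, K = K,
                MoreArgs = list(n = n, N = N))
    rows[[cl]] <- data.frame(cluster_id = cl, term_id = terms,
                             namespace = unname(ns), k = unname(k),
                             K = unname(K), n = n, N = N, p = unname(p),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(cluster_id = character(0), term_id = character(0),
                      namespace = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0)))
  }
  out$p_adj <- NA_real_
  for (nsx in unique(out$namespace)) {
    sel <- out$namespace == nsx
    out$p_adj[sel] <- bh_fdr(out$p[sel])
  }
  rownames(out) <- NULL
  out
}

#' Filter enrichment records by adjusted significance
#'
#' Keeps records with `p_adj` strictly below `alpha` (a record at exactly
#' `alpha` is dropped).
#'
#' @param records Data frame from [enrich_clusters()].
#' @param alpha Significance cutoff on the adjusted p-value.
#' @return The filtered data frame.
#' @export
significant_terms <- function(records, alpha = 0.001) {
  stopifnot("p_adj" %in% colnames(records))
  out <- records[!is.na(records$p_adj) & records$p_adj < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse semantically redundant enriched terms
#'
#' Greedy de-duplication: repeatedly take the remaining record with the
#' lowest adjusted p-value (ties broken by term ID) and discard every other
#' remaining record whose semantic similarity to it exceeds `threshold`.
#'
#' @param records Data frame with `term_id` and `p_adj` columns.
#' @param simrel Symmetric similarity matrix covering all record terms
#'   (e.g. from [simrel_matrix()]).
#' @param threshold Similarity above which two terms are redundant.
#' @return The surviving representative records.
#' @export
dedupe_by_similarity <- function(records, simrel, threshold = 0.7) {
  stopifnot(all(c("term_id", "p_adj") %in% colnames(records)))
  if (nrow(records) == 0L) return(records)
  missing <- setdiff(records$term_id, rownames(simrel))
  if (length(missing)) {
    stop("terms missing from similarity matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  remaining <- records[order(records$p_adj, records$term_id), , drop = FALSE]
  keep <- list()
  while (nrow(remaining) > 0L) {
    top <- remaining[1L, , drop = FALSE]
    keep[[length(keep) + 1L]] <- top
    sims <- simrel[top$term_id, remaining$term_id]
    remaining <- remaining[!(sims > threshold) &
                             remaining$term_id != top$term_id, , drop = FALSE]
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}
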