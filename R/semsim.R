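#' Information content of ontology terms
#'
#' For each annotated term, p(t) = |propagated(t)| / |universe| and
#' IC(t) = -ln p(t), computed within each namespace against the full
#' annotated gene universe.  The namespace root has p = 1 and IC = 0; IC
#' grows toward the leaves.
#'
#' @param graph A [go_graph()].
#' @param annotations An [annotation_set()] providing the propagated counts.
#' @return Object of class `ic_table`: data frame with `term_id`,
#'   `namespace`, `n_genes`, `p`, `ic` for every term with at least one
#'   propagated annotation.
#' @export
information_content <- function(graph, annotations) {
  stopifnot(inherits(graph, "go_graph"), inherits(annotations, "annotation_set"))
  if (length(annotations$universe) == 0L) {
    stop("empty annotation universe", call. = FALSE)
  }
  counts <- lengths(annotations$propagated[graph$terms$id])
  keep <- counts > 0L
  p <- counts[keep] / length(annotations$universe)
  out <- data.frame(
    term_id = graph$terms$id[keep],
    namespace = graph$terms$namespace[keep],
    n_genes = unname(counts[keep]),
    p = unname(p),
    ic = -log(unname(p)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$term_id
  class(out) <- c("ic_table", "data.frame")
  out
}

#' Schlicker relevance similarity between two ontology terms
#'
#' Combines Resnik's and Lin's information-content measures: with MICA the
#' common ancestor of maximal IC,
#' SimREL = \[2 IC(MICA) / (IC(t1) + IC(t2))\] x (1 - p(MICA)).
#' The Lin ratio rewards a deep shared ancestor relative to the terms' own
#' depths; the (1 - p) factor discounts shallow, near-root ancestors.  Values
#' range 0 to 1; a term's self-similarity is 1 - p(t).  The DAG may give a
#' pair several maximal ancestors, so all common ancestors are enumerated
#' and the one with maximal IC taken.
#'
#' @param t1,t2 Term IDs (same namespace, both annotated).
#' @param ic An [information_content()] table.
#' @param graph The [go_graph()].
#' @return Similarity in \[0, 1\].
#' @export
sim_rel <- function(t1, t2, ic, graph) {
  for (t in c(t1, t2)) {
    if (!t %in% ic$term_id) stop("term not annotated: ", t, call. = FALSE)
  }
  common <- intersect(graph$ancestors[[t1]], graph$ancestors[[t2]])
  common <- intersect(common, ic$term_id)
  if (length(common) == 0L) {
    stop(sprintf("no common ancestor for %s and %s", t1, t2), call. = FALSE)
  }
  ics <- ic[common, "ic"]
  mica <- common[which.max(ics)]
  denom <- ic[t1, "ic"] + ic[t2, "ic"]
  if (denom == 0) return(0)
  (2 * ic[mica, "ic"] / denom) * (1 - ic[mica, "p"])
}

#' Pairwise SimREL matrix for a term set
#'
#' @param terms Character vector of term IDs (one namespace).
#' @param ic An [information_content()] table.
#' @param graph The [go_graph()].
#' @return Symmetric matrix of SimREL values with term IDs as dimnames.
#' @export
simrel_matrix <- function(terms, ic, graph) {
  m <- length(terms)
  out <- matrix(NA_real_, m, m, dimnames = list(terms, terms))
  for (i in seq_len(m)) {
    for (j in i:m) {
      s <- sim_rel(terms[i], terms[j], ic, graph)
      out[i, j] <- out[j, i] <- s
    }
  }
  out
}

#' Uniqueness of each term in a set
#'
#' u(t) = 1 - mean SimREL of t to every other term of the set: how unlike
#' the rest of the set a term is.  For a single term u = 1.
#'
#' @param simrel A [simrel_matrix()].
#' @return Named numeric vector of uniqueness scores in \[0, 1\].
#' @export
term_uniqueness <- function(simrel) {
  m <- nrow(simrel)
  if (m == 1L) return(stats::setNames(1, rownames(simrel)))
  u <- vapply(seq_len(m), function(i) 1 - mean(simrel[i, -i]), numeric(1))
  stats::setNames(u, rownames(simrel))
}

#' Reduce a redundant term set to representative terms
#'
#' REVIGO-style redundancy reduction: UPGMA (average-linkage) clustering of
#' the terms on the 1 - SimREL distance, cut at the number of clusters
#' maximizing the mean silhouette width over k = 2 ... m - 1; within each
#' cluster the member with the highest uniqueness is kept (the single member
#' of a singleton cluster is kept as-is; uniqueness ties break
#' lexicographically by term ID).
#'
#' @param terms Character vector of term IDs (at least 2).
#' @param simrel A [simrel_matrix()] covering them.
#' @return List: `representatives` (character vector), `k` (chosen cluster
#'   count), `silhouette` (mean widths per tested k), `clusters` (named
#'   integer cluster assignment), `uniqueness`.
#' @export
reduce_redundancy <- function(terms, simrel) {
  stopifnot(length(terms) >= 2L, all(terms %in% rownames(simrel)))
  s <- simrel[terms, terms]
  d <- 1 - s
  diag(d) <- 0
  dd <- stats::as.dist(d)
  if (max(dd) - min(dd) < 1e-12) {
    warning("all pairwise distances identical; falling back to k = 2",
            call. = FALSE)
    hc <- stats::hclust(dd, method = "average")
    cl <- stats::cutree(hc, k = 2L)
    sil <- stats::setNames(NA_real_, "2")
    best_k <- 2L
  } else {
    hc <- stats::hclust(dd, method = "average")
    ks <- 2:(length(terms) - 1L)
    if (length(terms) == 2L) ks <- 2L
    sil <- vapply(ks, function(k) {
      cl <- stats::cutree(hc, k = k)
      if (length(unique(cl)) < 2L) return(NA_real_)
      mean(cluster::silhouette(cl, dd)[, "sil_width"])
    }, numeric(1))
    names(sil) <- as.character(ks)
    best_k <- ks[which.max(sil)]
    cl <- stats::cutree(hc, k = best_k)
  }
  u <- term_uniqueness(s)
  reps <- vapply(sort(unique(cl)), function(k) {
    members <- names(cl)[cl == k]
    members <- members[order(-u[members], members)]
    members[1L]
  }, character(1))
  list(representatives = sort(unname(reps)), k = best_k, silhouette = sil,
       clusters = cl, uniqueness = u)
}
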