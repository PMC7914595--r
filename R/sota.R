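#' Correlation distance between two six-variable profiles
#'
#' d = 1 - Pearson R across the six components, ranging 0 (identical shape)
#' to 2 (mirror-image shape); uncorrelated profiles sit at 1 in expectation.
#' A zero-variance (flat) profile carries no shape information, so its
#' distance to anything is defined as 1, with a warning.
#'
#' @param p1,p2 Numeric vectors of equal length (complete, no `NA`).
#' @return A single distance in \[0, 2\].
#' @export
profile_distance <- function(p1, p2) {
  stopifnot(length(p1) == length(p2), !anyNA(p1), !anyNA(p2))
  if (stats::sd(p1) == 0 || stats::sd(p2) == 0) {
    warning("zero-variance profile: distance set to 1", call. = FALSE)
    return(1)
  }
  1 - stats::cor(p1, p2)
}

## rowwise 1 - cor(x_i, centroid); x complete matrix
dist_to_centroid <- function(x, centroid) {
  if (stats::sd(centroid) == 0) return(rep(1, nrow(x)))
  xc <- x - rowMeans(x)
  cc <- centroid - mean(centroid)
  denom <- sqrt(rowSums(xc^2)) * sqrt(sum(cc^2))
  r <- as.vector(xc %*% cc) / denom
  r[denom == 0] <- 0
  out <- 1 - r
  out[denom == 0] <- 1
  out
}

#' Cluster genes by 6VP shape with a self-organizing tree algorithm
#'
#' Divisive neural-tree clustering: the tree starts as a single cell at the
#' grand centroid and, at each growth cycle, the leaf cell with the highest
#' resource (mean correlation distance of its members to its centroid) is
#' split into two daughter cells.  The members of the split cell are then
#' presented repeatedly, in seeded random order; the daughter cell closest
#' to each gene adapts toward it by the winner learning rate, its sister by
#' the sister rate, and the mother cell by the mother rate, until the
#' relative improvement in mean error falls below `tol` or `max_epochs` is
#' reached.  Growth stops when `target_clusters` leaf cells exist (or no
#' splittable cell remains); a post-pass merges any leaf with fewer than
#' `min_size` members into the leaf with the nearest centroid.
#'
#' @param ranks Complete (imputed) rank matrix; rows = genes.
#' @param target_clusters Number of leaf cells to grow, e.g. 10, 15, 20, 30.
#' @param min_size Minimum cluster size enforced by the merge pass.
#' @param seed Integer seed; gene presentation order is shuffled per epoch
#'   with this generator, making runs reproducible.
#' @param eta_w,eta_m,eta_s Winner / mother / sister learning rates.
#' @param max_epochs,tol Per-cycle convergence controls.
#' @return Object of class `gene_cluster_set`: `level` (the requested
#'   target), `clusters` (named list of gene ID vectors), `centroids`
#'   (cluster x variable matrix), `resource` (per-cluster mean member
#'   distance) and `seed`.
#' @export
sota_cluster <- function(ranks, target_clusters, min_size = 5L, seed = 1L,
                         eta_w = 0.01, eta_m = 0.005, eta_s = 0.001,
                         max_epochs = 1000L, tol = 1e-6) {
  stopifnot(is.matrix(ranks), !anyNA(ranks))
  n <- nrow(ranks)
  if (is.null(rownames(ranks))) rownames(ranks) <- paste0("g", seq_len(n))
  if (target_clusters < 1L) stop("target_clusters must be >= 1", call. = FALSE)
  if (target_clusters > n %/% min_size) {
    stop(sprintf("target_clusters (%d) exceeds n/min_size (%d)",
                 target_clusters, n %/% min_size), call. = FALSE)
  }
  set.seed(seed)
  ## leaves: list of list(centroid, members (integer indices))
  leaves <- list(list(centroid = colMeans(ranks), members = seq_len(n)))
  repeat {
    if (length(leaves) >= target_clusters) break
    res <- vapply(leaves, function(l) {
      if (length(l$members) < 2L) return(-1)
      mean(dist_to_centroid(ranks[l$members, , drop = FALSE], l$centroid))
    }, numeric(1))
    if (all(res <= 0)) break               # nothing heterogeneous left
    split_i <- which.max(res)
    parent <- leaves[[split_i]]
    mem <- parent$members
    x <- ranks[mem, , drop = FALSE]
    c_w <- parent$centroid
    c_s <- parent$centroid
    c_m <- parent$centroid
    err_prev <- Inf
    p <- ncol(x)
    xc <- x - rowMeans(x)                   # centered rows, fixed per cycle
    xn <- sqrt(rowSums(xc^2))
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(length(mem))
      for (i in ord) {
        xi <- x[i, ]
        cw <- c_w - sum(c_w) / p
        cs <- c_s - sum(c_s) / p
        nw <- sqrt(sum(cw * cw)); ns <- sqrt(sum(cs * cs))
        r1 <- if (nw == 0 || xn[i] == 0) 0 else sum(xc[i, ] * cw) / (xn[i] * nw)
        r2 <- if (ns == 0 || xn[i] == 0) 0 else sum(xc[i, ] * cs) / (xn[i] * ns)
        if (r1 >= r2) {
          c_w <- c_w + eta_w * (xi - c_w)
          c_s <- c_s + eta_s * (xi - c_s)
        } else {
          c_s <- c_s + eta_w * (xi - c_s)
          c_w <- c_w + eta_s * (xi - c_w)
        }
        c_m <- c_m + eta_m * (xi - c_m)
      }
      d1 <- dist_to_centroid(x, c_w)
      d2 <- dist_to_centroid(x, c_s)
      err <- mean(pmin(d1, d2))
      if (is.finite(err_prev) &&
          (err_prev - err) / max(err_prev, .Machine$double.eps) < tol) break
      err_prev <- err
    }
    d1 <- dist_to_centroid(x, c_w)
    d2 <- dist_to_centroid(x, c_s)
    to1 <- d1 <= d2
    child1 <- list(centroid = c_w, members = mem[to1])
    child2 <- list(centroid = c_s, members = mem[!to1])
    kids <- Filter(function(l) length(l$members) > 0L, list(child1, child2))
    if (length(kids) < 2L) {
      ## degenerate split (all members identical to one child): freeze leaf
      leaves[[split_i]]$frozen <- TRUE
      next
    }
    leaves <- c(leaves[-split_i], kids)
  }
  ## recompute centroids as member means, then merge undersized leaves
  for (i in seq_along(leaves)) {
    leaves[[i]]$centroid <- colMeans(ranks[leaves[[i]]$members, , drop = FALSE])
  }
  repeat {
    sizes <- vapply(leaves, function(l) length(l$members), integer(1))
    small <- which(sizes < min_size)
    if (length(small) == 0L || length(leaves) == 1L) break
    i <- small[which.min(sizes[small])]
    cents <- t(vapply(leaves, `[[`, numeric(ncol(ranks)), "centroid"))
    d <- dist_to_centroid(cents, leaves[[i]]$centroid)
    d[i] <- Inf
    j <- which.min(d)
    leaves[[j]]$members <- c(leaves[[j]]$members, leaves[[i]]$members)
    leaves[[j]]$centroid <- colMeans(ranks[leaves[[j]]$members, , drop = FALSE])
    leaves <- leaves[-i]
  }
  clusters <- lapply(leaves, function(l) rownames(ranks)[sort(l$members)])
  names(clusters) <- paste0("C", seq_along(clusters))
  centroids <- t(vapply(leaves, `[[`, numeric(ncol(ranks)), "centroid"))
  rownames(centroids) <- names(clusters)
  colnames(centroids) <- colnames(ranks)
  resource <- vapply(seq_along(leaves), function(i) {
    mean(dist_to_centroid(ranks[leaves[[i]]$members, , drop = FALSE],
                          leaves[[i]]$centroid))
  }, numeric(1))
  names(resource) <- names(clusters)
  structure(list(level = target_clusters, clusters = clusters,
                 centroids = centroids, resource = resource, seed = seed),
            class = "gene_cluster_set")
}

#' @export
print.gene_cluster_set <- function(x, ...) {
  cat(sprintf("gene_cluster_set: level %d -> %d clusters (sizes %s)\n",
              x$level, length(x$clusters),
              paste(lengths(x$clusters), collapse = ", ")))
  invisible(x)
}

#' Select non-overlapping clusters across clustering levels
#'
#' Clustering at several tree-growth levels yields nested, overlapping
#' candidate clusters.  This makes the selection reproducible: candidates
#' are taken greedily in ascending order of their best adjusted enrichment
#' p-value (ties broken by level then cluster ID), skipping any candidate
#' whose gene set overlaps an already-selected one, and an audit trail of
#' every decision is returned.
#'
#' @param cluster_sets List of `gene_cluster_set`s (one per level).
#' @param enrichment Data frame with columns `level`, `cluster_id`, `p_adj`
#'   giving each cluster's best adjusted enrichment p-value.
#' @return Data frame audit trail with columns `level`, `cluster_id`,
#'   `p_adj`, `size`, `selected` and `reason`, ordered as considered.
#' @export
rank_cluster_candidates <- function(cluster_sets, enrichment) {
  stopifnot(all(c("level", "cluster_id", "p_adj") %in% colnames(enrichment)))
  levels_map <- stats::setNames(cluster_sets,
                                vapply(cluster_sets, `[[`, numeric(1), "level"))
  enrichment <- enrichment[order(enrichment$p_adj, enrichment$level,
                                 enrichment$cluster_id), , drop = FALSE]
  taken <- character(0)
  audit <- enrichment
  audit$size <- NA_integer_
  audit$selected <- FALSE
  audit$reason <- ""
  for (i in seq_len(nrow(audit))) {
    cs <- levels_map[[as.character(audit$level[i])]]
    genes <- cs$clusters[[audit$cluster_id[i]]]
    audit$size[i] <- length(genes)
    if (length(intersect(genes, taken)) > 0L) {
      audit$reason[i] <- "overlaps selected cluster"
      next
    }
    audit$selected[i] <- TRUE
    audit$reason[i] <- "selected"
    taken <- c(taken, genes)
  }
  rownames(audit) <- NULL
  audit
}
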