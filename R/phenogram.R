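#' Read a two-column ortholog map
#'
#' Lines of `reference-gene<TAB>target-gene`; duplicate reference genes are
#' an error (the map must be a function), unmapped genes are simply absent.
#'
#' @param path File path.
#' @return Named character vector, reference gene -> target gene.
#' @export
read_ortholog_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    stop("ortholog map must be 2-column TSV: ", path, call. = FALSE)
  }
  ref <- vapply(fields, `[[`, character(1), 1L)
  tgt <- vapply(fields, `[[`, character(1), 2L)
  if (anyDuplicated(ref)) stop("duplicate reference genes in ", path, call. = FALSE)
  stats::setNames(tgt, ref)
}

#' GO-term-level 6VP matrix across organisms
#'
#' For each organism and each candidate GO term, the term's reference-set
#' genes are mapped through the organism's ortholog map and the per-variable
#' mean rank of the members is recorded, giving each organism a
#' (terms x 6)-dimensional profile.  A term is kept only if its mapped gene
#' count lies within `[min_genes, max_genes]` in every organism and every
#' organism has data for all six variables; an audit of dropped terms is
#' returned.
#'
#' @param rank_matrices Named list (organism -> rank matrix).
#' @param term_genes Named list (term -> reference gene IDs), typically the
#'   propagated sets of the reference annotation.
#' @param ortholog_maps Named list (organism -> named map from reference
#'   gene to organism gene); the reference organism may map by identity
#'   (`NULL` entry).
#' @param min_genes,max_genes Inclusive per-organism size bounds.
#' @return Object of class `go_profile_matrix`: `profiles` (organism x
#'   (term x variable) matrix with `term|variable` column names), `terms`
#'   (kept), `dropped` (data frame term/reason).
#' @export
build_go_profiles <- function(rank_matrices, term_genes, ortholog_maps = NULL,
                              min_genes = 5L, max_genes = 275L) {
  orgs <- names(rank_matrices)
  stopifnot(length(orgs) >= 1L, !is.null(orgs))
  kept <- character(0)
  dropped <- data.frame(term = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  prof_rows <- lapply(orgs, function(o) numeric(0))
  names(prof_rows) <- orgs
  ## per-organism member lists for each term
  member_sets <- list()
  for (term in names(term_genes)) {
    ok <- TRUE
    reason <- ""
    members <- list()
    for (o in orgs) {
      g <- term_genes[[term]]
      map <- if (is.null(ortholog_maps)) NULL else ortholog_maps[[o]]
      if (!is.null(map)) g <- unname(map[intersect(g, names(map))])
      g <- intersect(g, rownames(rank_matrices[[o]]))
      if (length(g) < min_genes || length(g) > max_genes) {
        ok <- FALSE
        reason <- sprintf("size %d in %s outside [%d, %d]",
                          length(g), o, min_genes, max_genes)
        break
      }
      members[[o]] <- g
    }
    if (ok) {
      ## require data for all six variables in every organism
      for (o in orgs) {
        sub <- rank_matrices[[o]][members[[o]], , drop = FALSE]
        if (any(colSums(!is.na(sub)) == 0L)) {
          ok <- FALSE
          reason <- sprintf("no data for some variable in %s", o)
          break
        }
      }
    }
    if (!ok) {
      dropped <- rbind(dropped, data.frame(term = term, reason = reason,
                                           stringsAsFactors = FALSE))
      next
    }
    kept <- c(kept, term)
    member_sets[[term]] <- members
  }
  if (length(kept) == 0L) stop("no terms survive the filters", call. = FALSE)
  cols <- as.vector(t(outer(kept, SIXVP_VARIABLES, paste, sep = "|")))
  profiles <- matrix(NA_real_, nrow = length(orgs), ncol = length(cols),
                     dimnames = list(orgs, cols))
  for (o in orgs) {
    for (term in kept) {
      sub <- rank_matrices[[o]][member_sets[[term]][[o]], , drop = FALSE]
      profiles[o, paste(term, SIXVP_VARIABLES, sep = "|")] <-
        suppressWarnings(colMeans(sub, na.rm = TRUE))
    }
  }
  structure(list(profiles = profiles, terms = kept, dropped = dropped,
                 members = member_sets),
            class = "go_profile_matrix")
}

#' @export
print.go_profile_matrix <- function(x, ...) {
  cat(sprintf("go_profile_matrix: %d organisms x %d terms (%d dropped)\n",
              nrow(x$profiles), length(x$terms), nrow(x$dropped)))
  invisible(x)
}

#' Pairwise organism distances from GO-term 6VPs
#'
#' Euclidean distance on the concatenated (term x variable) vectors,
#' normalized by the square root of the column count so trees built from
#' different term subsets share a scale; `one_minus_pearson` is available
#' as an alternative.
#'
#' @param profiles A [build_go_profiles()] result, or a plain organism x
#'   feature matrix.
#' @param metric `"euclidean"` (normalized) or `"one_minus_pearson"`.
#' @return Symmetric distance matrix with organism dimnames.
#' @export
organism_distance <- function(profiles, metric = c("euclidean", "one_minus_pearson")) {
  metric <- match.arg(metric)
  m <- if (inherits(profiles, "go_profile_matrix")) profiles$profiles else profiles
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  if (anyNA(m)) stop("profile matrix contains missing cells", call. = FALSE)
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(m)) / sqrt(ncol(m))
  } else {
    d <- 1 - stats::cor(t(m))
    diag(d) <- 0
  }
  d
}

#' Neighbor-joining phenogram
#'
#' Saitou-Nei agglomeration via [ape::nj()]; negative branch lengths are
#' clamped to zero with a warning.
#'
#' @param dist Symmetric distance matrix (>= 3 taxa).
#' @return An unrooted `phylo` tree with a `method` attribute `"NJ"`.
#' @export
nj_tree <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) < 3L) stop("neighbor-joining needs >= 3 taxa", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning(sum(tr$edge.length < 0), " negative NJ branch length(s) clamped to 0",
            call. = FALSE)
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  attr(tr, "method") <- "NJ"
  tr
}

#' UPGMA phenogram
#'
#' Average-linkage agglomeration with node heights at half the merge
#' distance, giving an ultrametric rooted tree.
#'
#' @param dist Symmetric distance matrix (>= 2 taxa).
#' @return A rooted ultrametric `phylo` tree with `method` `"UPGMA"`.
#' @export
upgma_tree <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2L) stop("UPGMA needs >= 2 taxa", call. = FALSE)
  if (n == 2L) {
    labs <- rownames(d) %||% c("t1", "t2")
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        labs[1L], d[1L, 2L] / 2,
                                        labs[2L], d[1L, 2L] / 2))
    attr(tr, "method") <- "UPGMA"
    return(tr)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ## as.phylo.hclust places each node at half its merge height, so tip-to-tip
  ## path lengths through the tree reproduce the merge distances directly
  tr <- ape::as.phylo(hc)
  attr(tr, "method") <- "UPGMA"
  tr
}

#' Per-functional-group phenograms
#'
#' Rebuilds NJ and UPGMA trees on the column subsets belonging to named
#' groups of GO terms (e.g. cytoplasmic translation, mitochondrion,
#' transcription, replication), so the divergence of each broad cellular
#' process can be compared on a common scale.
#'
#' @param profiles A [build_go_profiles()] result.
#' @param term_groups Named list of term ID vectors.
#' @param metric Passed to [organism_distance()].
#' @return Named list per group: `terms` used, `dist`, `nj` (or `NULL` for
#'   < 3 taxa), `upgma`.  Groups with no surviving terms are skipped with a
#'   warning.
#' @export
curated_group_tree <- function(profiles, term_groups,
                               metric = c("euclidean", "one_minus_pearson")) {
  metric <- match.arg(metric)
  stopifnot(inherits(profiles, "go_profile_matrix"))
  out <- list()
  for (gname in names(term_groups)) {
    terms <- intersect(term_groups[[gname]], profiles$terms)
    if (length(terms) == 0L) {
      warning("group '", gname, "' has no terms in the profile matrix; skipped",
              call. = FALSE)
      next
    }
    cols <- as.vector(t(outer(terms, SIXVP_VARIABLES, paste, sep = "|")))
    sub <- profiles$profiles[, cols, drop = FALSE]
    d <- organism_distance(sub, metric = metric)
    out[[gname]] <- list(
      terms = terms,
      dist = d,
      nj = if (nrow(d) >= 3L) nj_tree(d) else NULL,
      upgma = upgma_tree(d)
    )
  }
  out
}
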