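#' Filter a complex catalog by size
#'
#' Keeps complexes whose membership (restricted to `genes`, when given)
#' is strictly greater than `min_size` and strictly less than `max_size`.
#'
#' @param complexes Named list of gene ID vectors.
#' @param genes Optional gene set to restrict memberships to.
#' @param min_size,max_size Open size bounds (default: more than 5 and
#'   fewer than 150 members).
#' @return The filtered named list.
#' @export
filter_complexes <- function(complexes, genes = NULL, min_size = 5L,
                             max_size = 150L) {
  out <- lapply(complexes, function(g) {
    g <- unique(as.character(g))
    if (!is.null(genes)) g <- intersect(g, genes)
    g
  })
  out[lengths(out) > min_size & lengths(out) < max_size]
}

#' Read a complex catalog from two-column TSV
#'
#' Lines of `complex-ID<TAB>gene-ID`.
#'
#' @param path File path.
#' @return Named list, complex ID -> gene ID vector.
#' @export
read_complex_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    stop("complex catalog must be 2-column TSV: ", path, call. = FALSE)
  }
  cx <- vapply(fields, `[[`, character(1), 1L)
  gn <- vapply(fields, `[[`, character(1), 2L)
  lapply(split(gn, cx), function(g) sort(unique(g)))
}

#' Classify gene pairs by shared complex or GO category
#'
#' Every unordered pair of the given genes is assigned to exactly one
#' category: `Complex` if both genes share at least one complex, else
#' `Same_GO` if both share at least one of the selected (non-complex) GO
#' categories, else `No_group`.  Complex takes precedence so the three
#' categories partition all pairs.
#'
#' @param genes Character vector of genes under study.
#' @param complexes Named list of complex memberships (pre-filtered, e.g.
#'   via [filter_complexes()]).
#' @param go_groups Named list of non-complex GO category memberships.
#' @param max_go_size GO categories at or above this size are dropped
#'   (strictly-less-than rule).
#' @return Object of class `pair_classification`: list with `genes`,
#'   `category` (factor over the C(m,2) pairs, pair order matching
#'   `pair_index()`), and `counts`.
#' @export
classify_pairs <- function(genes, complexes, go_groups, max_go_size = 350L) {
  genes <- sort(unique(genes))
  m <- length(genes)
  if (m < 2L) stop("need at least 2 genes", call. = FALSE)
  go_groups <- lapply(go_groups, function(g) intersect(g, genes))
  go_groups <- go_groups[lengths(go_groups) < max_go_size]
  idx <- stats::setNames(seq_len(m), genes)
  in_complex <- matrix(FALSE, m, m)
  for (cx in complexes) {
    i <- idx[intersect(cx, genes)]
    if (length(i) >= 2L) in_complex[i, i] <- TRUE
  }
  in_go <- matrix(FALSE, m, m)
  for (gg in go_groups) {
    i <- idx[gg]
    if (length(i) >= 2L) in_go[i, i] <- TRUE
  }
  up <- upper.tri(in_complex)
  category <- ifelse(in_complex[up], "Complex",
                     ifelse(in_go[up], "Same_GO", "No_group"))
  category <- factor(category, levels = c("Complex", "Same_GO", "No_group"))
  structure(
    list(genes = genes, category = category, counts = table(category)),
    class = "pair_classification"
  )
}

#' @export
print.pair_classification <- function(x, ...) {
  cat(sprintf("pair_classification: %d genes, %d pairs\n",
              length(x$genes), length(x$category)))
  print(x$counts)
  invisible(x)
}

#' All-pairs 6VP correlation distances
#'
#' Computes 1 - Pearson R between every pair of gene rank profiles via one
#' matrix correlation; rows must be complete.
#'
#' @param ranks Complete rank matrix (genes x variables).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pairwise_profile_distances <- function(ranks) {
  stopifnot(is.matrix(ranks), !anyNA(ranks))
  sds <- apply(ranks, 1L, stats::sd)
  d <- 1 - suppressWarnings(stats::cor(t(ranks)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance profile(s): distances set to 1",
            call. = FALSE)
    d[sds == 0, ] <- 1
    d[, sds == 0] <- 1
  }
  diag(d) <- 0
  d
}

#' Profile-distance statistics by pair category
#'
#' Computes the 6VP correlation distance for every gene pair, summarizes it
#' per category (Complex / Same_GO / No_group), and tests the differences
#' with one-way ANOVA plus pairwise Welch t-tests.
#'
#' @param ranks Complete rank matrix restricted to the classified genes.
#' @param classification A [classify_pairs()] result on the same genes.
#' @return Object of class `pair_distance_stats`: `summary` data frame
#'   (category, n, mean, sd), `anova` (list with `F`, `p` or `NULL` when
#'   degenerate), `t_tests` (data frame of pairwise Welch p-values),
#'   `degenerate` flag.
#' @export
pair_distance_stats <- function(ranks, classification) {
  stopifnot(inherits(classification, "pair_classification"))
  genes <- classification$genes
  missing <- setdiff(genes, rownames(ranks))
  if (length(missing)) {
    stop("genes missing from rank matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  d <- pairwise_profile_distances(ranks[genes, , drop = FALSE])
  dist_vec <- d[upper.tri(d)]
  cat_vec <- classification$category
  stopifnot(length(dist_vec) == length(cat_vec))
  summ <- data.frame(
    category = levels(cat_vec),
    n = as.integer(table(cat_vec)),
    mean = as.numeric(tapply(dist_vec, cat_vec, mean)),
    sd = as.numeric(tapply(dist_vec, cat_vec, stats::sd)),
    stringsAsFactors = FALSE
  )
  present <- levels(cat_vec)[table(cat_vec) >= 2L]
  degenerate <- length(present) < 2L || stats::sd(dist_vec) == 0
  anova_res <- NULL
  t_tests <- data.frame(group1 = character(0), group2 = character(0),
                        p = numeric(0), stringsAsFactors = FALSE)
  if (!degenerate) {
    sub <- cat_vec %in% present
    fit <- stats::oneway.test(dist_vec[sub] ~ droplevels(cat_vec[sub]),
                              var.equal = TRUE)
    anova_res <- list(F = unname(fit$statistic), p = fit$p.value)
    combs <- utils::combn(present, 2L)
    rows <- lapply(seq_len(ncol(combs)), function(j) {
      a <- dist_vec[cat_vec == combs[1L, j]]
      b <- dist_vec[cat_vec == combs[2L, j]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      } else {
        p <- stats::t.test(a, b)$p.value
      }
      data.frame(group1 = combs[1L, j], group2 = combs[2L, j], p = p,
                 stringsAsFactors = FALSE)
    })
    t_tests <- do.call(rbind, rows)
  }
  structure(list(summary = summ, anova = anova_res, t_tests = t_tests,
                 degenerate = degenerate),
            class = "pair_distance_stats")
}

#' @export
print.pair_distance_stats <- function(x, ...) {
  cat("pair_distance_stats\n")
  print(x$summary)
  if (!is.null(x$anova)) {
    cat(sprintf("ANOVA F = %.3f, p = %.3g\n", x$anova$F, x$anova$p))
  } else {
    cat("ANOVA: degenerate input\n")
  }
  invisible(x)
}
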