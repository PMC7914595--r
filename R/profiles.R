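#' Rank-transform a six-variable matrix to the [0, 1] scale
#'
#' Within each variable column, non-missing values are replaced by
#' fractional ranks scaled as (rank - 1) / (n - 1), so the lowest value maps
#' to 0 and the highest to 1.  Ties receive their average rank; missing
#' cells stay missing and do not count toward n.  Ranking puts the six
#' variables, measured in incomparable units by very different techniques,
#' on one robust common scale.
#'
#' @param matrix A `sixvp_matrix` (see [six_variable_matrix()]).
#' @return A matrix of the same shape and class with cells in \[0, 1\] or `NA`.
#' @export
rank_matrix <- function(matrix) {
  stopifnot(is.matrix(matrix), identical(colnames(matrix), SIXVP_VARIABLES))
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    ok <- !is.na(x)
    n <- sum(ok)
    if (n == 0L) next
    if (n == 1L) { out[ok, j] <- 0.5; next }
    if (length(unique(x[ok])) == 1L) {
      warning(sprintf("constant column %s: all ranks set to 0.5",
                      colnames(matrix)[j]), call. = FALSE)
      out[ok, j] <- 0.5
      next
    }
    r <- rank(x[ok], ties.method = "average")
    out[ok, j] <- (r - 1) / (n - 1)
  }
  as_sixvp_matrix(out, attr(matrix, "organism") %||% "unknown")
}

#' Filter genes by variable coverage
#'
#' Keeps the genes with at least `min_total` non-missing variables, of which
#' at least `min_mrna` are mRNA-side (TR, RS, RA) and at least `min_protein`
#' protein-side (TLRi, PS, PA).  This is the 4-of-6 coverage rule applied
#' before profile clustering.
#'
#' @param matrix A `sixvp_matrix` or rank matrix.
#' @param min_total,min_mrna,min_protein Coverage thresholds.
#' @return Character vector of gene IDs passing the filter.
#' @export
filter_genes <- function(matrix, min_total = 4L, min_mrna = 2L, min_protein = 2L) {
  stopifnot(identical(colnames(matrix), SIXVP_VARIABLES))
  obs <- !is.na(matrix)
  total <- rowSums(obs)
  mrna <- rowSums(obs[, SIXVP_MRNA_VARIABLES, drop = FALSE])
  prot <- rowSums(obs[, SIXVP_PROTEIN_VARIABLES, drop = FALSE])
  rownames(matrix)[total >= min_total & mrna >= min_mrna & prot >= min_protein]
}

#' Six-variable profile (6VP) of a gene group
#'
#' Per variable, the mean and standard error (sd / sqrt(n)) of the rank
#' values over the group members with data for that variable.  The profile
#' vector follows the canonical order TR, RS, RA, TLRi, PS, PA.
#'
#' @param ranks A rank matrix from [rank_matrix()].
#' @param genes Character vector of member gene IDs.
#' @param group_id Label for the group.
#' @return Object of class `profile6v`: list with `group_id`, `n` (per
#'   variable), `mean` and `se` (6-vectors).
#' @export
group_profile <- function(ranks, genes, group_id = "group") {
  genes <- intersect(genes, rownames(ranks))
  if (length(genes) == 0L) stop("empty gene group", call. = FALSE)
  sub <- ranks[genes, , drop = FALSE]
  n <- colSums(!is.na(sub))
  if (all(n == 0L)) stop("group has no data for any variable", call. = FALSE)
  mu <- suppressWarnings(colMeans(sub, na.rm = TRUE))
  sdv <- suppressWarnings(apply(sub, 2L, stats::sd, na.rm = TRUE))
  se <- ifelse(n > 0L, ifelse(n > 1L, sdv / sqrt(n), 0), NA_real_)
  mu[n == 0L] <- NA_real_
  structure(list(group_id = group_id, n = n, mean = mu, se = se),
            class = "profile6v")
}

#' @export
print.profile6v <- function(x, digits = 3L, ...) {
  cat(sprintf("6VP '%s' (max n = %d)\n", x$group_id, max(x$n)))
  print(round(rbind(mean = x$mean, se = x$se, n = x$n), digits))
  invisible(x)
}

#' Random-sampling control profile
#'
#' Draws `reps` random gene groups of the given size and averages their
#' profiles, yielding the null expectation against which a functional
#' group's 6VP is judged.  On a rank matrix the control is a flat line at
#' 0.5.
#'
#' @param ranks A rank matrix.
#' @param size Group size for each random sample.
#' @param reps Number of random samplings.
#' @param seed Integer seed for reproducibility.
#' @return List with `grand_mean` (per-variable mean over reps), `lower` and
#'   `upper` (2.5% and 97.5% percentiles of the per-rep means), `reps` and
#'   `size`.
#' @export
random_control <- function(ranks, size, reps = 1000L, seed = 1L) {
  if (size < 1L) stop("size must be >= 1", call. = FALSE)
  if (size > nrow(ranks)) stop("size exceeds number of genes", call. = FALSE)
  set.seed(seed)
  means <- matrix(NA_real_, nrow = reps, ncol = ncol(ranks),
                  dimnames = list(NULL, colnames(ranks)))
  genes <- rownames(ranks)
  for (r in seq_len(reps)) {
    pick <- sample(genes, size)
    means[r, ] <- suppressWarnings(colMeans(ranks[pick, , drop = FALSE],
                                            na.rm = TRUE))
  }
  list(
    grand_mean = colMeans(means, na.rm = TRUE),
    lower = apply(means, 2L, stats::quantile, probs = 0.025, na.rm = TRUE),
    upper = apply(means, 2L, stats::quantile, probs = 0.975, na.rm = TRUE),
    reps = reps, size = size
  )
}
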