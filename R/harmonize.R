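#' Gate multiple datasets of one variable by pairwise correlation
#'
#' When a variable was measured by several studies, the datasets are merged
#' only if they agree: if every pairwise Pearson correlation (computed on
#' each pair's gene intersection) exceeds `threshold`, all datasets are
#' kept; otherwise only the dataset covering the most genes is retained.
#' A pair with an empty gene intersection counts as failing the gate.
#'
#' @param tables List of [expression_table()]s, all for the same organism
#'   and variable.
#' @param threshold Correlation gate; the default 0.3 keeps dataset pairs
#'   with R strictly above 0.3.
#' @param log_values Correlate log-transformed values instead of raw.
#' @return List with `kept` (list of tables) and `report` (a
#'   `harmonization_report` recording kept/dropped sources and pairwise R).
#' @export
gate_datasets <- function(tables, threshold = 0.3, log_values = FALSE) {
  stopifnot(length(tables) >= 1L)
  orgs <- unique(vapply(tables, function(t) t$organism, character(1)))
  vars <- unique(vapply(tables, function(t) t$variable, character(1)))
  if (length(orgs) != 1L || length(vars) != 1L) {
    stop("all tables must share organism and variable", call. = FALSE)
  }
  sources <- vapply(tables, function(t) t$source_id, character(1))
  if (length(tables) == 1L) {
    report <- harmonization_report(vars, kept = sources, dropped = character(0),
                                   pairwise_r = data.frame())
    return(list(kept = tables, report = report))
  }
  pairs <- utils::combn(length(tables), 2L)
  rvals <- data.frame(source1 = sources[pairs[1L, ]],
                      source2 = sources[pairs[2L, ]],
                      r = NA_real_, n = 0L, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- tables[[pairs[1L, j]]]$values
    b <- tables[[pairs[2L, j]]]$values
    shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
    rvals$n[j] <- length(shared)
    if (length(shared) < 3L) {
      warning(sprintf("datasets %s and %s share %d genes; pair fails the gate",
                      rvals$source1[j], rvals$source2[j], length(shared)),
              call. = FALSE)
      next
    }
    x <- a[shared]; y <- b[shared]
    if (log_values) { x <- log(x); y <- log(y) }
    rvals$r[j] <- stats::cor(x, y)
  }
  pass <- !is.na(rvals$r) & rvals$r > threshold
  if (all(pass)) {
    kept <- tables
    dropped <- character(0)
  } else {
    sizes <- vapply(tables, function(t) sum(!is.na(t$values)), integer(1))
    best <- which.max(sizes)
    kept <- tables[best]
    dropped <- sources[-best]
  }
  report <- harmonization_report(
    vars, kept = vapply(kept, function(t) t$source_id, character(1)),
    dropped = dropped, pairwise_r = rvals)
  list(kept = kept, report = report)
}

harmonization_report <- function(variable, kept, dropped, pairwise_r,
                                 n_imputed = 0L, median_scale_factors = numeric(0)) {
  structure(
    list(variable = variable, kept_sources = kept, dropped_sources = dropped,
         pairwise_r = pairwise_r, n_imputed = n_imputed,
         median_scale_factors = median_scale_factors),
    class = "harmonization_report"
  )
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat(sprintf("harmonization_report [%s]: kept %s; dropped %s; %d imputed\n",
              x$variable, paste(x$kept_sources, collapse = ","),
              if (length(x$dropped_sources)) paste(x$dropped_sources, collapse = ",") else "none",
              x$n_imputed))
  invisible(x)
}

#' K-nearest-neighbor imputation of a genes x sources matrix
#'
#' Each missing cell of a gene (row) is replaced by the mean of that
#' column's values over the `k` genes nearest in Euclidean distance on the
#' columns both genes have observed (distance rescaled to the full column
#' count).  Rows missing more than `rowmax` of their entries, and any
#' residual missing cells, are filled by column means.  The defaults (k =
#' 10, rowmax = 0.5, colmax = 0.8) follow the long-standing KNN-imputation
#' defaults for expression matrices.
#'
#' @param m Numeric matrix (genes x sources) with `NA` for missing cells.
#' @param k Number of neighbors.
#' @param rowmax Maximum fraction of missing entries per row before the row
#'   falls back to column means.
#' @param colmax Maximum tolerated fraction of missing entries per column.
#' @return The matrix with no missing values.
#' @export
impute_knn <- function(m, k = 10L, rowmax = 0.5, colmax = 0.8) {
  stopifnot(is.matrix(m))
  if (!anyNA(m)) return(m)
  col_miss <- colMeans(is.na(m))
  if (any(col_miss >= 1)) {
    stop("column(s) entirely missing: ",
         paste(colnames(m)[col_miss >= 1] %||% which(col_miss >= 1), collapse = ", "),
         call. = FALSE)
  }
  if (any(col_miss > colmax)) {
    warning("column(s) exceed colmax missingness; imputed all the same",
            call. = FALSE)
  }
  col_means <- colMeans(m, na.rm = TRUE)
  row_miss <- rowMeans(is.na(m))
  out <- m
  heavy <- row_miss > rowmax
  for (i in which(heavy)) {
    nas <- is.na(out[i, ])
    out[i, nas] <- col_means[nas]
  }
  todo <- which(rowMeans(is.na(m)) > 0 & !heavy)
  if (length(todo)) {
    donors <- m[!heavy, , drop = FALSE]
    for (i in todo) {
      x <- m[i, ]
      nas <- which(is.na(x))
      ## Euclidean distance on shared observed columns, scaled to p columns
      diffs <- sweep(donors, 2L, x, "-")
      sq <- diffs^2
      obs <- !is.na(sq)
      nshared <- rowSums(obs)
      d <- sqrt(rowSums(sq, na.rm = TRUE) * ncol(m) / pmax(nshared, 1L))
      d[nshared == 0L] <- Inf
      ## the row itself is among the donors but is NA at every column it
      ## needs, so it can never be selected as its own neighbor
      for (j in nas) {
        cand <- which(!is.na(donors[, j]) & is.finite(d))
        if (length(cand) == 0L) { out[i, j] <- col_means[j]; next }
        nn <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
        out[i, j] <- mean(donors[nn, j])
      }
    }
  }
  out
}

#' Rescale datasets so their medians match
#'
#' Each table is multiplied by (grand median / its median), where the grand
#' median is the median of the per-table medians.  Multiplicative matching
#' is the natural choice for ratio-scale abundances and rates; an additive
#' match on the log scale is available via `log_scale = TRUE`.
#'
#' @param tables List of [expression_table()]s.
#' @param log_scale Match by additive shift of log values instead.
#' @return List with `tables` (rescaled) and `factors` (named numeric of the
#'   per-source multipliers, or log-shifts when `log_scale`).
#' @export
match_medians <- function(tables, log_scale = FALSE) {
  stopifnot(length(tables) >= 1L)
  meds <- vapply(tables, function(t) stats::median(t$values, na.rm = TRUE),
                 numeric(1))
  if (anyNA(meds)) stop("a table has no non-missing values", call. = FALSE)
  if (!log_scale && any(meds == 0)) {
    stop("a table median of 0 cannot be rescaled multiplicatively", call. = FALSE)
  }
  grand <- stats::median(meds)
  out <- vector("list", length(tables))
  factors <- numeric(length(tables))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    if (log_scale) {
      shift <- grand / meds[i]           # multiplicative == additive in log
      factors[i] <- log(shift)
      t$values <- t$values * shift
    } else {
      factors[i] <- grand / meds[i]
      t$values <- t$values * factors[i]
    }
    out[[i]] <- t
  }
  names(factors) <- vapply(tables, function(t) t$source_id, character(1))
  list(tables = out, factors = factors)
}

#' Average gene values across datasets
#'
#' Per-gene arithmetic mean over the sources in which the gene appears with
#' a non-missing value.  Intended to run after [gate_datasets()],
#' [impute_knn()] and [match_medians()].
#'
#' @param tables List of [expression_table()]s (same organism/variable).
#' @param source_id Label for the merged table.
#' @return A single [expression_table()].
#' @export
average_datasets <- function(tables, source_id = "averaged") {
  stopifnot(length(tables) >= 1L)
  genes <- sort(unique(unlist(lapply(tables, function(t) names(t$values)))))
  acc <- stats::setNames(numeric(length(genes)), genes)
  cnt <- stats::setNames(integer(length(genes)), genes)
  for (t in tables) {
    ok <- !is.na(t$values)
    g <- names(t$values)[ok]
    acc[g] <- acc[g] + t$values[ok]
    cnt[g] <- cnt[g] + 1L
  }
  vals <- ifelse(cnt > 0L, acc / cnt, NA_real_)
  expression_table(vals, organism = tables[[1L]]$organism,
                   variable = tables[[1L]]$variable, source_id = source_id)
}

#' Derive transcription rate from mRNA amount and stability
#'
#' Under steady state the mRNA amount equals the product of its synthesis
#' rate and stability, so TR(g) = RA(g) / RS(g) on the gene intersection.
#' Genes with RS = 0 are dropped with a warning; any constant factor in the
#' stability units (e.g. ln 2 between half-life and 1/decay-rate) cancels in
#' the rank space used downstream.
#'
#' @param ra,rs [expression_table()]s of mRNA amount and mRNA stability.
#' @return An [expression_table()] for TR.
#' @export
derive_tr <- function(ra, rs) {
  stopifnot(ra$variable == "RA", rs$variable == "RS")
  shared <- intersect(names(ra$values)[!is.na(ra$values)],
                      names(rs$values)[!is.na(rs$values)])
  zero <- shared[rs$values[shared] == 0]
  if (length(zero)) {
    warning(length(zero), " gene(s) dropped: RS = 0", call. = FALSE)
    shared <- setdiff(shared, zero)
  }
  expression_table(ra$values[shared] / rs$values[shared],
                   organism = ra$organism, variable = "TR",
                   source_id = "derived:RA/RS")
}

#' Derive per-mRNA translation rate from protein and mRNA data
#'
#' From the steady-state balance PA = RA x TLRi x PS, the translation rate
#' per mRNA molecule is TLRi(g) = PA(g) / (RA(g) x PS(g)), computed on the
#' gene intersection.  Genes with a zero denominator are dropped with a
#' warning.
#'
#' @param pa,ra,ps [expression_table()]s of protein abundance, mRNA
#'   abundance and protein stability.
#' @return An [expression_table()] for TLRi.
#' @export
derive_tlri <- function(pa, ra, ps) {
  stopifnot(pa$variable == "PA", ra$variable == "RA", ps$variable == "PS")
  shared <- Reduce(intersect, list(
    names(pa$values)[!is.na(pa$values)],
    names(ra$values)[!is.na(ra$values)],
    names(ps$values)[!is.na(ps$values)]))
  denom <- ra$values[shared] * ps$values[shared]
  zero <- shared[denom == 0]
  if (length(zero)) {
    warning(length(zero), " gene(s) dropped: RA*PS = 0", call. = FALSE)
    shared <- setdiff(shared, zero)
  }
  expression_table(pa$values[shared] / (ra$values[shared] * ps$values[shared]),
                   organism = pa$organism, variable = "TLRi",
                   source_id = "derived:PA/(RA*PS)")
}

#' Convert iBAQ protein intensities to protein copy numbers
#'
#' Fits log10(PCN) on log10(iBAQ) by ordinary least squares over the genes
#' shared between the two tables (positive values only) and applies the
#' fitted transform to every iBAQ gene, putting intensity-based
#' quantification on the copies-per-cell scale of the reference.
#'
#' @param ibaq [expression_table()] of iBAQ intensities (variable PA).
#' @param pcn_reference [expression_table()] of protein copy numbers.
#' @param min_shared Minimum shared positive genes to attempt the fit.
#' @return List: `table` (converted [expression_table()]), `slope`,
#'   `intercept`, `n_shared`, and `se_slope`.
#' @export
ibaq_to_pcn <- function(ibaq, pcn_reference, min_shared = 10L) {
  shared <- intersect(names(ibaq$values), names(pcn_reference$values))
  shared <- shared[!is.na(ibaq$values[shared]) & ibaq$values[shared] > 0 &
                   !is.na(pcn_reference$values[shared]) &
                   pcn_reference$values[shared] > 0]
  if (length(shared) < min_shared) {
    stop(sprintf("only %d shared positive genes (need >= %d)",
                 length(shared), min_shared), call. = FALSE)
  }
  fit <- stats::lm(log10(pcn_reference$values[shared]) ~ log10(ibaq$values[shared]))
  coefs <- stats::coef(fit)
  pos <- !is.na(ibaq$values) & ibaq$values > 0
  conv <- rep(NA_real_, length(ibaq$values))
  names(conv) <- names(ibaq$values)
  conv[pos] <- 10^(coefs[[1L]] + coefs[[2L]] * log10(ibaq$values[pos]))
  list(
    table = expression_table(conv, organism = ibaq$organism, variable = "PA",
                             source_id = paste0(ibaq$source_id, ":pcn")),
    slope = unname(coefs[[2L]]),
    intercept = unname(coefs[[1L]]),
    se_slope = suppressWarnings(summary(fit))$coefficients[2L, 2L],
    n_shared = length(shared)
  )
}

#' Harmonize all datasets of one variable into a single table
#'
#' Convenience wrapper chaining the full per-variable protocol: correlation
#' gating, KNN imputation across sources, median matching and per-gene
#' averaging.
#'
#' @inheritParams gate_datasets
#' @param k,rowmax Passed to [impute_knn()].
#' @return List with the merged `table` and the `report`.
#' @export
harmonize_variable <- function(tables, threshold = 0.3, log_values = FALSE,
                               k = 10L, rowmax = 0.5) {
  gated <- gate_datasets(tables, threshold = threshold, log_values = log_values)
  kept <- gated$kept
  n_imputed <- 0L
  if (length(kept) > 1L) {
    genes <- sort(unique(unlist(lapply(kept, function(t) names(t$values)))))
    m <- matrix(NA_real_, length(genes), length(kept),
                dimnames = list(genes, vapply(kept, function(t) t$source_id,
                                              character(1))))
    for (j in seq_along(kept)) m[names(kept[[j]]$values), j] <- kept[[j]]$values
    n_imputed <- sum(is.na(m))
    m <- impute_knn(m, k = k, rowmax = rowmax)
    for (j in seq_along(kept)) {
      kept[[j]] <- expression_table(m[, j], organism = kept[[j]]$organism,
                                    variable = kept[[j]]$variable,
                                    source_id = kept[[j]]$source_id)
    }
    mm <- match_medians(kept)
    kept <- mm$tables
    gated$report$median_scale_factors <- mm$factors
  }
  gated$report$n_imputed <- n_imputed
  list(table = average_datasets(kept), report = gated$report)
}
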