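#' Pairwise Pearson correlations among the six variables
#'
#' For every pair of variables, the Pearson correlation over the genes with
#' complete (non-missing) data for that pair, with the usual two-sided
#' p-value from the t distribution on n - 2 degrees of freedom.  Pairs with
#' fewer than 3 complete cases are reported missing.
#'
#' @param matrix A `sixvp_matrix` (raw or ranked values).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Object of class `correlation_grid`: list of 6 x 6 matrices `r`,
#'   `p` and `n`.
#' @export
pairwise_correlations <- function(matrix, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(identical(colnames(matrix), SIXVP_VARIABLES))
  p <- ncol(matrix)
  r <- matrix(NA_real_, p, p, dimnames = list(SIXVP_VARIABLES, SIXVP_VARIABLES))
  pv <- r
  nmat <- matrix(0L, p, p, dimnames = dimnames(r))
  for (i in seq_len(p)) {
    r[i, i] <- 1
    pv[i, i] <- 0
    nmat[i, i] <- sum(!is.na(matrix[, i]))
    for (j in seq_len(p)) {
      if (j <= i) next
      ok <- !is.na(matrix[, i]) & !is.na(matrix[, j])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L) next
      ct <- suppressWarnings(
        stats::cor.test(matrix[ok, i], matrix[ok, j], method = method,
                        exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = pv, n = nmat, method = method),
            class = "correlation_grid")
}

#' @export
print.correlation_grid <- function(x, digits = 2L, ...) {
  cat(sprintf("correlation_grid (%s)\n", x$method))
  print(round(x$r, digits))
  invisible(x)
}

#' Z-score standardization of a six-variable matrix
#'
#' Per column, subtracts the mean and divides by the standard deviation of
#' the non-missing cells, making coefficients comparable across variables.
#'
#' @param matrix A `sixvp_matrix` or any numeric matrix.
#' @return The standardized matrix.
#' @export
zscore_matrix <- function(matrix) {
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    ok <- !is.na(x)
    if (!any(ok)) next
    s <- stats::sd(x[ok])
    if (is.na(s) || s == 0) {
      stop(sprintf("zero-variance column %s cannot be standardized",
                   colnames(matrix)[j] %||% j), call. = FALSE)
    }
    out[ok, j] <- (x[ok] - mean(x[ok])) / s
  }
  out
}

#' Bayesian model averaging for the regression of PA on the other variables
#'
#' Enumerates every subset of the candidate covariates, scores each model by
#' its closed-form marginal likelihood under a Zellner g-prior with unit
#' information (g = n) and a uniform prior over models, and averages the
#' per-model posterior coefficient estimates by the model posterior
#' probabilities.  Under the g-prior the conditional posterior mean of a
#' coefficient is the OLS estimate shrunk by g / (1 + g); the 95% credible
#' interval of each averaged coefficient is obtained from seeded Monte-Carlo
#' draws of the posterior mixture (multivariate-t draws within each model,
#' zeros when the covariate is excluded).
#'
#' @param y Numeric response vector (z-scored protein abundance), no missing
#'   values.
#' @param x Numeric matrix of candidate covariates (z-scored), complete
#'   cases only, at most 12 columns.
#' @param excluded Character vector of covariate names to drop before
#'   enumeration (used when a variable was computed mathematically from the
#'   response and would be circular).
#' @param ndraws Monte-Carlo draws for the credible intervals.
#' @param seed Integer seed for the mixture draws.
#' @return Object of class `bma_result`: `posterior_mean`, `ci95` (2 x p),
#'   `inclusion_prob`, `model_posteriors` (named by comma-separated
#'   covariate sets, `"(null)"` for the empty model), `conditional_mean`
#'   (per-covariate posterior mean given inclusion), `g`, `n`.
#' @export
bma_regression <- function(y, x, excluded = character(0), ndraws = 20000L,
                           seed = 1L) {
  stopifnot(is.numeric(y), is.matrix(x), nrow(x) == length(y))
  if (anyNA(y) || anyNA(x)) stop("complete cases only", call. = FALSE)
  if (length(excluded)) x <- x[, setdiff(colnames(x), excluded), drop = FALSE]
  p <- ncol(x)
  if (p < 1L) stop("no candidate covariates left", call. = FALSE)
  if (p > 12L) stop("too many covariates to enumerate", call. = FALSE)
  n <- length(y)
  if (n <= p + 2L) stop("too few observations", call. = FALSE)
  vars <- colnames(x) %||% paste0("x", seq_len(p))
  colnames(x) <- vars
  ## center (intercept integrated out under a flat prior)
  yc <- y - mean(y)
  xc <- scale(x, center = TRUE, scale = FALSE)
  xtx_full <- crossprod(xc)
  if (kappa(xtx_full, exact = TRUE) > 1e10) {
    stop("collinear covariates (condition number > 1e10)", call. = FALSE)
  }
  g <- n
  tss <- sum(yc^2)
  n_models <- 2L^p
  include <- matrix(FALSE, n_models, p, dimnames = list(NULL, vars))
  for (j in seq_len(p)) {
    include[, j] <- bitwAnd(seq_len(n_models) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  log_bf <- numeric(n_models)          # vs the null model
  betas <- vector("list", n_models)    # shrunk conditional means
  scales <- vector("list", n_models)   # multivariate-t scale matrices
  for (m in seq_len(n_models)) {
    sel <- include[m, ]
    pm <- sum(sel)
    if (pm == 0L) {
      log_bf[m] <- 0
      betas[[m]] <- numeric(0)
      next
    }
    xm <- xc[, sel, drop = FALSE]
    xtx <- xtx_full[sel, sel, drop = FALSE]
    xty <- crossprod(xm, yc)
    bhat <- solve(xtx, xty)
    r2 <- drop(crossprod(xty, bhat)) / tss
    log_bf[m] <- (n - 1 - pm) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2))
    shrink <- g / (1 + g)
    betas[[m]] <- drop(bhat) * shrink
    ssr_g <- tss * (1 - shrink * r2)
    scales[[m]] <- shrink * (ssr_g / (n - 1)) * solve(xtx)
  }
  post <- exp(log_bf - max(log_bf))
  post <- post / sum(post)
  posterior_mean <- stats::setNames(numeric(p), vars)
  inclusion <- stats::setNames(numeric(p), vars)
  cond_mass <- stats::setNames(numeric(p), vars)
  for (m in seq_len(n_models)) {
    sel <- include[m, ]
    if (!any(sel)) next
    posterior_mean[sel] <- posterior_mean[sel] + post[m] * betas[[m]]
    inclusion[sel] <- inclusion[sel] + post[m]
  }
  conditional_mean <- ifelse(inclusion > 0, posterior_mean / inclusion, NA_real_)
  ## mixture draws for credible intervals
  set.seed(seed)
  draw_counts <- stats::rmultinom(1L, ndraws, post)[, 1L]
  draws <- matrix(0, nrow = ndraws, ncol = p, dimnames = list(NULL, vars))
  offset <- 0L
  nu <- n - 1
  for (m in seq_len(n_models)) {
    cnt <- draw_counts[m]
    if (cnt == 0L) next
    sel <- include[m, ]
    if (any(sel)) {
      pm <- sum(sel)
      L <- chol(scales[[m]])
      z <- matrix(stats::rnorm(cnt * pm), cnt, pm) %*% L
      w <- sqrt(nu / stats::rchisq(cnt, df = nu))
      draws[offset + seq_len(cnt), sel] <-
        sweep(z * w, 2L, betas[[m]], "+")
    }
    offset <- offset + cnt
  }
  ci95 <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975))
  model_names <- apply(include, 1L, function(s) {
    if (!any(s)) "(null)" else paste(vars[s], collapse = ",")
  })
  structure(
    list(posterior_mean = posterior_mean,
         conditional_mean = conditional_mean,
         ci95 = ci95,
         inclusion_prob = inclusion,
         model_posteriors = stats::setNames(post, model_names),
         covariates = vars, g = g, n = n),
    class = "bma_result"
  )
}

#' @export
print.bma_result <- function(x, digits = 3L, ...) {
  cat(sprintf("bma_result: n = %d, g = %d, %d models\n", x$n, x$g,
              length(x$model_posteriors)))
  print(round(rbind(mean = x$posterior_mean,
                    `2.5%` = x$ci95[1L, ], `97.5%` = x$ci95[2L, ],
                    incl = x$inclusion_prob), digits))
  invisible(x)
}
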