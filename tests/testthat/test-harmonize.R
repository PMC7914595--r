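make_table <- function(vals, var = "RS", src = "s1", org = "yeast") {
  expression_table(vals, org, var, src)
}

test_that("correlation gate keeps agreeing datasets and resolves disagreement by size", {
  # pair engineered at R = 0.31, just above the 0.3 limit: both kept
  cp <- correlated_pair(200, 0.31, seed = 4)
  g <- paste0("g", 1:200)
  t1 <- make_table(setNames(exp(cp$x), g), src = "dta")
  t2 <- make_table(setNames(exp(cp$y), g), src = "rateseq")
  # gate correlates raw values; use log option to hit the engineered R exactly
  res <- gate_datasets(list(t1, t2), log_values = TRUE)
  expect_length(res$kept, 2L)
  expect_equal(res$report$pairwise_r$r, 0.31, tolerance = 1e-9)
  expect_length(res$report$dropped_sources, 0L)

  # R = 0.10 below the gate: only the larger table survives
  cp2 <- correlated_pair(100, 0.10, seed = 5)
  big <- make_table(setNames(exp(cp2$x), paste0("g", 1:100)), src = "big")
  small_vals <- setNames(exp(cp2$y)[1:80], paste0("g", 1:80))
  small <- make_table(small_vals, src = "small")
  res2 <- gate_datasets(list(small, big), log_values = TRUE)
  expect_length(res2$kept, 1L)
  expect_equal(res2$kept[[1]]$source_id, "big")
  expect_equal(res2$report$dropped_sources, "small")

  # single table passes through untouched
  res3 <- gate_datasets(list(t1))
  expect_length(res3$kept, 1L)
  expect_equal(res3$kept[[1]]$values, t1$values)

  # empty intersection counts as failing the gate
  a <- make_table(c(g1 = 1, g2 = 2), src = "a")
  b <- make_table(c(h1 = 1, h2 = 2), src = "b")
  expect_warning(res4 <- gate_datasets(list(a, b)), "fails the gate")
  expect_length(res4$kept, 1L)
})

test_that("KNN imputation fills missing cells from nearest neighbors", {
  # constant neighborhood: the missing value must be exactly 7
  m <- cbind(a = c(1, 1.01, 0.99, 1.02, 5), b = c(7, 7, 7, NA, 2))
  rownames(m) <- paste0("g", 1:5)
  out <- impute_knn(m, k = 3)
  expect_equal(out["g4", "b"], 7)
  expect_false(anyNA(out))

  # complete matrix returned unchanged
  full <- matrix(rnorm(20), 5, 4)
  expect_identical(impute_knn(full), full)

  # all-missing column errors
  bad <- cbind(a = 1:4, b = rep(NA_real_, 4))
  expect_error(impute_knn(bad), "missing")

  # heavily missing rows fall back to column means
  m2 <- cbind(a = c(1, 2, 3, NA), b = c(4, 5, 6, NA), c = c(7, 8, 9, 10))
  out2 <- impute_knn(m2, k = 2, rowmax = 0.5)
  expect_equal(unname(out2[4, "a"]), 2)
  expect_equal(unname(out2[4, "b"]), 5)
})

test_that("masked cells are recovered with positive correlation", {
  set.seed(9)
  n <- 120
  latent <- rnorm(n)
  truth <- sapply(1:4, function(j) latent + rnorm(n, 0, 0.3))
  rownames(truth) <- paste0("g", 1:n)
  masked <- truth
  holes <- which(matrix(runif(length(truth)) < 0.1, nrow(truth)))
  masked[holes] <- NA
  rec <- impute_knn(masked, k = 10)
  expect_false(anyNA(rec))
  expect_gt(cor(rec[holes], truth[holes]), 0.5)
})

test_that("median matching equalizes medians without changing rank order", {
  t1 <- make_table(c(g1 = 1, g2 = 2, g3 = 3))          # median 2
  t2 <- make_table(c(g1 = 6, g2 = 8, g3 = 10), src = "s2")  # median 8
  mm <- match_medians(list(t1, t2))
  # grand median = median(c(2, 8)) = 5
  expect_equal(unname(mm$factors), c(5 / 2, 5 / 8))
  meds <- vapply(mm$tables, function(t) median(t$values), numeric(1))
  expect_equal(meds, c(5, 5), tolerance = 1e-9, ignore_attr = TRUE)
  # rank order within each table is untouched
  for (i in 1:2) {
    expect_equal(cor(mm$tables[[i]]$values, list(t1, t2)[[i]]$values,
                     method = "spearman"), 1)
  }
  # single table and identical tables are unchanged
  one <- match_medians(list(t1))
  expect_equal(one$tables[[1]]$values, t1$values)
  same <- match_medians(list(t1, t1))
  expect_equal(same$tables[[2]]$values, t1$values)
  # zero median cannot be matched multiplicatively
  tz <- make_table(c(g1 = -1, g2 = 0, g3 = 1))
  expect_error(match_medians(list(tz, t1)), "median of 0")
})

test_that("averaging datasets is a per-gene mean, permutation-invariant", {
  t1 <- make_table(c(g1 = 4, g2 = 1))
  t2 <- make_table(c(g1 = 6, g3 = 9), src = "s2")
  avg <- average_datasets(list(t1, t2))
  expect_equal(unname(avg$values[c("g1", "g2", "g3")]), c(5, 1, 9))
  avg2 <- average_datasets(list(t2, t1))
  expect_equal(avg$values[sort(names(avg$values))],
               avg2$values[sort(names(avg2$values))])
})

test_that("averaging replicates moves estimates toward the planted truth", {
  cfg <- sixvp_sim_config(n_genes = 300, replicate_count = 3,
                          replicate_noise_sd = 0.5, missing_rate = 0,
                          seed = 21)
  org <- generate_organism(cfg)
  reps <- org$tables[["TR"]]
  avg <- average_datasets(reps)
  truth <- org$truth[names(avg$values), "TR"]
  r_avg <- cor(log(avg$values), log(truth))
  r_single <- vapply(reps, function(t) {
    cor(log(t$values[names(truth)]), log(truth))
  }, numeric(1))
  expect_true(all(r_avg > r_single))
})

test_that("TR and TLRi derivations invert the steady-state identities", {
  ra <- make_table(c(g1 = 10, g2 = 0, g3 = 8), var = "RA")
  rs <- make_table(c(g1 = 2, g2 = 4, g3 = 0), var = "RS")
  expect_warning(tr <- derive_tr(ra, rs), "RS = 0")
  expect_equal(unname(tr$values["g1"]), 5)
  expect_equal(unname(tr$values["g2"]), 0)    # RA = 0 gives TR = 0
  expect_false("g3" %in% names(tr$values))    # RS = 0 dropped

  pa <- make_table(c(g1 = 100, g2 = 0), var = "PA")
  ra2 <- make_table(c(g1 = 10, g2 = 5), var = "RA")
  ps <- make_table(c(g1 = 2, g2 = 3), var = "PS")
  tlri <- derive_tlri(pa, ra2, ps)
  expect_equal(unname(tlri$values[c("g1", "g2")]), c(5, 0))

  # noise-free synthetic organism: exact inversion to 1e-9 relative
  cfg <- sixvp_sim_config(n_genes = 200, replicate_noise_sd = 0,
                          missing_rate = 0, replicate_count = 1, seed = 3)
  org <- generate_organism(cfg)
  tab <- function(v) expression_table(org$truth[, v], "A", v)
  tr2 <- derive_tr(tab("RA"), tab("RS"))
  expect_equal(max(abs(tr2$values - org$truth[names(tr2$values), "TR"]) /
                     org$truth[names(tr2$values), "TR"]), 0, tolerance = 1e-9)
  tl2 <- derive_tlri(tab("PA"), tab("RA"), tab("PS"))
  expect_equal(max(abs(tl2$values - org$truth[names(tl2$values), "TLRi"]) /
                     org$truth[names(tl2$values), "TLRi"]), 0, tolerance = 1e-9)
})

test_that("iBAQ-to-PCN conversion recovers the calibration line", {
  set.seed(2)
  ibaq_vals <- setNames(10^runif(50, 2, 6), paste0("g", 1:50))
  # exact proportionality PCN = 3 * iBAQ: slope 1, intercept log10(3)
  ib <- make_table(ibaq_vals, var = "PA", src = "ibaq")
  pcn <- make_table(3 * ibaq_vals, var = "PA", src = "pcn")
  fit <- ibaq_to_pcn(ib, pcn)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, log10(3), tolerance = 1e-9)
  expect_equal(fit$table$values, pcn$values, tolerance = 1e-9)

  # identity reference: identity transform
  fit_id <- ibaq_to_pcn(ib, ib)
  expect_equal(fit_id$slope, 1, tolerance = 1e-9)
  expect_equal(fit_id$intercept, 0, tolerance = 1e-9)

  # too few shared genes errors
  tiny <- make_table(ibaq_vals[1:5], var = "PA")
  expect_error(ibaq_to_pcn(tiny, pcn), "shared")

  # lognormal scatter around a planted slope: recovery within 2 SE
  set.seed(8)
  planted_slope <- 0.85
  x <- setNames(10^runif(200, 2, 7), paste0("p", 1:200))
  y <- 10^(planted_slope * log10(x) + 0.4 + rnorm(200, 0, 0.25))
  fit2 <- ibaq_to_pcn(make_table(x, var = "PA"), make_table(y, var = "PA"))
  expect_lt(abs(fit2$slope - planted_slope), 2 * fit2$se_slope)
})

test_that("harmonize_variable chains gate, imputation, matching and averaging", {
  cfg <- sixvp_sim_config(n_genes = 150, replicate_count = 2,
                          replicate_noise_sd = 0.2, missing_rate = 0.1,
                          seed = 31)
  org <- generate_organism(cfg)
  hv <- harmonize_variable(org$tables[["RA"]])
  expect_s3_class(hv$table, "expression_table")
  expect_false(anyNA(hv$table$values))
  expect_gt(hv$report$n_imputed, 0L)
  expect_gt(cor(log(hv$table$values),
                log(org$truth[names(hv$table$values), "RA"])), 0.8)
})
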