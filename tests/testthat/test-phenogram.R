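test_that("GO-term profiles apply size and coverage filters across organisms", {
  set.seed(19)
  mk_ranks <- function(n) {
    m <- matrix(runif(n * 6), n, 6,
                dimnames = list(paste0("g", 1:n), SIXVP_VARIABLES))
    m
  }
  rks <- list(A = mk_ranks(40), B = mk_ranks(40))
  terms <- list(big = paste0("g", 1:20),
                tiny = paste0("g", 1:4),          # 4 genes: dropped everywhere
                ok = paste0("g", 5:15))
  pr <- build_go_profiles(rks, terms, min_genes = 5, max_genes = 275)
  expect_setequal(pr$terms, c("big", "ok"))
  expect_true("tiny" %in% pr$dropped$term)
  expect_equal(dim(pr$profiles), c(2L, 12L))
  # profile entries are the plain mean ranks of the member genes
  expect_equal(pr$profiles["A", "ok|TR"], mean(rks$A[paste0("g", 5:15), "TR"]))

  # a term missing the size bound in ONE organism is dropped for all
  rks2 <- list(A = mk_ranks(40), B = mk_ranks(40)[1:6, ])
  pr2 <- build_go_profiles(rks2, list(wide = paste0("g", 1:30)),
                           min_genes = 5, max_genes = 275)
  # only 6 genes exist in B; term survives there but not if bound tightened
  expect_equal(pr2$terms, "wide")
  expect_error(build_go_profiles(rks2, list(wide = paste0("g", 1:30)),
                                 min_genes = 10), "no terms survive")

  # ortholog maps reroute reference genes before membership is counted
  map_b <- setNames(paste0("g", 21:40), paste0("g", 1:20))
  pr3 <- build_go_profiles(rks, list(grp = paste0("g", 1:10)),
                           ortholog_maps = list(B = map_b))
  expect_equal(pr3$profiles["B", "grp|PA"],
               mean(rks$B[paste0("g", 21:30), "PA"]))
})

test_that("organism distances honor the chosen metric", {
  m <- rbind(A = c(0.2, 0.4, 0.6), B = c(0.2, 0.4, 0.6), C = c(0.8, 0.1, 0.3))
  d <- organism_distance(m, "euclidean")
  expect_equal(d["A", "B"], 0)
  expect_equal(d, t(d))
  # normalization by sqrt(ncol): doubling the columns keeps the distance
  m2 <- cbind(m, m)
  d2 <- organism_distance(m2, "euclidean")
  expect_equal(d2["A", "C"], d["A", "C"], tolerance = 1e-12)
  dp <- organism_distance(m, "one_minus_pearson")
  expect_equal(dp["A", "B"], 0, tolerance = 1e-12)
  expect_error(organism_distance(m[1, , drop = FALSE]))
})

test_that("NJ reconstructs additive distances exactly", {
  # quartet ((A:2,B:3):1,(C:4,D:5)) gives an exactly additive matrix
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 5
  d["A", "C"] <- d["C", "A"] <- 7
  d["A", "D"] <- d["D", "A"] <- 8
  d["B", "C"] <- d["C", "B"] <- 8
  d["B", "D"] <- d["D", "B"] <- 9
  d["C", "D"] <- d["D", "C"] <- 9
  tr <- nj_tree(d)
  # oracle: path lengths through the tree reproduce every input distance
  back <- as.matrix(ape::cophenetic.phylo(tr))[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(back, d, tolerance = 1e-9)
  expect_true(has_cherry(tr, "A", "B"))
  expect_true(has_cherry(tr, "C", "D"))

  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  len <- setNames(t3$edge.length[t3$edge[, 2] <= 3],
                  t3$tip.label[t3$edge[t3$edge[, 2] <= 3, 2]])
  expect_equal(len[["x"]], (3 + 4 - 5) / 2)
  expect_equal(len[["y"]], (3 + 5 - 4) / 2)
  expect_equal(len[["z"]], (4 + 5 - 3) / 2)
  expect_error(nj_tree(d3[1:2, 1:2]), ">= 3")
})

test_that("UPGMA is ultrametric and round-trips ultrametric inputs", {
  # ultrametric input: two taxa at 2, joined with a third at 6
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- upgma_tree(d)
  back <- as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)]
  expect_equal(back, d, tolerance = 1e-9)
  # root-to-leaf depths all equal
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_lt(max(depths) - min(depths), 1e-9)

  # two taxa at distance d: two branches of d/2
  t2 <- upgma_tree(matrix(c(0, 3, 3, 0), 2, 2,
                          dimnames = list(c("p", "q"), c("p", "q"))))
  expect_equal(sort(t2$edge.length), c(1.5, 1.5))

  # independent cross-check against phangorn's UPGMA on a random matrix
  skip_if_not_installed("phangorn")
  set.seed(3)
  x <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(letters[1:5], NULL))
  dd <- as.matrix(dist(x))
  mine <- upgma_tree(dd)
  ref <- phangorn::upgma(as.dist(dd))
  expect_equal(as.matrix(ape::cophenetic.phylo(mine))[letters[1:5], letters[1:5]],
               as.matrix(ape::cophenetic.phylo(ref))[letters[1:5], letters[1:5]],
               tolerance = 1e-9)
})

test_that("tree construction is invariant under taxon input order", {
  set.seed(8)
  x <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(paste0("o", 1:6), NULL))
  d <- as.matrix(dist(x))
  perm <- c(4, 1, 6, 2, 5, 3)
  dp <- d[perm, perm]
  expect_equal(ape::dist.topo(ape::unroot(nj_tree(d)),
                              ape::unroot(nj_tree(dp))), 0, ignore_attr = TRUE)
  expect_equal(as.matrix(ape::cophenetic.phylo(upgma_tree(d)))[paste0("o", 1:6), paste0("o", 1:6)],
               as.matrix(ape::cophenetic.phylo(upgma_tree(dp)))[paste0("o", 1:6), paste0("o", 1:6)],
               tolerance = 1e-9)
})

test_that("clade profiles separate organisms according to the planted tree", {
  cfg <- sixvp_sim_config(n_genes = 400, seed = 53)
  clade <- generate_clade(cfg)
  rks <- lapply(clade$organisms, function(o) rank_matrix(o$truth))
  tg <- clade$annotations$propagated[grep("^GO:G", names(clade$annotations$propagated))]
  pr <- build_go_profiles(rks, tg, clade$ortholog_maps)
  d <- organism_distance(pr)
  # planted ((A,B),C): the A-B distance is the smallest
  expect_lt(d["A", "B"], d["A", "C"])
  expect_lt(d["A", "B"], d["B", "C"])
  up <- upgma_tree(d)
  expect_true(has_cherry(up, "A", "B"))
})

test_that("curated group trees reuse the global machinery per term subset", {
  cfg <- sixvp_sim_config(n_genes = 400, seed = 59,
                          organism_tree = "((A:0.1,B:0.1):0.08,(C:0.1,D:0.1):0.08);")
  clade <- generate_clade(cfg)
  rks <- lapply(clade$organisms, function(o) rank_matrix(o$truth))
  tg <- clade$annotations$propagated[grep("^GO:G", names(clade$annotations$propagated))]
  pr <- build_go_profiles(rks, tg, clade$ortholog_maps)
  groups <- list(all = pr$terms, solo = pr$terms[1])
  out <- curated_group_tree(pr, groups)
  # the whole-term group reproduces the global tree
  d_global <- organism_distance(pr)
  expect_equal(out$all$dist, d_global, tolerance = 1e-12)
  # singleton term group is still constructible (6 columns)
  expect_s3_class(out$solo$upgma, "phylo")
  expect_equal(dim(out$solo$dist), c(4L, 4L))
  expect_warning(curated_group_tree(pr, list(none = "GO:MISSING")), "skipped")
})
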