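test_that("expression tables read from TSV with duplicate and missing handling", {
  f <- tmp_lines("g1\t2.0", "g2\t4.0")
  t1 <- read_expression_table(f, "yeast", "RA")
  expect_length(t1, 2L)
  expect_equal(unname(t1$values[c("g1", "g2")]), c(2, 4))

  # duplicates collapse to the mean, with a warning
  f2 <- tmp_lines("g1\t2.0", "g1\t4.0")
  expect_warning(t2 <- read_expression_table(f2, "yeast", "RA"), "duplicate")
  expect_length(t2, 1L)
  expect_equal(unname(t2$values["g1"]), 3)
  # alternative collapse rules
  expect_warning(t2max <- read_expression_table(f2, "yeast", "RA", collapse = "max"))
  expect_equal(unname(t2max$values["g1"]), 4)
  expect_warning(t2sum <- read_expression_table(f2, "yeast", "RA", collapse = "sum"))
  expect_equal(unname(t2sum$values["g1"]), 6)

  # non-numeric values become missing
  t3 <- read_expression_table(tmp_lines("g1\tNA", "g2\t1.5"), "yeast", "PS")
  expect_true(is.na(t3$values["g1"]))
  expect_equal(unname(t3$values["g2"]), 1.5)

  # header is skipped, errors on malformed input
  t4 <- read_expression_table(tmp_lines("gene\tvalue", "g1\t1"), "yeast", "TR")
  expect_length(t4, 1L)
  expect_error(read_expression_table(tmp_lines("g1\t1\t2"), "yeast", "TR"),
               "malformed")
  expect_error(read_expression_table(tmp_lines(""), "yeast", "TR"), "empty")
})

test_that("expression table invariants are enforced and round-trip through TSV", {
  expect_error(expression_table(c(1, 2), "o", "RA"), "named")
  expect_error(expression_table(c(g1 = 1, g1 = 2), "o", "RA"), "unique")
  expect_error(expression_table(c(g1 = Inf), "o", "RA"), "finite")
  expect_error(expression_table(setNames(numeric(0), character(0)), "o", "RA"))

  t <- expression_table(c(g1 = 1.25, g2 = NA, g3 = 7), "o", "PA", "src")
  f <- tempfile()
  write_expression_table(t, f)
  back <- read_expression_table(f, "o", "PA", "src")
  expect_equal(back$values, t$values)
})

test_that("six-variable matrices assemble with fixed column order and survive TSV", {
  tr <- expression_table(c(g1 = 1, g2 = 2), "o", "TR")
  pa <- expression_table(c(g2 = 5, g3 = 6), "o", "PA")
  m <- six_variable_matrix(list(tr, pa))
  expect_identical(colnames(m), SIXVP_VARIABLES)
  expect_equal(nrow(m), 3L)
  expect_equal(m["g2", "TR"], 2)
  expect_equal(m["g2", "PA"], 5)
  expect_true(is.na(m["g1", "PA"]))

  f <- tempfile()
  write_sixvp_matrix(m, f)
  back <- read_sixvp_matrix(f, "o")
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
})

test_that("OBO parsing builds the DAG, skips obsolete terms and detects cycles", {
  f <- tmp_lines(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "name: mid", "namespace: biological_process",
    "is_a: GO:1 ! root", "",
    "[Term]", "id: GO:3", "name: child", "namespace: biological_process",
    "is_a: GO:2", "",
    "[Term]", "id: GO:9", "name: gone", "namespace: biological_process",
    "is_obsolete: true", ""
  )
  g <- read_obo(f)
  expect_setequal(g$terms$id, c("GO:1", "GO:2", "GO:3"))
  expect_equal(sum(lengths(g$parents)), 2L)       # two edges
  expect_false("GO:9" %in% g$terms$id)
  expect_setequal(g$ancestors[["GO:3"]], c("GO:3", "GO:2", "GO:1"))

  fc <- tmp_lines(
    "[Term]", "id: GO:1", "namespace: biological_process", "is_a: GO:2", "",
    "[Term]", "id: GO:2", "namespace: biological_process", "is_a: GO:1", ""
  )
  expect_error(read_obo(fc), "cycle")
})

test_that("part_of relationships are parental by default and ignorable", {
  f <- tmp_lines(
    "[Term]", "id: GO:1", "namespace: cellular_component", "",
    "[Term]", "id: GO:2", "namespace: cellular_component",
    "relationship: part_of GO:1 ! whole", ""
  )
  g <- read_obo(f)
  expect_equal(g$parents[["GO:2"]], "GO:1")
  g2 <- read_obo(f, part_of = FALSE)
  expect_length(g2$parents[["GO:2"]], 0L)
})

test_that("the synthetic toy ontology round-trips through write_obo/read_obo", {
  org <- generate_organism(sixvp_sim_config(n_genes = 60, n_groups = 4,
                                            n_complexes = 2, complex_size = 6,
                                            seed = 11))
  f <- tempfile(fileext = ".obo")
  write_obo(org$graph, f)
  back <- read_obo(f)
  expect_setequal(back$terms$id, org$graph$terms$id)
  for (t in org$graph$terms$id) {
    expect_setequal(back$parents[[t]], org$graph$parents[[t]])
  }
})

test_that("annotation propagation closes over ancestors", {
  fx <- diamond_fixture()
  a <- fx$annotations
  # gene annotated to a leaf appears in every ancestor's propagated set
  expect_true(all(c("g1", "g2") %in% a$propagated[["A"]]))
  expect_true(all(c("g1", "g2") %in% a$propagated[["B"]]))
  expect_true(all(c("g1", "g2") %in% a$propagated[["R"]]))
  expect_setequal(a$propagated[["C"]], c("g1", "g2"))
  # propagated(root) equals the union of all direct sets
  expect_setequal(a$propagated[["R"]], unique(unlist(a$direct)))
  # monotonicity along every edge
  for (child in names(fx$graph$parents)) {
    for (p in fx$graph$parents[[child]]) {
      expect_true(all(a$propagated[[child]] %in% a$propagated[[p]]))
    }
  }
})

test_that("random toy annotations satisfy the brute-force closure oracle", {
  fx <- diamond_fixture()
  set.seed(42)
  genes <- paste0("x", 1:30)
  direct <- lapply(setNames(nm = fx$graph$terms$id), function(t) {
    sample(genes, sample(0:6, 1))
  })
  direct <- direct[lengths(direct) > 0]
  a <- annotation_set(direct, fx$graph)
  # oracle: propagated(t) = union of direct(d) over all descendants d of t
  for (t in fx$graph$terms$id) {
    desc <- fx$graph$terms$id[vapply(fx$graph$terms$id, function(d) {
      t %in% fx$graph$ancestors[[d]]
    }, logical(1))]
    want <- sort(unique(unlist(direct[intersect(desc, names(direct))])))
    expect_setequal(a$propagated[[t]], want %||% character(0))
  }
  expect_setequal(a$propagated[["R"]], unique(unlist(direct)))
})

test_that("annotation readers handle two-column TSV, GAF, and unknown terms", {
  fx <- diamond_fixture()
  f <- tmp_lines("g1\tC", "g2\tD")
  a <- read_annotations(f, fx$graph)
  expect_setequal(a$direct[["C"]], "g1")
  expect_setequal(a$propagated[["A"]], c("g1", "g2"))

  funk <- tmp_lines("g1\tC", "g2\tNOPE")
  expect_warning(a2 <- read_annotations(funk, fx$graph), "unknown")
  expect_length(a2$direct, 1L)
  expect_error(read_annotations(funk, fx$graph, strict = TRUE), "unknown")

  # GAF 2.x: 17 columns, comments, NOT qualifier dropped
  gaf_row <- function(gene, term, qual = "") {
    paste(c("DB", gene, gene, qual, term, "REF", "IEA", "", "P", "", "",
            "protein", "taxon:1", "20200101", "DB", "", ""), collapse = "\t")
  }
  fg <- tmp_lines("!gaf-version: 2.1", gaf_row("g1", "C"),
                  gaf_row("g2", "D", "NOT"))
  a3 <- read_annotations(fg, fx$graph)
  expect_setequal(a3$universe, "g1")

  empty <- read_annotations(tmp_lines("!only a comment"), fx$graph)
  expect_length(empty$universe, 0L)
})

test_that("newick output validates labels and round-trips exactly", {
  tr <- ape::read.tree(text = "(A:1,B:2);")
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  txt <- readLines(f)
  expect_match(txt, "^\\(A:1,B:2\\);$")

  # 4-taxon NJ tree round-trips topology and branch lengths
  d <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 0, 0), 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d[4, 3] <- 9; d[3, 4] <- 9; d[4, 4] <- 0
  nj <- nj_tree(d)
  write_newick(nj, f)
  back <- read_newick(f)
  expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(nj$edge.length), tolerance = 1e-9)

  expect_error(write_newick(list(), f), "phylo")
  tr_nolen <- ape::read.tree(text = "(A,B);")
  expect_error(write_newick(tr_nolen, f), "branch lengths")
})
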