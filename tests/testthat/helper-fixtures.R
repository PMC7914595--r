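# Small in-code fixtures shared across test files.

# write lines to a temp file and return the path
tmp_lines <- function(...) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(...), f)
  f
}

# a tiny diamond-shaped BP ontology with hand-countable annotations:
#   R is root; A, B children of R; C child of both A and B; D child of A.
# direct annotations: C: g1,g2; D: g3; A: g4; B: g5,g6
# propagated: C={g1,g2} D={g3} A={g1..g4} B={g1,g2,g5,g6} R={g1..g6}
diamond_fixture <- function() {
  graph <- go_graph(
    data.frame(id = c("R", "A", "B", "C", "D"),
               namespace = "BP", stringsAsFactors = FALSE),
    list(R = character(0), A = "R", B = "R", C = c("A", "B"), D = "A")
  )
  anns <- annotation_set(
    list(C = c("g1", "g2"), D = "g3", A = "g4", B = c("g5", "g6")),
    graph
  )
  list(graph = graph, annotations = anns)
}

# six-variable matrix from a plain matrix of values (genes x 6)
toy_matrix <- function(values, organism = "toy") {
  colnames(values) <- SIXVP_VARIABLES
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  tabs <- lapply(SIXVP_VARIABLES, function(v) {
    expression_table(values[, v], organism, v, paste0(v, "_src"))
  })
  six_variable_matrix(tabs, organism)
}

# engineer two vectors with an exact sample Pearson correlation r
correlated_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  xs <- (x - mean(x)) / sd(x)
  zr <- residuals(lm(z ~ xs))
  zs <- zr / sd(zr)
  y <- r * xs + sqrt(1 - r^2) * zs
  list(x = xs, y = y)
}

# cluster labels (named by gene) from a gene_cluster_set
cluster_labels <- function(cs) {
  lab <- rep(NA_integer_, sum(lengths(cs$clusters)))
  names(lab) <- unlist(cs$clusters)
  for (k in seq_along(cs$clusters)) lab[cs$clusters[[k]]] <- k
  lab
}

# TRUE if tips a and b are attached to the same internal node (a cherry)
has_cherry <- function(tree, a, b) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  for (node in unique(tree$edge[, 1])) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    kid_tips <- tips[kids[kids <= length(tips)]]
    if (all(c(a, b) %in% kid_tips)) return(TRUE)
  }
  FALSE
}
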