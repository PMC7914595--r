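#' Configuration for the synthetic six-variable generator
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' latent per-gene expression level drives correlated values of the four
#' primitive variables (TR, RS, TLRi, PS) on the log scale; RA = TR x RS and
#' PA = RA x TLRi x PS hold exactly in the planted truth; functional groups
#' share archetype rank profiles; complexes are subsets of groups with
#' tighter dispersion; replicate datasets add lognormal noise and missing
#' cells; and archetypes drift along a planted organism tree.
#'
#' Because RA and PA are tied to the primitives by the steady-state
#' identities, only the TR, RS, TLRi and PS components of each archetype are
#' free; the RA and PA components emerge from them and are reported in the
#' ground truth as realized profile means.
#'
#' @param n_genes Number of genes.
#' @param n_groups Number of planted functional groups (genes are split
#'   evenly among them).
#' @param n_complexes Number of planted complexes; complex `i` is a subset
#'   of group `i` with dispersion `within_complex_sd`.
#' @param complex_size Genes per complex.
#' @param group_profile_archetypes Optional matrix (groups x 6) of archetype
#'   rank targets in \[0, 1\]; a built-in spread of distinct shapes is used
#'   when `NULL`.
#' @param archetype_effect Log-scale amplitude translating an archetype
#'   component of 0 or 1 into a low or high value.
#' @param within_group_sd,within_complex_sd Per-gene log-scale dispersion
#'   around the group archetype (`within_complex_sd < within_group_sd`).
#' @param latent_level_sd SD of the latent expression level.
#' @param rs_latent_coupling Coupling of log RS to the latent level (kept
#'   below 1 so TR correlates with RA more strongly than RS does).
#' @param potentiation_slope Coupling of log TLRi to the latent level
#'   (abundant mRNAs translate better when positive).
#' @param replicate_count Datasets emitted per variable.
#' @param replicate_noise_sd Lognormal measurement noise per replicate.
#' @param missing_rate Fraction of cells deleted per replicate dataset.
#' @param annotation_overlap Fraction of genes additionally annotated to a
#'   sibling group's term, so ontology terms overlap partially.
#' @param organism_tree Newick string with branch lengths; leaves are
#'   organism names.
#' @param divergence_rate Archetype drift SD per unit branch length.
#' @param ortholog_dropout Fraction of genes absent from each non-reference
#'   organism's ortholog map.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A validated list of class `sixvp_sim_config`.
#' @export
sixvp_sim_config <- function(n_genes = 1200L,
                             n_groups = 8L,
                             n_complexes = 4L,
                             complex_size = 12L,
                             group_profile_archetypes = NULL,
                             archetype_effect = 3,
                             within_group_sd = 0.5,
                             within_complex_sd = 0.2,
                             latent_level_sd = 1,
                             rs_latent_coupling = 0.35,
                             potentiation_slope = 0.3,
                             replicate_count = 2L,
                             replicate_noise_sd = 0.3,
                             missing_rate = 0.1,
                             annotation_overlap = 0.05,
                             organism_tree = "((A:0.1,B:0.1):0.1,C:0.2);",
                             divergence_rate = 1,
                             ortholog_dropout = 0,
                             seed = 7L) {
  cfg <- list(n_genes = as.integer(n_genes), n_groups = as.integer(n_groups),
              n_complexes = as.integer(n_complexes),
              complex_size = as.integer(complex_size),
              group_profile_archetypes = group_profile_archetypes,
              archetype_effect = archetype_effect,
              within_group_sd = within_group_sd,
              within_complex_sd = within_complex_sd,
              latent_level_sd = latent_level_sd,
              rs_latent_coupling = rs_latent_coupling,
              potentiation_slope = potentiation_slope,
              replicate_count = as.integer(replicate_count),
              replicate_noise_sd = replicate_noise_sd,
              missing_rate = missing_rate,
              annotation_overlap = annotation_overlap,
              organism_tree = organism_tree,
              divergence_rate = divergence_rate,
              ortholog_dropout = ortholog_dropout,
              seed = as.integer(seed))
  if (cfg$n_genes < cfg$n_groups * 2L) stop("too few genes for the groups", call. = FALSE)
  if (cfg$n_complexes > cfg$n_groups) stop("n_complexes exceeds n_groups", call. = FALSE)
  if (cfg$n_complexes > 0L && cfg$within_complex_sd >= cfg$within_group_sd) {
    stop("within_complex_sd must be smaller than within_group_sd", call. = FALSE)
  }
  rates <- c(cfg$archetype_effect, cfg$within_group_sd, cfg$within_complex_sd,
             cfg$latent_level_sd, cfg$replicate_noise_sd, cfg$missing_rate,
             cfg$annotation_overlap, cfg$divergence_rate, cfg$ortholog_dropout)
  if (any(rates < 0)) stop("rates and dispersions must be >= 0", call. = FALSE)
  if (cfg$missing_rate >= 1 || cfg$ortholog_dropout >= 1) {
    stop("missing_rate and ortholog_dropout must be < 1", call. = FALSE)
  }
  if (is.null(cfg$group_profile_archetypes)) {
    cfg$group_profile_archetypes <- default_archetypes(cfg$n_groups)
  } else {
    a <- as.matrix(cfg$group_profile_archetypes)
    if (nrow(a) != cfg$n_groups || ncol(a) != 6L) {
      stop("group_profile_archetypes must be n_groups x 6", call. = FALSE)
    }
    if (any(a < 0 | a > 1)) stop("archetype components must lie in [0, 1]", call. = FALSE)
    colnames(a) <- SIXVP_VARIABLES
    cfg$group_profile_archetypes <- a
  }
  structure(cfg, class = "sixvp_sim_config")
}

## a spread of distinct 6VP shapes (V-shaped, inverted, tilted, high, low ...)
default_archetypes <- function(n_groups) {
  base <- rbind(
    c(0.90, 0.30, 0.90, 0.80, 0.50, 0.90),   # high expression, V-ish mRNA arm
    c(0.10, 0.70, 0.20, 0.30, 0.50, 0.20),   # low expression
    c(0.80, 0.80, 0.90, 0.20, 0.30, 0.60),   # mRNA-heavy, weak translation
    c(0.20, 0.20, 0.10, 0.80, 0.70, 0.40),   # translation-compensated
    c(0.50, 0.90, 0.70, 0.50, 0.90, 0.70),   # stability-driven
    c(0.60, 0.10, 0.40, 0.90, 0.10, 0.50),   # turnover-heavy
    c(0.30, 0.50, 0.30, 0.10, 0.80, 0.20),   # quiescent, stable proteins
    c(0.70, 0.60, 0.80, 0.60, 0.40, 0.80)    # moderately high throughout
  )
  colnames(base) <- SIXVP_VARIABLES
  base[rep_len(seq_len(nrow(base)), n_groups), , drop = FALSE]
}

## gene-level draws shared by all organisms of a clade
draw_gene_effects <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  group <- rep_len(seq_len(cfg$n_groups), cfg$n_genes)  # cycle through groups
  names(group) <- genes
  complex <- rep(NA_integer_, cfg$n_genes)
  names(complex) <- genes
  for (k in seq_len(cfg$n_complexes)) {
    members <- names(group)[group == k][seq_len(cfg$complex_size)]
    complex[members] <- k
  }
  sd_g <- ifelse(is.na(complex), cfg$within_group_sd, cfg$within_complex_sd)
  L <- stats::rnorm(cfg$n_genes, 0, cfg$latent_level_sd)
  eps <- matrix(stats::rnorm(cfg$n_genes * 4L), cfg$n_genes, 4L,
                dimnames = list(genes, c("TR", "RS", "TLRi", "PS"))) * sd_g
  list(genes = genes, group = group, complex = complex, L = L, eps = eps)
}

## true six-variable values for one organism given its archetypes
synth_truth <- function(effects, archetypes, cfg) {
  a <- archetypes[effects$group, , drop = FALSE]
  eff <- cfg$archetype_effect
  logTR <- eff * (a[, "TR"] - 0.5) + effects$L + effects$eps[, "TR"]
  logRS <- eff * (a[, "RS"] - 0.5) + cfg$rs_latent_coupling * effects$L +
    effects$eps[, "RS"]
  logTLRi <- eff * (a[, "TLRi"] - 0.5) + cfg$potentiation_slope * effects$L +
    effects$eps[, "TLRi"]
  logPS <- eff * (a[, "PS"] - 0.5) + effects$eps[, "PS"]
  m <- cbind(TR = exp(logTR), RS = exp(logRS),
             RA = exp(logTR + logRS),
             TLRi = exp(logTLRi), PS = exp(logPS),
             PA = exp(logTR + logRS + logTLRi + logPS))
  rownames(m) <- effects$genes
  m
}

## toy GO DAG: BP root -> 2 branches -> mids -> one leaf term per group,
## plus a CC arm whose leaves are the complexes (depth 3-4 overall)
synth_go_graph <- function(cfg) {
  groups <- seq_len(cfg$n_groups)
  leaf_bp <- sprintf("GO:G%03d", groups)
  n_mid <- max(1L, ceiling(cfg$n_groups / 2L))
  mids <- sprintf("GO:M%03d", seq_len(n_mid))
  branches <- c("GO:B001", "GO:B002")[seq_len(min(2L, n_mid))]
  terms <- data.frame(
    id = c("GO:ROOTBP", branches, mids, leaf_bp,
           "GO:ROOTCC", "GO:CPLX",
           if (cfg$n_complexes > 0L) sprintf("GO:C%03d", seq_len(cfg$n_complexes))),
    namespace = c(rep("BP", 1L + length(branches) + n_mid + cfg$n_groups),
                  rep("CC", 2L + cfg$n_complexes)),
    stringsAsFactors = FALSE
  )
  terms$name <- terms$id
  parents <- stats::setNames(vector("list", nrow(terms)), terms$id)
  for (b in branches) parents[[b]] <- "GO:ROOTBP"
  for (i in seq_along(mids)) {
    parents[[mids[i]]] <- branches[((i - 1L) %% length(branches)) + 1L]
  }
  for (k in groups) {
    parents[[leaf_bp[k]]] <- mids[((k - 1L) %% n_mid) + 1L]
  }
  parents[["GO:CPLX"]] <- "GO:ROOTCC"
  if (cfg$n_complexes > 0L) {
    for (k in seq_len(cfg$n_complexes)) {
      parents[[sprintf("GO:C%03d", k)]] <- "GO:CPLX"
    }
  }
  go_graph(terms, parents)
}

synth_annotations <- function(effects, graph, cfg) {
  direct <- list()
  for (k in seq_len(cfg$n_groups)) {
    direct[[sprintf("GO:G%03d", k)]] <- names(effects$group)[effects$group == k]
  }
  ## partial overlap: a slice of each group is also annotated to the next
  if (cfg$annotation_overlap > 0 && cfg$n_groups > 1L) {
    for (k in seq_len(cfg$n_groups)) {
      members <- names(effects$group)[effects$group == k]
      n_extra <- floor(cfg$annotation_overlap * length(members))
      if (n_extra >= 1L) {
        sibling <- sprintf("GO:G%03d", (k %% cfg$n_groups) + 1L)
        direct[[sibling]] <- c(direct[[sibling]], members[seq_len(n_extra)])
      }
    }
  }
  for (k in seq_len(cfg$n_complexes)) {
    direct[[sprintf("GO:C%03d", k)]] <-
      names(effects$complex)[!is.na(effects$complex) & effects$complex == k]
  }
  annotation_set(direct, graph)
}

#' Generate one organism's synthetic datasets
#'
#' Draws the planted truth for a single organism and wraps it in the file
#' forms the pipeline consumes: per-variable replicate expression tables
#' with lognormal noise and missing cells, a toy GO graph whose BP leaf
#' terms are the planted groups and whose CC leaves are the complexes, the
#' matching annotation set, a complex catalog and the ground-truth labels.
#'
#' @param config A [sixvp_sim_config()].
#' @param organism Organism label.
#' @return List with `truth` (a `sixvp_matrix` of exact values), `tables`
#'   (per variable, a list of replicate [expression_table()]s), `graph`,
#'   `annotations`, `complexes`, and `ground_truth` (`group`, `complex`,
#'   `archetypes`, `latent`).
#' @export
generate_organism <- function(config, organism = "A") {
  stopifnot(inherits(config, "sixvp_sim_config"))
  set.seed(config$seed)
  effects <- draw_gene_effects(config)
  truth <- synth_truth(effects, config$group_profile_archetypes, config)
  out <- replicate_tables(truth, config, organism)
  graph <- synth_go_graph(config)
  anns <- synth_annotations(effects, graph, config)
  complexes <- list()
  for (k in seq_len(config$n_complexes)) {
    complexes[[sprintf("CPX%03d", k)]] <-
      names(effects$complex)[!is.na(effects$complex) & effects$complex == k]
  }
  list(
    truth = as_sixvp_matrix(truth, organism),
    tables = out,
    graph = graph,
    annotations = anns,
    complexes = complexes,
    ground_truth = list(group = effects$group, complex = effects$complex,
                        archetypes = config$group_profile_archetypes,
                        latent = stats::setNames(effects$L, effects$genes))
  )
}

replicate_tables <- function(truth, cfg, organism) {
  out <- list()
  for (v in SIXVP_VARIABLES) {
    reps <- list()
    for (r in seq_len(cfg$replicate_count)) {
      vals <- truth[, v] *
        exp(stats::rnorm(nrow(truth), 0, cfg$replicate_noise_sd))
      if (cfg$missing_rate > 0) {
        drop <- stats::runif(length(vals)) < cfg$missing_rate
        vals[drop] <- NA_real_
      }
      reps[[r]] <- expression_table(vals, organism = organism, variable = v,
                                    source_id = sprintf("%s_%s_rep%d",
                                                        organism, v, r))
    }
    out[[v]] <- reps
  }
  out
}

#' Generate a clade of organisms with drifting expression strategies
#'
#' Gene-level effects (group membership, latent levels, within-group noise)
#' are drawn once at the root and shared by all organisms; each organism's
#' group archetypes are obtained by drifting the root archetypes along the
#' planted tree, adding Normal(0, divergence_rate x branch length) per
#' component and clipping to \[0, 1\].  With zero divergence all organisms
#' carry identical truth.  Ortholog maps are identity maps with optional
#' dropout.
#'
#' @param config A [sixvp_sim_config()]; its `organism_tree` must have at
#'   least 2 leaves.
#' @return List with `organisms` (named list of per-organism outputs as in
#'   [generate_organism()]), `tree` (the planted `phylo`), `ortholog_maps`
#'   (reference = first leaf), `graph`, `annotations` (reference),
#'   `ground_truth` (shared labels plus per-organism archetypes).
#' @export
generate_clade <- function(config) {
  stopifnot(inherits(config, "sixvp_sim_config"))
  tree <- ape::read.tree(text = config$organism_tree)
  if (is.null(tree) || length(tree$tip.label) < 2L) {
    stop("organism_tree must have at least 2 leaves", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("organism_tree must carry branch lengths", call. = FALSE)
  }
  set.seed(config$seed)
  effects <- draw_gene_effects(config)
  ## drift archetypes from the root along each edge (preorder)
  n_nodes <- max(tree$edge)
  arch <- vector("list", n_nodes)
  root <- length(tree$tip.label) + 1L
  arch[[root]] <- config$group_profile_archetypes
  done <- rep(FALSE, nrow(tree$edge))
  while (!all(done)) {
    progressed <- FALSE
    for (e in which(!done)) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      if (is.null(arch[[parent]])) next
      len <- tree$edge.length[e]
      drift <- matrix(stats::rnorm(length(arch[[parent]]), 0,
                                   config$divergence_rate * len),
                      nrow = nrow(arch[[parent]]))
      a <- pmin(pmax(arch[[parent]] + drift, 0), 1)
      dimnames(a) <- dimnames(arch[[parent]])
      arch[[child]] <- a
      done[e] <- TRUE
      progressed <- TRUE
    }
    if (!progressed) stop("malformed organism tree", call. = FALSE)
  }
  graph <- synth_go_graph(config)
  anns <- synth_annotations(effects, graph, config)
  organisms <- list()
  per_org_arch <- list()
  for (i in seq_along(tree$tip.label)) {
    o <- tree$tip.label[i]
    truth <- synth_truth(effects, arch[[i]], config)
    organisms[[o]] <- list(
      truth = as_sixvp_matrix(truth, o),
      tables = replicate_tables(truth, config, o),
      graph = graph,
      annotations = anns,
      complexes = NULL,
      ground_truth = list(group = effects$group, complex = effects$complex,
                          archetypes = arch[[i]],
                          latent = stats::setNames(effects$L, effects$genes))
    )
    per_org_arch[[o]] <- arch[[i]]
  }
  ref <- tree$tip.label[1L]
  ortholog_maps <- list()
  for (o in tree$tip.label) {
    if (o == ref) { ortholog_maps[[o]] <- NULL; next }
    genes <- effects$genes
    if (config$ortholog_dropout > 0) {
      keep <- stats::runif(length(genes)) >= config$ortholog_dropout
      genes <- genes[keep]
    }
    ortholog_maps[[o]] <- stats::setNames(genes, genes)
  }
  list(organisms = organisms, tree = tree, reference = ref,
       ortholog_maps = ortholog_maps, graph = graph, annotations = anns,
       ground_truth = list(group = effects$group, complex = effects$complex,
                           archetypes = per_org_arch,
                           latent = stats::setNames(effects$L, effects$genes)))
}
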