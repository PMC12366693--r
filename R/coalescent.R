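#' Locus configuration for the genetic simulation
#'
#' Defaults: 50 independent loci of 1000 bp, no recombination within a
#' locus, free recombination between loci, mutation rate 2.15e-8 per site
#' per generation.
#'
#' @param n_loci number of independent loci (>= 1).
#' @param locus_length locus length in bp.
#' @param mu mutation rate per site per generation.
#' @return a `locus_config` list.
#' @export
locus_config <- function(n_loci = 50, locus_length = 1000, mu = 2.15e-8) {
  stopifnot(n_loci >= 1, locus_length >= 1, mu > 0)
  structure(list(n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length), mu = mu),
            class = "locus_config")
}

#' Trace gene genealogies backward through a recorded demography
#'
#' One gene copy per sampled individual (pseudo-haploid representation) is
#' traced backward: each generation a lineage picks its origin in
#' proportion to the recorded forward inflows of its deme and layer
#' (residents, stepping-stone immigrants, LDD immigrants and, for the FA
#' layer, admixture transfers from HG, which move the lineage to the HG
#' layer), then co-located lineages coalesce pairwise with probability
#' `1/N`. Lineages reaching generation 0 coalesce in a panmictic ancestral
#' pool of size `K_anc`; FA lineages pre-dating the FA seeding coalesce in
#' a panmictic source pool of the FA carrying capacity.
#'
#' @param db a `demography_db`.
#' @param scheme a [sampling_scheme()]; `db` must satisfy
#'   [demographic_filter()] for it.
#' @param n_loci number of independent genealogies to draw.
#' @param K_anc ancestral pool size (default: the HG carrying capacity).
#' @return a `gene_forest`: edge/node tables over all loci plus tip
#'   metadata. Tips are numbered in sample order; `tip_label` holds
#'   per-individual labels `<sample>.<i>`.
#' @export
trace_genealogies <- function(db, scheme, n_loci = 1, K_anc = NULL) {
  stopifnot(inherits(db, "demography_db"), nrow(scheme) >= 1)
  if (is.null(K_anc)) K_anc <- db$hg$K
  demes <- scheme_demes(db$world, scheme)
  res <- cpp_trace_loci(db$N_hg, db$N_fa, db$postadm_fa, db$res_hg,
                        db$res_fa, db$imm_hg, db$imm_fa, db$ldd, db$A,
                        db$world$n_cols, db$world$n_rows,
                        as.integer(demes),
                        as.integer(scheme$layer == "FA"),
                        as.integer(scheme$generation),
                        as.integer(scheme$n), as.integer(n_loci),
                        as.integer(db$fa_origin), as.integer(db$fa_onset),
                        db$fa$K, K_anc)
  res$n_loci <- as.integer(n_loci)
  res$tip_label <- unlist(lapply(seq_len(nrow(scheme)), function(i)
    paste0(scheme$label[i], ".", seq_len(scheme$n[i]))))
  res$scheme <- scheme
  class(res) <- "gene_forest"
  res
}

#' Extract one locus genealogy from a forest
#'
#' @param forest a [trace_genealogies()] result.
#' @param locus locus index.
#' @return a `gene_tree`: list with `edges` (parent, child), `time` (per
#'   node, simulation generations; ancestral-pool nodes are negative),
#'   `n_tips` and `tip_label`.
#' @export
locus_tree <- function(forest, locus = 1) {
  e <- forest$edges[forest$edges$locus == locus, c("parent", "child")]
  nd <- forest$nodes[forest$nodes$locus == locus, ]
  n_nodes <- max(forest$n_tips, e$parent, nd$id)
  time <- rep(NA_real_, n_nodes)
  time[seq_len(forest$n_tips)] <- forest$tip_time
  time[nd$id] <- nd$time
  structure(list(edges = e, time = time, n_tips = forest$n_tips,
                 tip_label = forest$tip_label), class = "gene_tree")
}

#' Single-locus genealogy (convenience wrapper)
#' @inheritParams trace_genealogies
#' @export
trace_locus <- function(db, scheme, K_anc = NULL) {
  locus_tree(trace_genealogies(db, scheme, n_loci = 1, K_anc = K_anc), 1)
}

#' Time to the most recent common ancestor of a genealogy, in generations
#'
#' Measured from the most recent tip back to the root.
#' @param tree a `gene_tree`.
#' @export
tmrca <- function(tree) {
  root <- setdiff(tree$edges$parent, tree$edges$child)
  max(tree$time[seq_len(tree$n_tips)]) - tree$time[root]
}

#' Convert a gene tree to an ape phylo object
#'
#' Branch lengths are in generations. Multifurcations (simultaneous
#' multiple mergers) are preserved.
#' @param tree a `gene_tree`.
#' @return an [ape::read.tree()]-compatible `phylo`.
#' @export
as_phylo <- function(tree) {
  ids <- sort(unique(c(tree$edges$parent, tree$edges$child)))
  internal <- setdiff(ids, seq_len(tree$n_tips))
  root <- setdiff(tree$edges$parent, tree$edges$child)
  internal <- c(root, setdiff(internal, root))  # ape wants root first
  remap <- integer(max(ids))
  remap[seq_len(tree$n_tips)] <- seq_len(tree$n_tips)
  remap[internal] <- tree$n_tips + seq_along(internal)
  phy <- list(edge = cbind(remap[tree$edges$parent], remap[tree$edges$child]),
              edge.length = tree$time[tree$edges$child] -
                tree$time[tree$edges$parent],
              tip.label = tree$tip_label, Nnode = length(internal))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

mutate_bases <- function(seqv, pos) {
  # substitute with a uniformly chosen different base (finite sites);
  # repeat hits at one site compose sequentially
  if (length(pos) == 0) return(seqv)
  steps <- sample.int(3, length(pos), replace = TRUE)
  if (anyDuplicated(pos)) {
    for (i in seq_along(pos))
      seqv[pos[i]] <- 1L + (seqv[pos[i]] - 1L + steps[i]) %% 4L
  } else {
    seqv[pos] <- 1L + (seqv[pos] - 1L + steps) %% 4L
  }
  seqv
}

#' Drop mutations on a genealogy and emit pseudo-haploid sequences
#'
#' Mutation counts per branch are Poisson with mean
#' `branch_length * locus_length * mu`; each mutation hits a uniform site
#' and substitutes a uniformly chosen different base (finite-sites model).
#' The root sequence is uniform random.
#'
#' @param tree a `gene_tree`.
#' @param cfg a [locus_config()] (`locus_length` and `mu` are used).
#' @return integer matrix `locus_length x n_tips` with bases coded 1..4
#'   (A, C, G, T), columns named by tip labels.
#' @export
drop_mutations <- function(tree, cfg) {
  L <- cfg$locus_length
  root <- setdiff(tree$edges$parent, tree$edges$child)
  stopifnot(length(root) == 1)
  n_nodes <- length(tree$time)
  seqs <- vector("list", n_nodes)
  seqs[[root]] <- sample.int(4, L, replace = TRUE)
  # parents always strictly older than children: process edges oldest-first
  ord <- order(tree$time[tree$edges$parent])
  for (i in ord) {
    p <- tree$edges$parent[i]
    ch <- tree$edges$child[i]
    len <- tree$time[ch] - tree$time[p]
    nmut <- rpois(1, len * L * cfg$mu)
    seqs[[ch]] <- mutate_bases(seqs[[p]],
                               if (nmut > 0) sample.int(L, nmut,
                                                        replace = TRUE)
                               else integer(0))
  }
  out <- do.call(cbind, seqs[seq_len(tree$n_tips)])
  colnames(out) <- tree$tip_label
  out
}

#' Apply sequencing error to a sequence panel
#'
#' Independently for each site of each genome, with probability `eps` the
#' base is replaced by one of the other three, uniformly.
#'
#' @param panel a `sequence_panel` (or a single locus matrix).
#' @param eps per-site error probability in `[0, 1]`.
#' @return the panel with errors applied (`eps` recorded in the metadata).
#' @export
apply_sequencing_error <- function(panel, eps) {
  stopifnot(eps >= 0, eps <= 1)
  err1 <- function(m) {
    n_cells <- length(m)
    n_err <- rbinom(1, n_cells, eps)
    if (n_err > 0) {
      pos <- sample.int(n_cells, n_err)
      m[pos] <- 1L + (m[pos] - 1L + sample.int(3, n_err, replace = TRUE)) %% 4L
    }
    m
  }
  if (is.matrix(panel)) return(err1(panel))
  stopifnot(inherits(panel, "sequence_panel"))
  panel$loci <- lapply(panel$loci, err1)
  panel$eps_applied <- eps
  panel
}

#' Simulate a full sequence panel for a sampling scheme
#'
#' Traces `cfg$n_loci` independent genealogies through the recorded
#' demography, drops mutations on each, and applies sequencing error once
#' per genome. Same-seed runs are bit-identical.
#'
#' @param db a `demography_db` that passes the demographic filter.
#' @param scheme a [sampling_scheme()].
#' @param cfg a [locus_config()].
#' @param eps sequencing error rate.
#' @param K_anc ancestral pool size (default: HG carrying capacity).
#' @return a `sequence_panel`: per-locus base matrices plus per-genome
#'   metadata (sample, layer, coordinates, age, generation).
#' @export
simulate_genomes <- function(db, scheme, cfg = locus_config(), eps = 0,
                             K_anc = NULL) {
  forest <- trace_genealogies(db, scheme, n_loci = cfg$n_loci, K_anc = K_anc)
  loci <- lapply(seq_len(cfg$n_loci), function(l)
    drop_mutations(locus_tree(forest, l), cfg))
  meta <- data.frame(
    genome = forest$tip_label,
    sample = scheme$label[forest$tip_sample],
    layer = scheme$layer[forest$tip_sample],
    x = scheme$x[forest$tip_sample], y = scheme$y[forest$tip_sample],
    mean_age = scheme$mean_age[forest$tip_sample],
    generation = scheme$generation[forest$tip_sample])
  panel <- structure(list(loci = loci, meta = meta, cfg = cfg,
                          eps_applied = 0), class = "sequence_panel")
  if (eps > 0) panel <- apply_sequencing_error(panel, eps)
  panel
}

#' @export
print.sequence_panel <- function(x, ...) {
  cat(sprintf("sequence_panel: %d genomes x %d loci x %d bp (eps = %g)\n",
              nrow(x$meta), length(x$loci), x$cfg$locus_length,
              x$eps_applied))
  invisible(x)
}

#' Write a sequence panel as one multi-FASTA per locus
#'
#' Sequence IDs are the individual genome labels.
#' @param panel a `sequence_panel`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_panel_fasta <- function(panel, dir) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to write FASTA")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")
  paths <- character(length(panel$loci))
  for (l in seq_along(panel$loci)) {
    m <- panel$loci[[l]]
    ss <- Biostrings::DNAStringSet(apply(m, 2, function(col)
      paste(bases[col], collapse = "")))
    names(ss) <- colnames(m)
    paths[l] <- file.path(dir, sprintf("locus_%03d.fasta", l))
    Biostrings::writeXStringSet(ss, paths[l])
  }
  invisible(paths)
}
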