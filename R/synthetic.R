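#' @include AllClasses.R hetgraph.R
NULL

#' Configuration of the planted-module synthetic graph
#'
#' The generator emulates a drug-gene-disease heterogeneous graph in which
#' drug-disease associations are mediated by short gene paths: genes are
#' partitioned into latent functional modules wired as a planted-partition
#' graph, each drug/disease is assigned 1-2 modules and anchored to
#' `k_anchor` genes drawn from them, and a pair is a true association iff
#' the two entities share a module. A `noise_rate` fraction of pair labels
#' is then flipped.
#'
#' @param n_drugs,n_diseases,n_genes node counts.
#' @param n_modules number of latent gene modules.
#' @param genes_per_module genes assigned to each module.
#' @param p_intra,p_inter gene-gene edge probabilities within / between
#'   modules (`p_intra > p_inter`).
#' @param k_anchor gene attachments per drug/disease.
#' @param p_two_modules probability that an entity carries a second module
#'   (multi-function drugs/diseases). Kept below 0.5 so that module-overlap
#'   positives stay under half of all pairs, leaving a negative pool large
#'   enough for 1:1 negative sampling.
#' @param noise_rate fraction of drug-disease labels flipped, in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return A validated config list of class `synthConfig`.
#' @export
synthConfig <- function(n_drugs = 20L, n_diseases = 20L, n_genes = 60L,
                        n_modules = 3L, genes_per_module = 20L,
                        p_intra = 0.35, p_inter = 0.02, k_anchor = 3L,
                        p_two_modules = 0.2, noise_rate = 0.05, seed = 7L) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_diseases = as.integer(n_diseases),
              n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              genes_per_module = as.integer(genes_per_module),
              p_intra = p_intra, p_inter = p_inter, k_anchor = as.integer(k_anchor),
              p_two_modules = p_two_modules, noise_rate = noise_rate,
              seed = as.integer(seed))
  stopIfNot(cfg$n_modules * cfg$genes_per_module <= cfg$n_genes,
            "n_modules * genes_per_module must be <= n_genes", class = "geneDRConfigError")
  stopIfNot(cfg$p_intra > cfg$p_inter, "p_intra must exceed p_inter",
            class = "geneDRConfigError")
  stopIfNot(cfg$noise_rate >= 0 && cfg$noise_rate < 0.5,
            "noise_rate must lie in [0, 0.5)", class = "geneDRConfigError")
  stopIfNot(cfg$p_intra <= 1 && cfg$p_inter >= 0, "edge probabilities must lie in [0,1]",
            class = "geneDRConfigError")
  stopIfNot(cfg$k_anchor >= 1L && cfg$k_anchor <= cfg$genes_per_module,
            "k_anchor must lie in 1..genes_per_module", class = "geneDRConfigError")
  stopIfNot(cfg$p_two_modules >= 0 && cfg$p_two_modules < 0.5,
            "p_two_modules must lie in [0, 0.5)", class = "geneDRConfigError")
  class(cfg) <- c("synthConfig", "list")
  cfg
}

.pairKey <- function(d, z) paste(d, z, sep = ":")

#' Generate a synthetic heterogeneous graph with planted gene-path signal
#'
#' Fully determined by `config$seed`. Drug-disease edges of the returned
#' graph carry the label noise; the returned truth records the noiseless
#' module structure.
#'
#' @param config a [synthConfig()].
#' @return List with `graph` (a [HeteroGraph-class]) and `truth`, a list
#'   holding `module_of_gene` (gene id -> module), `modules_of_entity`
#'   (drug/disease id -> module ids), `positive_pairs` (noiseless 2-column
#'   id matrix) and `flipped_pairs`.
#' @export
generateSynthetic <- function(config) {
  stopIfNot(inherits(config, "synthConfig"), "config must come from synthConfig()",
            class = "geneDRConfigError")
  withSeed(config$seed, {
    registry <- nodeRegistry()
    registry <- addNodes(registry, sprintf("DR%03d", seq_len(config$n_drugs)), "drug")
    registry <- addNodes(registry, sprintf("DI%03d", seq_len(config$n_diseases)), "disease")
    registry <- addNodes(registry, sprintf("G%04d", seq_len(config$n_genes)), "gene")
    drugs <- nodesOfType(registry, "drug")
    diseases <- nodesOfType(registry, "disease")
    genes <- nodesOfType(registry, "gene")

    ## module assignment: first n_modules*genes_per_module genes in blocks,
    ## leftovers are background genes (module 0, never anchored)
    module_of_gene <- integer(config$n_genes)
    core <- seq_len(config$n_modules * config$genes_per_module)
    module_of_gene[core] <- rep(seq_len(config$n_modules), each = config$genes_per_module)
    names(module_of_gene) <- as.character(genes)

    ## gene-gene planted partition
    gp <- t(utils::combn(genes, 2L))
    same <- module_of_gene[as.character(gp[, 1L])] == module_of_gene[as.character(gp[, 2L])] &
            module_of_gene[as.character(gp[, 1L])] > 0L
    p <- ifelse(same, config$p_intra, config$p_inter)
    gg <- gp[stats::runif(nrow(gp)) < p, , drop = FALSE]

    ## 1-2 modules per entity, uniform; anchors drawn from own modules
    assignEntity <- function(ids) {
      out <- vector("list", length(ids))
      names(out) <- as.character(ids)
      for (i in seq_along(ids)) {
        k <- 1L + (stats::runif(1L) < config$p_two_modules)
        out[[i]] <- sort(sample(seq_len(config$n_modules), min(k, config$n_modules)))
      }
      out
    }
    mod_drug <- assignEntity(drugs)
    mod_dis <- assignEntity(diseases)
    anchorEdges <- function(ids, mods) {
      from <- integer(); to <- integer()
      for (i in seq_along(ids)) {
        pool <- genes[module_of_gene %in% mods[[i]]]
        sel <- sample(pool, min(config$k_anchor, length(pool)))
        from <- c(from, rep(ids[i], length(sel))); to <- c(to, sel)
      }
      cbind(from, to)
    }
    rg <- anchorEdges(drugs, mod_drug)
    dg <- anchorEdges(diseases, mod_dis)

    ## noiseless positives: module overlap
    overlap <- outer(seq_along(drugs), seq_along(diseases), Vectorize(function(i, j)
      length(intersect(mod_drug[[i]], mod_dis[[j]])) > 0L))
    pos <- which(overlap, arr.ind = TRUE)
    positive_pairs <- cbind(drugs[pos[, 1L]], diseases[pos[, 2L]])
    positive_pairs <- positive_pairs[order(positive_pairs[, 1L], positive_pairs[, 2L]), , drop = FALSE]

    ## label noise: flip a noise_rate fraction of all (drug, disease) pairs
    all_pairs <- as.matrix(expand.grid(drugs, diseases))
    n_flip <- floor(config$noise_rate * nrow(all_pairs))
    flip_idx <- if (n_flip > 0L) sample(nrow(all_pairs), n_flip) else integer()
    labels <- matrix(FALSE, config$n_drugs, config$n_diseases,
                     dimnames = list(as.character(drugs), as.character(diseases)))
    labels[cbind(as.character(positive_pairs[, 1L]), as.character(positive_pairs[, 2L]))] <- TRUE
    for (k in flip_idx) {
      i <- as.character(all_pairs[k, 1L]); j <- as.character(all_pairs[k, 2L])
      labels[i, j] <- !labels[i, j]
    }
    obs <- which(labels, arr.ind = TRUE)
    dd <- cbind(as.integer(rownames(labels)[obs[, 1L]]),
                as.integer(colnames(labels)[obs[, 2L]]))

    graph <- buildHeteroGraph(registry, list(
      "drug-disease" = dd, "drug-gene" = rg, "disease-gene" = dg, "gene-gene" = gg))
    truth <- list(module_of_gene = module_of_gene,
                  modules_of_entity = c(mod_drug, mod_dis),
                  positive_pairs = positive_pairs,
                  flipped_pairs = all_pairs[flip_idx, , drop = FALSE],
                  config = config)
    list(graph = graph, truth = truth)
  })
}

#' Fraction of true associations reachable through short gene paths
#'
#' For every noiseless positive (drug, disease) pair, checks whether some
#' path drug - gene (- gene ...) - disease with at most 4 genes exists,
#' i.e. a drug-anchored gene and a disease-anchored gene at gene-gene
#' distance at most 3. Used to certify that a synthetic fixture is
#' learnable from path information before it enters end-to-end evaluation.
#'
#' @param truth truth list from [generateSynthetic()].
#' @param graph the matching [HeteroGraph-class].
#' @param max_genes maximum number of genes on the connecting path.
#' @return Fraction in `[0, 1]`.
#' @export
expectedSignal <- function(truth, graph, max_genes = 4L) {
  pos <- truth$positive_pairs
  if (nrow(pos) == 0L) return(NA_real_)
  gg <- relationEdges(graph, "gene-gene")
  genes <- nodesOfType(graph, "gene")
  ig <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  gidx <- match(seq_len(nodeCount(graph)), genes)  # node id -> gene index
  if (nrow(gg))
    ig <- igraph::add_edges(ig, t(cbind(gidx[gg[, 1L]], gidx[gg[, 2L]])))
  dmat <- igraph::distances(ig)
  ok <- vapply(seq_len(nrow(pos)), function(k) {
    ga <- neighborsOf(graph, pos[k, 1L], "drug-gene")
    gb <- neighborsOf(graph, pos[k, 2L], "disease-gene")
    if (!length(ga) || !length(gb)) return(FALSE)
    min(dmat[gidx[ga], gidx[gb]]) <= max_genes - 1L
  }, TRUE)
  mean(ok)
}

#' Write a synthetic dataset to disk
#'
#' Writes the four edge-list TSVs plus manifest (via [writeDataset()]), a
#' `labels.tsv` of all drug-disease pairs with their noisy labels, and a
#' `truth.json` with the module structure.
#'
#' @param sim result of [generateSynthetic()].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
writeSynthetic <- function(sim, dir) {
  writeDataset(sim$graph, dir)
  g <- sim$graph
  drugs <- nodesOfType(g, "drug"); diseases <- nodesOfType(g, "disease")
  dd <- relationEdges(g, "drug-disease")
  key <- .pairKey(dd[, 1L], dd[, 2L])
  pairs <- expand.grid(drug = drugs, disease = diseases)
  lab <- as.integer(.pairKey(pairs$drug, pairs$disease) %in% key)
  utils::write.table(
    data.frame(drug = nodeName(g, pairs$drug), disease = nodeName(g, pairs$disease),
               label = lab),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(module_of_gene = as.list(truth$module_of_gene),
         modules_of_entity = truth$modules_of_entity,
         positive_pairs = truth$positive_pairs,
         config = unclass(truth$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
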