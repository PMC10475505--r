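#' @include AllClasses.R evaluation.R synthetic.R
NULL

#' Validate a dataset and print its statistics
#'
#' Loads the four edge lists of a manifest (or takes a built graph), checks
#' type consistency, and reports node/edge counts, input duplicate rates,
#' drug/disease nodes without any gene neighbor, and gene-gene component
#' counts -- the same shape of summary the real datasets are described by.
#'
#' @param x manifest path or a [HeteroGraph-class].
#' @param quiet suppress printing.
#' @return Invisibly, a list with `counts`, `edges`, `duplicate_rows`,
#'   `anchors_without_genes` (ids), `gene_components`.
#' @export
validateDataset <- function(x, quiet = FALSE) {
  dup <- NA_integer_
  if (is.character(x)) {
    man <- yaml::read_yaml(x)
    base <- dirname(normalizePath(x))
    dup <- 0L
    for (key in unname(.MANIFEST_KEYS)) {
      f <- man[[key]]
      if (!is.null(f) && !file.exists(f)) f <- file.path(base, f)
      stopIfNot(!is.null(f) && file.exists(f),
                sprintf("missing dataset file for '%s': %s", key,
                        if (is.null(man[[key]])) "<unset>" else man[[key]]),
                class = "geneDRIOError")
      rows <- readLines(f, warn = FALSE)
      rows <- rows[!grepl("^\\s*(#|$)", rows)]
      dup <- dup + sum(duplicated(rows))
    }
    graph <- readDatasetManifest(x)
  } else graph <- x
  counts <- vapply(.NODE_TYPES, function(tt) length(nodesOfType(graph, tt)), 0L)
  edges <- vapply(.RELATIONS, function(r) edgeCount(graph, r), 0L)
  anchors <- c(nodesOfType(graph, "drug"), nodesOfType(graph, "disease"))
  iso <- anchors[vapply(anchors, function(a) {
    rel <- if (nodeType(graph, a) == "drug") "drug-gene" else "disease-gene"
    nodeDegree(graph, a, rel) == 0L
  }, TRUE)]
  gg <- relationEdges(graph, "gene-gene")
  genes <- nodesOfType(graph, "gene")
  ncomp <- if (length(genes)) {
    ig <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
    if (nrow(gg)) ig <- igraph::add_edges(ig, t(cbind(match(gg[, 1L], genes),
                                                      match(gg[, 2L], genes))))
    igraph::count_components(ig)
  } else 0L
  rep <- list(counts = counts, edges = edges, duplicate_rows = dup,
              anchors_without_genes = iso, gene_components = ncomp)
  if (!quiet) {
    cat(sprintf("Nodes: %d drugs, %d diseases, %d genes\n",
                counts[["drug"]], counts[["disease"]], counts[["gene"]]))
    for (r in .RELATIONS) cat(sprintf("  %-12s %6d edges\n", r, edges[[r]]))
    if (!is.na(dup)) cat(sprintf("Duplicate input rows: %d\n", dup))
    cat(sprintf("Drug/disease nodes without gene neighbors: %d%s\n", length(iso),
                if (length(iso)) paste0(" (", paste(nodeName(graph, iso), collapse = ", "), ")")
                else ""))
    cat(sprintf("Gene-gene connected components: %d\n", ncomp))
  }
  invisible(rep)
}

#' Run the ablation suite on one graph
#'
#' Cross-validates each requested variant under each seed and tabulates
#' mean metrics per variant (plus the median AUC across seeds), mirroring
#' the design of the method's ablation comparison.
#'
#' @param graph a [HeteroGraph-class].
#' @param config base [genedrConfig()]; `variant` and `seed` are overridden.
#' @param variants character vector of variants to run.
#' @param seeds integer seeds.
#' @param folds folds evaluated per run (default all).
#' @param out_dir optional directory for per-run JSON results.
#' @return data.frame, one row per variant: mean aupr/auc/f1/recall across
#'   runs and `median_auc` across seeds. Attribute `runs` holds per-run rows.
#' @export
runAblationSuite <- function(graph, config, variants = c("full", "no_lstm", "no_gmp"),
                             seeds = config$seed, folds = NULL, out_dir = NULL) {
  stopIfNot(length(variants) >= 1L, "at least one variant required",
            class = "geneDRConfigError")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  runs <- list()
  for (v in variants) for (s in seeds) {
    cfg <- config
    cfg$variant <- v
    cfg$seed <- as.integer(s)
    cv <- crossValidate(graph, cfg, folds = folds)
    row <- data.frame(variant = v, seed = s, t(cv$mean))
    runs[[length(runs) + 1L]] <- row
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(variant = v, seed = s, per_fold = cv$per_fold,
             mean = as.list(cv$mean), sd = as.list(cv$sd)),
        file.path(out_dir, sprintf("cv_%s_seed%d.json", v, s)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  runs <- do.call(rbind, runs)
  tab <- do.call(rbind, lapply(unique(runs$variant), function(v) {
    sub <- runs[runs$variant == v, , drop = FALSE]
    data.frame(variant = v, aupr = mean(sub$aupr), auc = mean(sub$auc),
               f1 = mean(sub$f1), recall = mean(sub$recall),
               median_auc = stats::median(sub$auc))
  }))
  if (!is.null(out_dir))
    utils::write.table(tab, file.path(out_dir, "ablation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  attr(tab, "runs") <- runs
  tab
}
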