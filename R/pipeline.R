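defaultPipelineConfig <- function() {
  list(
    simulate = TRUE,
    inputs = list(matrix = NULL, metadata = NULL, promoters = NULL,
                  genome = NULL, gff = NULL, motifs = NULL,
                  term_map = NULL, blast_ab = NULL, blast_ba = NULL),
    simulate_params = list(n_genes = 1000, n_modules = 10,
                           module_size = 15, neg_fraction = 0.2,
                           noise_sd = 0.25, deg_genes = 50,
                           deg_effect = 2, promoter_length = 500,
                           motif = "CACGTG", motif_planted_rate = 3,
                           motif_background_rate = 0.5,
                           n_orthologs_a = 40, n_orthologs_b = 40,
                           true_pair_fraction = 0.8),
    threshold = list(quantile = 0.05, sd_multiplier = 3,
                     aggregate = "min"),
    network = list(pos_cutoff = 0.65, neg_cutoff = -0.45,
                   cutoff_mode = "fixed", pos_percentile = 0.95,
                   neg_percentile = 0.05, rank_cutoff = 3,
                   mr_cutoff = 30),
    deg = list(fdr = 0.05, lfc = 1, floor = NULL, adjust = "BH",
               class_a = NULL, class_b = NULL),
    modules = list(k = 6, min_linking_nodes = 3, sign_mode = "both"),
    enrichment = list(n_perm = 1000, alpha = 0.05, adjust = "BY",
                      gene_list = NULL),
    orthology = list(top_n = 3, secondary_evalue = 1e-55),
    seed = 1)
}

#' Read and validate a pipeline configuration
#'
#' YAML file with the sections `simulate`, `inputs`,
#' `simulate_params`, `threshold`, `network`, `deg`, `modules`,
#' `enrichment`, `orthology`, `seed`; unknown keys are rejected and
#' numeric parameters are range-checked. Omitted keys take the
#' documented defaults.
#'
#' @param path path to a YAML config file, or a named list with the
#'   same structure.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config must be a YAML mapping")
  def <- defaultPipelineConfig()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(user)) {
    if (is.list(def[[sec]]) && !is.null(user[[sec]])) {
      bad <- setdiff(names(user[[sec]]), names(def[[sec]]))
      if (length(bad))
        stop("unknown key(s) in config section '", sec, "': ",
             paste(bad, collapse = ", "))
    }
  }
  cfg <- utils::modifyList(def, user)
  with(cfg, {
    if (network$rank_cutoff < 1) stop("network.rank_cutoff must be >= 1")
    if (network$mr_cutoff <= 0) stop("network.mr_cutoff must be > 0")
    if (!network$cutoff_mode %in% c("fixed", "percentile"))
      stop("network.cutoff_mode must be 'fixed' or 'percentile'")
    if (deg$fdr <= 0 || deg$fdr > 1) stop("deg.fdr must be in (0, 1]")
    if (modules$k < 3) stop("modules.k must be >= 3")
    if (modules$min_linking_nodes < 1)
      stop("modules.min_linking_nodes must be >= 1")
    if (enrichment$n_perm < 100) stop("enrichment.n_perm must be >= 100")
    if (enrichment$alpha <= 0 || enrichment$alpha >= 1)
      stop("enrichment.alpha must be in (0, 1)")
    if (threshold$quantile <= 0 || threshold$quantile > 0.5)
      stop("threshold.quantile must be in (0, 0.5]")
  })
  cfg
}

pipelineStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full multi-dimensional co-expression pipeline
#'
#' Orchestrates all stages from a configuration: expression input (read
#' or simulated), expression threshold, global / tissue-specific /
#' stress-treatment networks with pairwise comparisons, DEG calling,
#' tissue and stress overlays, CPM module detection with module links,
#' cis-element and term enrichment, orthologue calling, and a JSON run
#' manifest echoing all parameters and seeds. Each stage failure aborts
#' with the stage name.
#'
#' @param config config list or YAML path (see [readPipelineConfig()]).
#' @param outDir output directory (created if absent).
#' @param seed optional seed overriding `config$seed`.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  cfg <- readPipelineConfig(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outDir, f)
  manifest <- list(package = "mdcoexnet",
                   version = as.character(utils::packageVersion("mdcoexnet")),
                   config = cfg, outputs = character())
  addOut <- function(f) manifest$outputs <<- c(manifest$outputs, f)

  sp <- cfg$simulate_params
  truth <- NULL
  fs <- pipelineStage("expression_input", {
    if (isTRUE(cfg$simulate)) {
      sim <- generateExpression(nGenes = sp$n_genes,
                                nModules = sp$n_modules,
                                moduleSize = sp$module_size,
                                negFraction = sp$neg_fraction,
                                noiseSd = sp$noise_sd,
                                degGenes = sp$deg_genes,
                                degEffect = sp$deg_effect,
                                seed = cfg$seed)
      truth <- sim$truth
      writeExpressionMatrix(sim$fpkm, pth("expression.tsv"),
                            pth("sample_metadata.tsv"))
      addOut(c("expression.tsv", "sample_metadata.tsv"))
      sim$fpkm
    } else {
      if (is.null(cfg$inputs$matrix) || is.null(cfg$inputs$metadata))
        stop("inputs.matrix and inputs.metadata are required")
      readExpressionMatrix(cfg$inputs$matrix, cfg$inputs$metadata)
    }
  })

  thr <- pipelineStage("expression_threshold",
    computeExpressionThreshold(fs, quantile = cfg$threshold$quantile,
                               sdMultiplier = cfg$threshold$sd_multiplier,
                               aggregate = cfg$threshold$aggregate))
  floorVal <- if (is.null(cfg$deg$floor)) thr$global_threshold
  else cfg$deg$floor
  if (floorVal <= 0) floorVal <- 0.24

  cd <- SummarizedExperiment::colData(fs)
  allS <- colnames(fs)
  tissueS <- allS[!cd$treatment %in% c("PEG", "NaCl")]
  stressS <- allS[cd$treatment %in% c("CK", "PEG", "NaCl")]

  nets <- pipelineStage("networks", {
    buildOne <- function(samples, provenance) {
      net <- buildNetwork(fs, samples = samples,
                          posCutoff = cfg$network$pos_cutoff,
                          negCutoff = cfg$network$neg_cutoff,
                          cutoffMode = cfg$network$cutoff_mode,
                          posPercentile = cfg$network$pos_percentile,
                          negPercentile = cfg$network$neg_percentile,
                          rankCutoff = cfg$network$rank_cutoff,
                          mrCutoff = cfg$network$mr_cutoff,
                          provenance = provenance)
      writeEdgeList(net, pth(paste0("network_", provenance, ".tsv")))
      exportNetworkView(net, NULL, "graphml",
                        pth(paste0("network_", provenance, ".graphml")))
      exportNetworkView(net, NULL, "json",
                        pth(paste0("network_", provenance, ".json")))
      addOut(paste0("network_", provenance,
                    c(".tsv", ".graphml", ".json")))
      net
    }
    out <- list(global = buildOne(allS, "global"))
    if (length(tissueS) >= 3 && length(tissueS) < length(allS))
      out$tissue_specific <- buildOne(tissueS, "tissue_specific")
    if (length(stressS) >= 3 && length(stressS) < length(allS))
      out$stress_treatment <- buildOne(stressS, "stress_treatment")
    out
  })

  pipelineStage("network_comparisons", {
    if (length(nets) >= 2) {
      nm <- names(nets)
      rows <- list()
      for (i in seq_len(length(nets) - 1L))
        for (j in seq.int(i + 1L, length(nets))) {
          cmp <- compareNetworks(nets[[i]], nets[[j]])
          rows[[length(rows) + 1L]] <-
            data.frame(network_a = nm[i], network_b = nm[j],
                       as.data.frame(cmp), stringsAsFactors = FALSE)
        }
      write.table(do.call(rbind, rows), pth("network_comparisons.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      addOut("network_comparisons.tsv")
    }
  })

  degs <- pipelineStage("differential_expression", {
    classA <- cfg$deg$class_a
    classB <- cfg$deg$class_b
    if (is.null(classA) || is.null(classB)) {
      classA <- allS[cd$treatment == "NaCl"]
      classB <- allS[cd$treatment == "CK"]
    }
    if (length(classA) >= 2 && length(classB) >= 2) {
      dd <- callDEGs(fs, classA, classB, fdrCutoff = cfg$deg$fdr,
                     lfcCutoff = cfg$deg$lfc, floor = floorVal,
                     adjust = cfg$deg$adjust)
      write.table(dd, pth("degs.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      addOut("degs.tsv")
      dd
    } else NULL
  })

  pipelineStage("overlays", {
    genes <- networkNodes(nets$global)
    if (length(genes)) {
      tis <- unique(cd$tissue)
      tisOv <- do.call(rbind, lapply(tis, function(t)
        assignTissueStates(genes, fs, t, thr$global_threshold)))
      writeOverlay(tisOv, pth("overlay_tissue.tsv"))
      addOut("overlay_tissue.tsv")
      stressPairs <- unique(data.frame(
        tissue = cd$tissue, treatment = cd$treatment,
        stringsAsFactors = FALSE))
      stressPairs <- stressPairs[stressPairs$treatment %in%
                                   c("PEG", "NaCl"), , drop = FALSE]
      if (nrow(stressPairs)) {
        stOv <- do.call(rbind, lapply(seq_len(nrow(stressPairs)),
          function(i) assignStressStates(genes, fs,
                                         stressPairs$tissue[i],
                                         stressPairs$treatment[i],
                                         thr$global_threshold,
                                         floor = floorVal)))
        writeOverlay(stOv, pth("overlay_stress.tsv"))
        addOut("overlay_stress.tsv")
        firstCtx <- paste(stressPairs$tissue[1], stressPairs$treatment[1],
                          sep = ":")
        exportNetworkView(nets$global,
                          stOv[stOv$context == firstCtx, , drop = FALSE],
                          "graphml", pth("network_global_stress_view.graphml"))
        addOut("network_global_stress_view.graphml")
      }
    }
  })

  mods <- pipelineStage("module_detection", {
    cm <- cpmCommunities(nets$global, k = cfg$modules$k,
                         signMode = cfg$modules$sign_mode)
    conn <- moduleConnections(cm, nets$global,
                              minLinkingNodes = cfg$modules$min_linking_nodes)
    writeModules(conn, pth("modules.tsv"), pth("module_links.tsv"))
    addOut(c("modules.tsv", "module_links.tsv"))
    conn
  })

  enrichGenes <- cfg$enrichment$gene_list
  promoters <- NULL
  motifTab <- NULL
  pipelineStage("promoters", {
    if (isTRUE(cfg$simulate)) {
      genes <- rownames(fs)
      enriched <- if (is.null(enrichGenes)) {
        ml <- moduleList(mods$modules)
        if (length(ml)) ml[[1]] else head(genes, 25)
      } else enrichGenes
      pr <- generatePromoters(genes, length = sp$promoter_length,
                              motif = sp$motif,
                              enrichedGenes = enriched,
                              plantedRate = sp$motif_planted_rate,
                              backgroundRate = sp$motif_background_rate,
                              seed = cfg$seed + 1)
      promoters <- pr$promoters
      enrichGenes <- enriched
      motifTab <- data.frame(motif_id = "planted", iupac = sp$motif,
                              stringsAsFactors = FALSE)
      Biostrings::writeXStringSet(pr$promoters, pth("promoters.fasta"))
      addOut("promoters.fasta")
    } else if (!is.null(cfg$inputs$promoters)) {
      promoters <- Biostrings::readDNAStringSet(cfg$inputs$promoters)
    } else if (!is.null(cfg$inputs$genome) && !is.null(cfg$inputs$gff)) {
      promoters <- extractPromoters(cfg$inputs$genome, cfg$inputs$gff)
    }
    if (!isTRUE(cfg$simulate) && !is.null(cfg$inputs$motifs))
      motifTab <- readMotifTable(cfg$inputs$motifs)
  })

  pipelineStage("cis_element_enrichment", {
    if (!is.null(promoters) && !is.null(motifTab) &&
        !is.null(enrichGenes)) {
      res <- do.call(rbind, lapply(seq_len(nrow(motifTab)), function(i) {
        r <- motifZTest(intersect(enrichGenes, names(promoters)),
                        promoters, motifTab$iupac[i],
                        nPerm = cfg$enrichment$n_perm,
                        seed = cfg$seed + 2 + i,
                        alpha = cfg$enrichment$alpha)
        cbind(motif_id = motifTab$motif_id[i], r)
      }))
      write.table(res, pth("motif_enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      addOut("motif_enrichment.tsv")
    }
  })

  pipelineStage("term_enrichment", {
    termMap <- if (!is.null(cfg$inputs$term_map))
      readTermMap(cfg$inputs$term_map)
    else if (isTRUE(cfg$simulate)) {
      # synthetic annotation: one term per planted module plus broad terms
      tm <- truth$modules
      if (length(tm)) {
        names(tm) <- paste0("TERM:", names(tm))
        tm$`TERM:broad` <- rownames(fs)[seq_len(min(200, nrow(fs)))]
        tm
      } else NULL
    } else NULL
    if (!is.null(termMap) && !is.null(enrichGenes)) {
      res <- fisherTermEnrichment(enrichGenes, rownames(fs), termMap,
                                  adjust = cfg$enrichment$adjust,
                                  alpha = cfg$enrichment$alpha)
      write.table(res, pth("term_enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      addOut("term_enrichment.tsv")
    }
  })

  pipelineStage("orthology", {
    hits <- if (!is.null(cfg$inputs$blast_ab) &&
                !is.null(cfg$inputs$blast_ba)) {
      list(ab = parseBlastTabular(cfg$inputs$blast_ab),
           ba = parseBlastTabular(cfg$inputs$blast_ba))
    } else if (isTRUE(cfg$simulate)) {
      bt <- generateBlastTables(sp$n_orthologs_a, sp$n_orthologs_b,
                                truePairs = sp$true_pair_fraction,
                                seed = cfg$seed + 10)
      writeBlastTabular(bt$hits_ab, pth("blast_ab.tsv"))
      writeBlastTabular(bt$hits_ba, pth("blast_ba.tsv"))
      addOut(c("blast_ab.tsv", "blast_ba.tsv"))
      list(ab = parseBlastTabular(pth("blast_ab.tsv")),
           ba = parseBlastTabular(pth("blast_ba.tsv")))
    } else NULL
    if (!is.null(hits)) {
      pairs <- callOrthologs(hits$ab, hits$ba,
                             topN = cfg$orthology$top_n,
                             secondaryEvalue = cfg$orthology$secondary_evalue)
      writeOrthologs(pairs, pth("orthologs.tsv"))
      addOut("orthologs.tsv")
    }
  })

  pipelineStage("manifest", {
    addOut("manifest.json")
    manifest$threshold <- thr
    manifest$counts <- list(
      genes = nrow(fs), samples = ncol(fs),
      network_nodes = length(networkNodes(nets$global)),
      network_edges = nrow(networkEdges(nets$global)),
      positive_edges = sum(networkEdges(nets$global)$sign == "positive"),
      negative_edges = sum(networkEdges(nets$global)$sign == "negative"),
      zero_variance_excluded =
        networkParameters(nets$global)$zero_variance_excluded,
      degs = if (is.null(degs)) 0L else nrow(degs),
      modules = length(moduleList(mods$modules)),
      linked_module_pairs = nrow(mods$links))
    jsonlite::write_json(manifest, pth("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(manifest)
}

#' Export a network with expression-state overlays
#'
#' Writes GraphML (via igraph) or a JSON node-link document. Node
#' attributes: `gene_id`, `state` and `color` following the standard
#' scheme (grey `not_expressed`, green `unchanged`/`expressed`, red
#' `up`, blue `down`); edge attributes include `sign` and a `style`
#' colour (pink positive, blue negative).
#'
#' @param network a [CoexpressionNetwork-class].
#' @param overlays optional overlay data.frame (`gene_id`, `state`,
#'   one context) from [assignTissueStates()]/[assignStressStates()].
#' @param format `"graphml"` or `"json"`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
exportNetworkView <- function(network, overlays = NULL,
                              format = c("graphml", "json"), path) {
  stopifnot(is(network, "CoexpressionNetwork"))
  if (!is.character(format) ||
      !format[1] %in% c("graphml", "json"))
    stop("unknown format: ", format[1])
  format <- format[1]
  colorOf <- c(up = "red", down = "blue", unchanged = "green",
               expressed = "green", not_expressed = "grey")
  state <- setNames(rep("expressed", length(network@nodes)),
                    network@nodes)
  if (!is.null(overlays) && nrow(overlays)) {
    if (length(unique(overlays$context)) > 1L)
      stop("overlay must contain a single context")
    known <- intersect(overlays$gene_id, names(state))
    state[known] <- overlays$state[match(known, overlays$gene_id)]
  }
  ed <- network@edges
  edgeStyle <- ifelse(ed$sign == "positive", "pink", "blue")
  if (format == "graphml") {
    g <- networkToIgraph(network)
    if (igraph::vcount(g)) {
      igraph::V(g)$state <- unname(state[igraph::V(g)$name])
      igraph::V(g)$color <- unname(colorOf[igraph::V(g)$state])
    }
    if (igraph::ecount(g)) igraph::E(g)$style <- edgeStyle
    igraph::write_graph(g, path, format = "graphml")
  } else {
    doc <- list(
      nodes = if (length(network@nodes))
        data.frame(id = network@nodes,
                   gene_id = network@nodes,
                   state = unname(state[network@nodes]),
                   color = unname(colorOf[state[network@nodes]]),
                   stringsAsFactors = FALSE)
      else list(),
      links = if (nrow(ed))
        cbind(data.frame(source = ed$gene_a, target = ed$gene_b,
                         style = edgeStyle,
                         stringsAsFactors = FALSE),
              ed[, c("pcc", "rank_ab", "rank_ba", "mr", "sign",
                     "tier")])
      else list())
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}
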