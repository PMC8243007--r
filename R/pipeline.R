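#' Pipeline configuration
#'
#' Collects paths, stage parameters, stage toggles and the global seed for
#' [runPipeline()]. Either `sim` (a [simConfig()]) or `gemPath` +
#' `samplesPath` must be supplied.
#'
#' @param outputDir run directory (created if needed).
#' @param sim a [simConfig()] to generate the input GEM, or `NULL` to read
#'   it from `gemPath`.
#' @param gemPath,samplesPath,gene2goPath,deFlagsPath input TSV paths (see
#'   [readGEM()], [readSampleTable()], [readGene2GO()]); `deFlagsPath` is an
#'   optional gene annotation table with a `gene_id` column, attached to the
#'   GraphML export.
#' @param gemScale scale of the GEM on disk (`"rpkm"` GEMs are
#'   log2(x+1)-transformed before analysis).
#' @param labelFactors design factors used as the feature-selection label.
#' @param nIter,borutaAlpha,numTrees Boruta parameters.
#' @param minClusterSize,networkAlpha,power,maxK,corMethod network
#'   construction parameters.
#' @param phasedAlpha phased-edge significance level.
#' @param mergeThresholds named meta-module merge thresholds per tissue
#'   (default [mergeThresholdPresets]).
#' @param enrichAlpha enrichment significance gate.
#' @param stages character vector of enabled stages, a subset of
#'   `c("features", "network", "phased", "modules", "enrichment")`.
#' @param seed global integer seed; per-stage child seeds are derived from
#'   it by a counter scheme so stages can be reproduced in isolation.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(outputDir, sim = simConfig(), gemPath = NULL,
                           samplesPath = NULL, gene2goPath = NULL,
                           deFlagsPath = NULL, gemScale = "rpkm",
                           labelFactors = c("tissue", "position"),
                           nIter = 1000, borutaAlpha = 0.05, numTrees = 500,
                           minClusterSize = 15, networkAlpha = 0.001,
                           power = 0.8, maxK = 5, corMethod = "spearman",
                           phasedAlpha = 0.001,
                           mergeThresholds = mergeThresholdPresets,
                           enrichAlpha = 0.05,
                           stages = c("features", "network", "phased",
                                      "modules", "enrichment"),
                           seed = 1) {
  known <- c("features", "network", "phased", "modules", "enrichment")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(sim)) {
    for (p in c(gemPath, samplesPath))
      if (is.null(p) || !file.exists(p))
        stop("without a simulation config, gemPath and samplesPath must exist")
  }
  if ("enrichment" %in% stages && is.null(sim) &&
      (is.null(gene2goPath) || !file.exists(gene2goPath)))
    stop("enrichment stage enabled but gene2goPath does not exist")
  cfg <- list(outputDir = outputDir, sim = sim, gemPath = gemPath,
              samplesPath = samplesPath, gene2goPath = gene2goPath,
              deFlagsPath = deFlagsPath, gemScale = gemScale,
              labelFactors = labelFactors, nIter = nIter,
              borutaAlpha = borutaAlpha, numTrees = numTrees,
              minClusterSize = minClusterSize, networkAlpha = networkAlpha,
              power = power, maxK = maxK, corMethod = corMethod,
              phasedAlpha = phasedAlpha, mergeThresholds = mergeThresholds,
              enrichAlpha = enrichAlpha, stages = stages, seed = seed)
  class(cfg) <- "pipelineConfig"
  cfg
}

# counter-based child seed derivation (kept below 2^31)
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 10007) %% 2147483629) + 1L
}

runStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order and as enabled: simulate (or load) the GEM, Boruta
#' feature selection, condition-specific network construction, phased-edge
#' detection, per-tissue link-community module discovery with meta-module
#' merging, and GO enrichment of meta-modules. Per-stage outputs are written
#' under `config$outputDir` (tidy edge TSVs, module TSV, enrichment TSV,
#' GraphML, manifest JSON). Re-running with the same config and seed
#' reproduces all outputs byte-identically.
#'
#' @param config a [pipelineConfig()].
#' @param verbose print stage progress.
#' @return (invisibly) a list with the run directory, the manifest, and the
#'   in-memory stage results.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  manifest <- list(parameters = config[setdiff(names(config),
                                               c("outputDir", "sim"))],
                   seed = config$seed, stages = list())
  if (!is.null(config$sim)) manifest$parameters$sim <- unclass(config$sim)
  note <- function(name, enabled, counts = list()) {
    manifest$stages[[name]] <<- c(list(enabled = enabled), counts)
  }
  truth <- NULL

  ## stage 0: input GEM
  if (!is.null(config$sim)) {
    say("simulating GEM")
    sim <- runStage("simulate", {
      sc <- config$sim
      sc$seed <- childSeed(config$seed, 0L)
      simulateGEM(sc)
    })
    gem <- sim$gem; samples <- sim$samples; truth <- sim$truth
    writeGEM(gem, file.path(config$outputDir, "gem.tsv"))
    writeSampleTable(samples, file.path(config$outputDir, "samples.tsv"))
    note("simulate", TRUE, list(n_genes = nrow(gem), n_samples = ncol(gem)))
  } else {
    say("reading GEM")
    gem <- runStage("read_gem", {
      g <- readGEM(config$gemPath, scale = config$gemScale,
                   sampleTable = config$samplesPath)
      if (identical(expressionScale(g), "rpkm")) g <- logTransform(g, 1) else g
    })
    samples <- sampleInfo(gem)
    note("simulate", FALSE)
  }

  ## stage 1: feature selection
  if ("features" %in% config$stages) {
    say("feature selection")
    decisions <- runStage("features", {
      labels <- compositeLabels(samples, config$labelFactors)
      borutaSelect(gem, labels, nIter = config$nIter,
                   alpha = config$borutaAlpha, numTrees = config$numTrees,
                   seed = childSeed(config$seed, 1L))
    })
    write.table(decisions, file.path(config$outputDir, "features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    geneSubset <- confirmedGenes(decisions)
    note("features", TRUE, list(n_confirmed = length(geneSubset),
                                n_rejected = sum(decisions$status == "rejected"),
                                n_tentative = sum(decisions$status == "tentative")))
  } else {
    decisions <- NULL
    geneSubset <- rownames(gem)
    note("features", FALSE)
  }

  ## stage 2: network construction
  if ("network" %in% config$stages) {
    say("network construction (", length(geneSubset), " genes)")
    edges <- runStage("network",
      buildNetwork(gem, samples, geneSubset,
                   minClusterSize = config$minClusterSize,
                   alpha = config$networkAlpha, power = config$power,
                   maxK = config$maxK, method = config$corMethod,
                   seed = childSeed(config$seed, 2L)))
    writeTidyEdges(edges, file.path(config$outputDir, "edges.tsv"))
    note("network", TRUE, list(n_edges = nrow(edges),
                               n_genes = length(unique(c(edges$gene_a,
                                                         edges$gene_b)))))
  } else {
    edges <- emptyEdgeTable()
    note("network", FALSE)
  }

  ## stage 3: phased edge detection
  if ("phased" %in% config$stages && nrow(edges)) {
    say("phased edge detection")
    phased <- runStage("phased",
      detectPhasedEdges(edges, gem, samples, alpha = config$phasedAlpha,
                        retain = TRUE))
    writeTidyEdges(phased, file.path(config$outputDir, "phased_edges.tsv"))
    note("phased", TRUE, list(n_phased_edges = nrow(phased),
                              n_phased_genes = length(unique(c(phased$gene_a,
                                                               phased$gene_b)))))
  } else {
    phased <- emptyEdgeTable()
    note("phased", "phased" %in% config$stages)
  }

  ## stage 4: module discovery per tissue network
  moduleTable <- data.frame()
  metaByTissue <- list()
  if ("modules" %in% config$stages && nrow(phased)) {
    say("module discovery")
    moduleTable <- runStage("modules", {
      tissues <- sort(unique(sub("^tissue=", "", phased$condition_label)))
      do.call(rbind, lapply(tissues, function(tis) {
        sel <- phased[phased$condition_label == paste0("tissue=", tis), ,
                      drop = FALSE]
        lc <- linkCommunities(sel)
        thr <- config$mergeThresholds[[tis]]
        if (is.null(thr) || is.na(thr)) thr <- 0.5
        metas <- mergeMetaModules(lc$communities, thr)
        metaByTissue[[tis]] <<- list(communities = lc, metas = metas)
        meta_of <- integer()
        for (mm in metas) meta_of[as.character(mm$members)] <- mm$meta_id
        ec <- lc$edge_communities
        ec$meta_module <- meta_of[as.character(ec$module)]
        cbind(tissue = tis, ec)
      }))
    })
    write.table(moduleTable, file.path(config$outputDir, "modules.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("modules", TRUE,
         list(n_communities = length(unique(paste(moduleTable$tissue,
                                                  moduleTable$module))),
              n_meta_modules = length(unique(paste(moduleTable$tissue,
                                                   moduleTable$meta_module)))))
  } else {
    note("modules", "modules" %in% config$stages)
  }

  ## stage 5: GO enrichment of meta-modules
  enrichTable <- data.frame()
  if ("enrichment" %in% config$stages && length(metaByTissue)) {
    say("GO enrichment")
    enrichTable <- runStage("enrichment", {
      gene2go <- if (!is.null(config$gene2goPath))
        readGene2GO(config$gene2goPath)
      else
        simulateGene2GO(rownames(gem), truth,
                        seed = childSeed(config$seed, 5L))
      background <- rownames(gem)
      out <- lapply(names(metaByTissue), function(tis) {
        metas <- metaByTissue[[tis]]$metas
        do.call(rbind, lapply(metas, function(mm) {
          er <- fisherEnrichment(mm$node_set, background, gene2go,
                                 alpha = config$enrichAlpha)
          if (nrow(er)) cbind(tissue = tis, meta_module = mm$meta_id, er)
          else NULL
        }))
      })
      res <- do.call(rbind, out)
      if (is.null(res)) data.frame() else res
    })
    write.table(enrichTable, file.path(config$outputDir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("enrichment", TRUE,
         list(n_terms_tested = nrow(enrichTable),
              n_significant = if (nrow(enrichTable))
                sum(enrichTable$significant) else 0L))
  } else {
    note("enrichment", "enrichment" %in% config$stages)
  }

  ## GraphML export of the phased network (falls back to the full network)
  netOut <- if (nrow(phased)) phased else edges
  if (nrow(netOut)) {
    if (nrow(moduleTable)) {
      key <- edgeId(netOut$gene_a, netOut$gene_b)
      mkey <- setNames(paste(moduleTable$tissue, moduleTable$meta_module,
                             sep = ":"), moduleTable$edge_id)
      netOut$module <- unname(mkey[key])
      netOut$module[is.na(netOut$module)] <- ""
    }
    nodeAnn <- NULL
    if (!is.null(config$deFlagsPath) && file.exists(config$deFlagsPath))
      nodeAnn <- read.delim(config$deFlagsPath, stringsAsFactors = FALSE)
    writeGraphML(netOut, file.path(config$outputDir, "network.graphml"),
                 nodeAnnotations = nodeAnn)
  }

  manifest$summary <- summarizeNetwork(edges)
  jsonlite::write_json(manifest,
                       file.path(config$outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  say("done")
  invisible(list(outputDir = config$outputDir, manifest = manifest,
                 gem = gem, samples = samples, truth = truth,
                 decisions = decisions, edges = edges, phased = phased,
                 modules = moduleTable, metaByTissue = metaByTissue,
                 enrichment = enrichTable))
}

#' Summarize a network by condition label
#'
#' Per condition label: the number of edges and the number of distinct genes
#' incident to them (the layout of the study's edge taxonomy table).
#'
#' @param edges edge data.frame.
#' @return data.frame with `condition`, `n_edges`, `n_genes`, sorted by
#'   decreasing edge count.
#' @export
summarizeNetwork <- function(edges) {
  if (!nrow(edges))
    return(data.frame(condition = character(), n_edges = integer(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  sp <- split(edges, edges$condition_label)
  out <- data.frame(
    condition = names(sp),
    n_edges = vapply(sp, nrow, 1L),
    n_genes = vapply(sp, function(e)
      length(unique(c(e$gene_a, e$gene_b))), 1L),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_edges, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}
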