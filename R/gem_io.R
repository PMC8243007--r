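#' Read a gene expression matrix from TSV
#'
#' The expected layout is a header row of sample ids, a first column of gene
#' ids, and numeric cells with the literal token `NA` for missing values
#' (RSEM-style GEM export).
#'
#' @param path TSV file path.
#' @param scale scale of the stored values: `"rpkm"` (default) or `"log2"`.
#' @param sampleTable optional sample annotation data.frame or TSV path
#'   (forwarded to [readSampleTable()]).
#' @return a [GEM-class].
#' @export
readGEM <- function(path, scale = c("rpkm", "log2"), sampleTable = NULL) {
  scale <- match.arg(scale)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2L) stop("GEM file needs a gene id column plus samples")
  gene_ids <- raw[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicated gene id in GEM: ", gene_ids[duplicated(gene_ids)][1L])
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id in GEM: ",
         sample_ids[duplicated(sample_ids)][1L])
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & cells != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]],
                 cells[bad[1L, , drop = FALSE]]))
  dimnames(vals) <- list(gene_ids, sample_ids)
  if (is.character(sampleTable)) sampleTable <- readSampleTable(sampleTable)
  GEM(vals, sampleTable = sampleTable, scale = scale)
}

#' Write a GEM to TSV (inverse of [readGEM()])
#'
#' @param gem a [GEM-class]
#' @param path output file path
#' @export
writeGEM <- function(gem, path) {
  v <- exprValues(gem)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' Requires columns `sample_id`, `tissue` (cortex/peel), `position`
#' (internal/external), `timepoint` (T0..T3) and `replicate`.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
readSampleTable <- function(path) {
  validateSampleTable(read.delim(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}

#' Write a sample annotation table to TSV
#' @param samples sample annotation data.frame
#' @param path output file path
#' @export
writeSampleTable <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-transform an RPKM-scale GEM
#'
#' Replaces each non-missing value x by `log2(x + pseudocount)` and flags
#' the GEM as log2 scale. Applying it twice is an error: network statistics
#' must see a single, known transform.
#'
#' @param gem a [GEM-class] on the rpkm scale
#' @param pseudocount positive offset added before the log (default 1)
#' @return the transformed [GEM-class]
#' @export
logTransform <- function(gem, pseudocount = 1) {
  if (!is(gem, "GEM")) stop("gem must be a GEM")
  if (identical(expressionScale(gem), "log2"))
    stop("GEM is already log2 scale; refusing to double-transform")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  v <- exprValues(gem)
  out <- log2(v + pseudocount)
  assay(gem, "expr") <- out
  gem@scale <- "log2"
  validObject(gem)
  gem
}

## ---- tidy edge table -------------------------------------------------------

# Canonical column order of the tidy edge format.
.EDGE_COLS <- c("gene_a", "gene_b", "mode_index", "n", "r", "condition_label",
                "proportion_p_A", "proportion_p_B", "phase_p", "rank_score",
                "sample_string")

emptyEdgeTable <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             mode_index = integer(), n = integer(), r = numeric(),
             condition_label = character(), proportion_p_A = numeric(),
             proportion_p_B = numeric(), phase_p = numeric(),
             rank_score = numeric(), sample_string = character(),
             stringsAsFactors = FALSE)
}

#' Encode mode membership as a per-sample string
#'
#' One character per GEM sample, in GEM column order: `1` in the mode,
#' `0` out of the mode, `9` missing (sample not pairwise-complete for the
#' gene pair).
#'
#' @param mode_samples sample ids inside the mode
#' @param all_samples all GEM sample ids, in order
#' @param missing_samples sample ids excluded as pairwise-incomplete
#' @return a character scalar of length `length(all_samples)`
#' @export
sampleString <- function(mode_samples, all_samples, missing_samples = character()) {
  code <- ifelse(all_samples %in% missing_samples, "9",
                 ifelse(all_samples %in% mode_samples, "1", "0"))
  paste(code, collapse = "")
}

#' Decode a sample-membership string
#' @param s a string of `0`/`1`/`9` codes
#' @param all_samples all GEM sample ids, in order
#' @return list with `mode_samples` and `missing_samples` character vectors
#' @export
decodeSampleString <- function(s, all_samples) {
  code <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (length(code) != length(all_samples))
    stop("sample string length does not match the sample id vector")
  list(mode_samples = all_samples[code == "1"],
       missing_samples = all_samples[code == "9"])
}

#' Write network edges in tidy TSV format
#'
#' One row per (gene pair, GMM mode, condition label), with the per-sample
#' membership string. [readTidyEdges()] inverts this file exactly.
#'
#' @param edges edge data.frame (see [buildNetwork()]); may be empty
#' @param path output file path
#' @export
writeTidyEdges <- function(edges, path) {
  if (is.null(edges) || nrow(edges) == 0L) edges <- emptyEdgeTable()
  miss <- setdiff(.EDGE_COLS, names(edges))
  if (length(miss))
    stop("edge table is missing columns: ", paste(miss, collapse = ", "))
  out <- edges[, .EDGE_COLS, drop = FALSE]
  # full precision so that the round trip is value-exact
  for (cc in c("r", "proportion_p_A", "proportion_p_B", "phase_p", "rank_score"))
    out[[cc]] <- formatC(out[[cc]], format = "g", digits = 17)
  out$phase_p[is.na(edges$phase_p)] <- "NA"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a tidy edge TSV written by [writeTidyEdges()]
#' @param path TSV file path
#' @return edge data.frame
#' @export
readTidyEdges <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(gene_a = "character", gene_b = "character",
                                  mode_index = "integer", n = "integer",
                                  r = "numeric", condition_label = "character",
                                  proportion_p_A = "numeric",
                                  proportion_p_B = "numeric",
                                  phase_p = "numeric", rank_score = "numeric",
                                  sample_string = "character"))
  df[, .EDGE_COLS, drop = FALSE]
}

## ---- GraphML export --------------------------------------------------------

#' Export a network to GraphML (Cytoscape-compatible)
#'
#' Nodes are genes; one graph edge per edge-table row, carrying `r`,
#' `condition_label`, `phase_p` and, when present, `module`. Node annotations
#' (e.g. DE flags) are attached by gene id; annotations for genes absent from
#' the network are dropped with a warning.
#'
#' @param edges edge data.frame; an optional `module` column is exported
#' @param path output GraphML path
#' @param nodeAnnotations optional data.frame with a `gene_id` column plus
#'   arbitrary annotation columns
#' @return the path, invisibly
#' @export
writeGraphML <- function(edges, path, nodeAnnotations = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b"), drop = FALSE], directed = FALSE)
  if (nrow(edges)) {
    igraph::E(g)$r <- edges$r
    igraph::E(g)$condition_label <- edges$condition_label
    igraph::E(g)$phase_p <- ifelse(is.na(edges$phase_p), -1, edges$phase_p)
    if ("module" %in% names(edges))
      igraph::E(g)$module <- as.character(edges$module)
  }
  if (!is.null(nodeAnnotations)) {
    nodeAnnotations <- as.data.frame(nodeAnnotations)
    if (!"gene_id" %in% names(nodeAnnotations))
      stop("nodeAnnotations needs a gene_id column")
    absent <- setdiff(nodeAnnotations$gene_id, igraph::V(g)$name)
    if (length(absent)) {
      warning("dropping annotations for ", length(absent),
              " gene(s) absent from the network")
      nodeAnnotations <-
        nodeAnnotations[!nodeAnnotations$gene_id %in% absent, , drop = FALSE]
    }
    idx <- match(igraph::V(g)$name, nodeAnnotations$gene_id)
    for (cc in setdiff(names(nodeAnnotations), "gene_id")) {
      val <- nodeAnnotations[[cc]][idx]
      if (is.numeric(val)) val[is.na(val)] <- -1
      else { val <- as.character(val); val[is.na(val)] <- "" }
      g <- igraph::set_vertex_attr(g, cc, value = val)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
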