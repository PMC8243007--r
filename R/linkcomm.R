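## Edge-based (link-community) module discovery: Ahn-style edge similarity,
## McQuitty-linkage agglomeration per connected component, partition-density
## dendrogram cut, and Jaccard meta-module merging.

edgeId <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# inclusive neighbourhoods n+(v) = {v} U neighbours(v) from a unique pair list
inclusiveNeighbourhoods <- function(pairs) {
  nodes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  nb <- setNames(lapply(nodes, function(v) v), nodes)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  lapply(nb, unique)
}

#' Ahn link similarity of two adjacent edges
#'
#' For edges sharing exactly one node, with i and j the unshared endpoints,
#' the similarity is the Jaccard coefficient of the inclusive neighbourhoods
#' \eqn{|n^+(i) \cap n^+(j)| / |n^+(i) \cup n^+(j)|}. Identical edges have
#' similarity 1; edges sharing zero or two nodes are undefined (`NA`) — the
#' clustering treats non-adjacent pairs as maximally dissimilar.
#'
#' @param e1,e2 character vectors of length 2 (the edge endpoints).
#' @param pairs unique-edge data.frame (`gene_a`, `gene_b`) defining the
#'   graph adjacency.
#' @return similarity in \[0, 1\], or `NA` when undefined.
#' @export
edgeSimilarity <- function(e1, e2, pairs) {
  shared <- intersect(e1, e2)
  if (length(shared) == 2L) {
    return(if (setequal(e1, e2)) 1 else NA_real_)
  }
  if (length(shared) != 1L) return(NA_real_)
  nb <- inclusiveNeighbourhoods(pairs)
  i <- setdiff(e1, shared); j <- setdiff(e2, shared)
  length(intersect(nb[[i]], nb[[j]])) / length(union(nb[[i]], nb[[j]]))
}

communityFromEdges <- function(module_id, eids, pairs) {
  sel <- pairs[pairs$edge_id %in% eids, , drop = FALSE]
  nodes <- unique(c(sel$gene_a, sel$gene_b))
  m <- nrow(sel); n <- length(nodes)
  # normalized density contribution in [0, 1]
  Dc <- if (n <= 2) 0 else (m - (n - 1)) / ((n * (n - 1) / 2) - (n - 1))
  list(module_id = module_id, edge_set = sort(sel$edge_id),
       node_set = sort(nodes), m = m, n_nodes = n, Dc = Dc)
}

#' Partition density of a link-community partition
#'
#' \deqn{D = \frac{2}{M} \sum_c m_c \frac{m_c - (n_c - 1)}
#'   {(n_c - 2)(n_c - 1)}}
#' with the c-term taken as 0 when \eqn{n_c \le 2}. A partition into
#' single-edge communities has D = 0; a partition of a graph of disjoint
#' cliques into those cliques has D = 1.
#'
#' @param communities list of communities, each with `m` (edge count) and
#'   `n_nodes`.
#' @param M total number of edges partitioned.
#' @return partition density.
#' @export
partitionDensity <- function(communities, M) {
  if (M == 0) return(0)
  terms <- vapply(communities, function(cc) {
    m <- cc$m; n <- cc$n_nodes
    if (n <= 2) 0 else m * (m - (n - 1)) / ((n - 2) * (n - 1))
  }, 1)
  2 / M * sum(terms)
}

#' Link-community module discovery
#'
#' Deduplicates the network to unique gene pairs, then, independently for
#' each connected component: builds the edge dissimilarity matrix
#' (1 - [edgeSimilarity()], non-adjacent edge pairs maximally dissimilar at
#' 1), agglomerates with McQuitty (WPGMA) linkage, and cuts the dendrogram
#' at the height maximizing the partition density over all merge heights
#' (coarsest cut on ties). Single-edge components form their own community.
#' Edges are sorted canonically first, so the result does not depend on
#' input order.
#'
#' @param edges edge data.frame (only `gene_a`, `gene_b` are used; duplicate
#'   pairs from multiple modes/labels collapse to one link).
#' @param linkage hierarchical clustering linkage (default `"mcquitty"`).
#' @return list with `communities` (list of module records: `module_id`,
#'   `edge_set`, `node_set`, `m`, `n_nodes`, `Dc`), `edge_communities`
#'   (data.frame edge -> module id), `partition_density`, and `M` (unique
#'   edge count).
#' @export
linkCommunities <- function(edges, linkage = "mcquitty") {
  if (!nrow(edges)) stop("network is empty")
  pairs <- unique(data.frame(gene_a = pmin(edges$gene_a, edges$gene_b),
                             gene_b = pmax(edges$gene_a, edges$gene_b),
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  pairs$edge_id <- edgeId(pairs$gene_a, pairs$gene_b)
  M <- nrow(pairs)
  g <- igraph::graph_from_data_frame(pairs[, 1:2], directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  nb <- inclusiveNeighbourhoods(pairs)

  communities <- list()
  next_id <- 0L
  # deterministic component order: by smallest edge id within the component
  comp_of_edge <- membership[pairs$gene_a]
  comp_order <- unique(comp_of_edge)
  for (cmp in comp_order) {
    sel <- pairs[comp_of_edge == cmp, , drop = FALSE]
    ne <- nrow(sel)
    if (ne == 1L) {
      next_id <- next_id + 1L
      communities[[next_id]] <- communityFromEdges(next_id, sel$edge_id, pairs)
      next
    }
    D <- matrix(1, ne, ne, dimnames = list(sel$edge_id, sel$edge_id))
    diag(D) <- 0
    for (i in seq_len(ne - 1L)) for (j in seq((i + 1L), ne)) {
      shared <- intersect(c(sel$gene_a[i], sel$gene_b[i]),
                          c(sel$gene_a[j], sel$gene_b[j]))
      if (length(shared) == 1L) {
        u <- setdiff(c(sel$gene_a[i], sel$gene_b[i]), shared)
        w <- setdiff(c(sel$gene_a[j], sel$gene_b[j]), shared)
        s <- length(intersect(nb[[u]], nb[[w]])) /
          length(union(nb[[u]], nb[[w]]))
        D[i, j] <- D[j, i] <- 1 - s
      }
    }
    hc <- hclust(as.dist(D), method = linkage)
    heights <- sort(unique(c(0, hc$height)))
    best <- list(density = -Inf, cut = NULL)
    for (ht in heights) {
      ct <- cutree(hc, h = ht)
      comms <- lapply(split(names(ct), ct), function(eids)
        communityFromEdges(0L, eids, pairs))
      dens <- partitionDensity(comms, ne)   # component-local objective
      if (dens >= best$density - 1e-12) {   # ties -> coarser (larger height)
        if (dens > best$density + 1e-12 || is.null(best$cut) ||
            max(ct) <= max(best$cut))
          best <- list(density = dens, cut = ct)
      }
    }
    for (eids in split(names(best$cut), best$cut)) {
      next_id <- next_id + 1L
      communities[[next_id]] <- communityFromEdges(next_id, eids, pairs)
    }
  }
  edge2mod <- do.call(rbind, lapply(communities, function(cc)
    data.frame(edge_id = cc$edge_set, module = cc$module_id,
               stringsAsFactors = FALSE)))
  ec <- merge(pairs, edge2mod, by = "edge_id", sort = TRUE)
  list(communities = communities,
       edge_communities = ec[, c("gene_a", "gene_b", "edge_id", "module")],
       partition_density = partitionDensity(communities, M), M = M)
}

#' Study merge-threshold presets
#'
#' Named meta-module merge thresholds used for the two tissue networks.
#' @export
mergeThresholdPresets <- c(peel = 0.3, cortex = 0.6)

#' Merge link communities into meta-modules
#'
#' Communities are hierarchically clustered (McQuitty linkage) by the
#' Jaccard distance of their node sets and merged when their cophenetic
#' distance is strictly below `threshold`; each cluster's edge and node sets
#' are unioned into a MetaModule. A larger threshold merges more, so the
#' meta-module count is non-increasing in the threshold. Node-disjoint
#' communities (distance 1) are never merged for thresholds in (0, 1].
#'
#' @param communities `communities` list from [linkCommunities()].
#' @param threshold merge height in (0, 1]; see [mergeThresholdPresets] for
#'   the study defaults (0.3 peel, 0.6 cortex).
#' @param linkage linkage for the community dendrogram.
#' @return list of meta-modules: `meta_id`, `members` (community ids),
#'   `edge_set`, `node_set`.
#' @export
mergeMetaModules <- function(communities, threshold,
                             linkage = "mcquitty") {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  k <- length(communities)
  if (k == 0L) return(list())
  if (k == 1L) {
    cc <- communities[[1L]]
    return(list(list(meta_id = 1L, members = cc$module_id,
                     edge_set = cc$edge_set, node_set = cc$node_set)))
  }
  D <- matrix(1, k, k)
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    a <- communities[[i]]$node_set; b <- communities[[j]]$node_set
    D[i, j] <- D[j, i] <- 1 - length(intersect(a, b)) / length(union(a, b))
  }
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = linkage)
  ct <- cutree(hc, h = threshold - 1e-9)   # strict: distance-1 pairs never merge
  metas <- lapply(seq_len(max(ct)), function(mid) {
    idx <- which(ct == mid)
    list(meta_id = mid,
         members = vapply(communities[idx], `[[`, 1L, "module_id"),
         edge_set = sort(unique(unlist(lapply(communities[idx], `[[`,
                                              "edge_set")))),
         node_set = sort(unique(unlist(lapply(communities[idx], `[[`,
                                              "node_set")))))
  })
  metas
}
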