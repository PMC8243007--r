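
twoTriangles <- data.frame(
  gene_a = c("a", "a", "b", "c", "c", "d"),
  gene_b = c("b", "c", "c", "d", "e", "e"),
  stringsAsFactors = FALSE)

test_that("edge similarity matches hand enumeration", {
  tri <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"))
  # triangle: edges (a,c) and (b,c) share c; n+(a) = n+(b) = {a,b,c}
  expect_equal(edgeSimilarity(c("a", "c"), c("b", "c"), tri), 1)
  # path a-c-b: n+(a) = {a,c}, n+(b) = {b,c} -> 1/3
  path <- data.frame(gene_a = c("a", "b"), gene_b = c("c", "c"))
  expect_equal(edgeSimilarity(c("a", "c"), c("b", "c"), path), 1 / 3)
  expect_equal(edgeSimilarity(c("a", "b"), c("a", "b"), tri), 1)
  # disjoint edges are undefined
  quad <- data.frame(gene_a = c("a", "c"), gene_b = c("b", "d"))
  expect_true(is.na(edgeSimilarity(c("a", "b"), c("c", "d"), quad)))
})

test_that("partition density hand checks", {
  # one triangle as one community: term = 3 * (3-2)/(1*2); D = 2/3 * 1.5 = 1
  expect_equal(partitionDensity(list(list(m = 3, n_nodes = 3)), 3), 1)
  # 3-edge star: m = 3, n = 4 -> numerator m - (n-1) = 0
  expect_equal(partitionDensity(list(list(m = 3, n_nodes = 4)), 3), 0)
  # all singletons
  singl <- replicate(6, list(m = 1, n_nodes = 2), simplify = FALSE)
  expect_equal(partitionDensity(singl, 6), 0)
})

test_that("two triangles sharing a node split into two communities at D = 1", {
  lc <- linkCommunities(twoTriangles)
  expect_identical(length(lc$communities), 2L)
  expect_equal(lc$partition_density, 1)
  nodes <- lapply(lc$communities, `[[`, "node_set")
  expect_setequal(vapply(nodes, paste, "", collapse = ""),
                  c("abc", "cde"))
  # matches the exhaustive-partition oracle
  oracle <- bruteBestPartition(twoTriangles)
  expect_equal(lc$partition_density, oracle$density)
  expect_identical(length(oracle$partition), 2L)
})

test_that("cliques stay whole and components are never bridged", {
  clique <- function(nodes) {
    cmb <- t(combn(nodes, 2))
    data.frame(gene_a = cmb[, 1], gene_b = cmb[, 2],
               stringsAsFactors = FALSE)
  }
  k4 <- clique(c("a", "b", "c", "d"))
  lc <- linkCommunities(k4)
  expect_identical(length(lc$communities), 1L)
  two <- rbind(clique(c("a", "b", "c")), clique(c("x", "y", "z")))
  lc2 <- linkCommunities(two)
  for (cc in lc2$communities) {
    nodes <- cc$node_set
    expect_true(all(nodes %in% c("a", "b", "c")) ||
                  all(nodes %in% c("x", "y", "z")))
  }
  # a single-edge component is its own community
  lone <- rbind(clique(c("a", "b", "c")),
                data.frame(gene_a = "p", gene_b = "q"))
  lc3 <- linkCommunities(lone)
  expect_true(any(vapply(lc3$communities, function(cc)
    identical(cc$node_set, c("p", "q")), TRUE)))
})

test_that("community assignment ignores edge input order", {
  set.seed(40)
  sim <- simulateGEM(simConfig(n_genes = 20, n_module_blocks = 3,
                               genes_per_block = 4, n_phased_pairs = 0,
                               n_informative_genes = 0,
                               n_hard_negative_pairs = 0, seed = 40))
  edges <- buildNetwork(sim$gem, seed = 41)
  skip_if(nrow(edges) < 4)
  lc1 <- linkCommunities(edges)
  lc2 <- linkCommunities(edges[sample(nrow(edges)), ])
  expect_identical(lc1$edge_communities, lc2$edge_communities)
})

test_that("meta-module merging follows the Jaccard threshold semantics", {
  mkcomm <- function(id, nodes) list(module_id = id,
                                     edge_set = paste0("e", id),
                                     node_set = sort(nodes), m = 1L,
                                     n_nodes = length(nodes))
  # identical node sets merge at any threshold
  cs <- list(mkcomm(1L, c("a", "b", "c")), mkcomm(2L, c("a", "b", "c")))
  expect_identical(length(mergeMetaModules(cs, 0.05)), 1L)
  # node-disjoint communities never merge, even at threshold 1
  cs2 <- list(mkcomm(1L, c("a", "b")), mkcomm(2L, c("x", "y")))
  expect_identical(length(mergeMetaModules(cs2, 1)), 2L)
  expect_error(mergeMetaModules(cs2, 0), "threshold")
  expect_error(mergeMetaModules(cs2, 1.2), "threshold")
  # monotone: higher threshold never yields more meta-modules
  set.seed(50)
  cs3 <- lapply(1:8, function(i)
    mkcomm(i, sample(letters[1:10], sample(3:6, 1))))
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                   function(th) length(mergeMetaModules(cs3, th)), 1L)
  expect_true(all(diff(counts) <= 0))
  # the study presets are exposed
  expect_equal(mergeThresholdPresets[["peel"]], 0.3)
  expect_equal(mergeThresholdPresets[["cortex"]], 0.6)
})

test_that("meta-modules partition the communities and union their sets", {
  lc <- linkCommunities(twoTriangles)
  metas <- mergeMetaModules(lc$communities, 0.3)
  members <- sort(unlist(lapply(metas, `[[`, "members")))
  expect_identical(members, vapply(lc$communities, `[[`, 1L, "module_id"))
  all_edges <- sort(unlist(lapply(metas, `[[`, "edge_set")))
  expect_identical(all_edges,
                   sort(unlist(lapply(lc$communities, `[[`, "edge_set"))))
})
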