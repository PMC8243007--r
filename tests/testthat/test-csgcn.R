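test_that("a single tight blob selects K = 1 with one full mode", {
  set.seed(2)
  x <- setNames(rnorm(60), paste0("s", 1:60))
  y <- setNames(rnorm(60), paste0("s", 1:60))
  pm <- fitPairGMM(x, y, seed = 7)
  expect_identical(pm$K_selected, 1L)
  expect_identical(length(pm$modes), 1L)
  expect_identical(length(pm$modes[[1]]$sample_set), 60L)
})

test_that("two 6-sigma blobs are recovered with ARI >= 0.95", {
  set.seed(3)
  truth <- rep(1:2, each = 40)
  x <- setNames(rnorm(80) + 6 * (truth - 1), paste0("s", 1:80))
  y <- setNames(rnorm(80) + 6 * (truth - 1), paste0("s", 1:80))
  pm <- fitPairGMM(x, y, seed = 5)
  expect_identical(pm$K_selected, 2L)
  expect_gte(adjustedRand(pm$assignment, truth), 0.95)
  # responsibilities are a proper soft assignment
  expect_equal(rowSums(pm$responsibilities), rep(1, 80), tolerance = 1e-8)
  # independent oracle: mclust agrees on K and assignment
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  mc <- mclust::Mclust(cbind(x, y), G = 1:5, modelNames = "VVV",
                       verbose = FALSE)
  expect_identical(mc$G, 2L)
  expect_gte(adjustedRand(pm$assignment, mc$classification), 0.95)
})

test_that("components below the minimum cluster size are discarded", {
  set.seed(4)
  truth <- rep(1:2, c(40, 14))
  x <- setNames(rnorm(54) + 8 * (truth - 1), paste0("s", 1:54))
  y <- setNames(rnorm(54) + 8 * (truth - 1), paste0("s", 1:54))
  pm <- fitPairGMM(x, y, seed = 9)
  sizes <- vapply(pm$modes, function(m) length(m$sample_set), 1L)
  expect_true(all(sizes >= 15))
  expect_identical(length(pm$modes), 1L)   # the 14-sample component is gone
  expect_identical(sizes, 40L)
})

test_that("pairs with too few complete samples give an empty PairModes", {
  x <- setNames(c(rnorm(10), rep(NA, 10)), paste0("s", 1:20))
  y <- setNames(rnorm(20), paste0("s", 1:20))
  pm <- fitPairGMM(x, y)
  expect_identical(pm$K_selected, 0L)
  expect_identical(length(pm$modes), 0L)
  expect_identical(sort(pm$missing_samples), sort(paste0("s", 11:20)))
})

test_that("mode correlation matches direct rank computation", {
  s <- paste0("s", 1:20)
  x <- setNames(seq_len(20), s)
  expect_equal(modeCorrelation(x, x, s)$r, 1)
  expect_equal(modeCorrelation(x, setNames(-x, s), s)$r, -1)
  # fixed 10-point set against the hand rank-correlation formula
  set.seed(6)
  s10 <- paste0("s", 1:10)
  a <- setNames(rnorm(10), s10); b <- setNames(rnorm(10), s10)
  rs <- 1 - 6 * sum((rank(a) - rank(b))^2) / (10 * (10^2 - 1))
  expect_equal(modeCorrelation(a, b, s10)$r, rs, tolerance = 1e-12)
  expect_equal(modeCorrelation(a, b, s10, method = "pearson")$r, cor(a, b))
  # zero variance -> undefined
  expect_true(is.na(modeCorrelation(setNames(rep(1, 10), s10), b, s10)$r))
})

test_that("Fisher-z required sample sizes match the closed form", {
  # independent closed-form evaluation
  oracle <- function(r, alpha = 0.001, power = 0.8)
    ceiling(((qnorm(1 - alpha / 2) + qnorm(power)) / atanh(abs(r)))^2 + 3)
  expect_identical(requiredSampleSize(0.9), 11)
  expect_identical(requiredSampleSize(0.5), 60)
  expect_identical(requiredSampleSize(0.9), oracle(0.9))
  expect_identical(requiredSampleSize(0.5), oracle(0.5))
  for (r in c(-0.95, -0.6, 0.3, 0.7))
    expect_identical(requiredSampleSize(r), oracle(r))
  expect_identical(requiredSampleSize(0), Inf)
  expect_true(powerFilter(0.9, 15))
  expect_false(powerFilter(0.5, 15))
  expect_false(powerFilter(0, 1000))
  expect_false(powerFilter(NA, 50))
})

test_that("proportion tests flag a perfectly separated tissue mode", {
  sam <- designTable()
  peel <- sam$sample_id[sam$tissue == "peel"]
  pt_ <- proportionTests(peel, sam, "tissue")
  row <- pt_[pt_$level == "peel", ]
  expect_true(row$significant)
  expect_lt(row$p_A, 1e-9)
  expect_lt(row$p_B, 1e-9)
  expect_false(pt_[pt_$level == "cortex", "significant"])
  # a balanced mode is associated with nothing at the position factor
  mixed <- sam$sample_id[sam$replicate <= 3]   # balanced over position
  pt2 <- proportionTests(mixed, sam, "position")
  expect_false(any(pt2$significant))
})

test_that("random modes are associated at about the nominal alpha rate", {
  sam <- designTable()
  set.seed(77)
  alpha <- 0.01   # larger alpha for a stable Monte-Carlo estimate
  hits <- vapply(seq_len(400), function(i) {
    mode <- sample(sam$sample_id, 20)
    any(proportionTests(mode, sam, "tissue", alpha = alpha)$significant)
  }, TRUE)
  # one test per tissue level, both must fire; expected rate < 2 * alpha
  expect_lt(mean(hits), 0.05)
})

test_that("the bias filter rejects purely shift-driven correlations", {
  set.seed(8)
  s <- paste0("s", 1:40)
  grp <- setNames(rep(c("internal", "external"), each = 20), s)
  # two internally uncorrelated blobs offset along the diagonal: pooled r
  # is high, centred r is ~0
  x <- setNames(rnorm(40) + 3 * (grp == "external"), s)
  y <- setNames(rnorm(40) + 3 * (grp == "external"), s)
  expect_gt(cor(x, y, method = "spearman"), 0.5)
  expect_false(biasFilter(x, y, s, grp))
  # a genuine correlation present in both groups is kept
  f <- rnorm(40)
  x2 <- setNames(f + 0.3 * rnorm(40) + 3 * (grp == "external"), s)
  y2 <- setNames(f + 0.3 * rnorm(40) + 3 * (grp == "external"), s)
  expect_true(biasFilter(x2, y2, s, grp))
  # a single represented subgroup keeps vacuously
  expect_true(biasFilter(x, y, s[1:20], grp))
})

test_that("edge ranking is by worst condition p, then |r|, then n, stably", {
  e <- randomEdges(30, paste0("s", 1:10), seed = 3)
  ranked <- rankEdges(e)
  expect_equal(ranked$rank_score,
               -log10(pmax(ranked$proportion_p_A, ranked$proportion_p_B)))
  expect_true(all(diff(ranked$rank_score) <= 1e-12))
  # permutation invariance
  perm <- e[sample(nrow(e)), ]
  expect_identical(rankEdges(perm), ranked)
  # explicit tie-breaks
  f <- e[1:2, ]
  f$proportion_p_A <- 1e-4; f$proportion_p_B <- 1e-5
  f$r <- c(0.9, 0.5); f$n <- 20L
  expect_identical(rankEdges(f)$r, c(0.9, 0.5))
  f$r <- 0.9; f$gene_a <- c("gB", "gA"); f$gene_b <- "gZ"
  expect_identical(rankEdges(f)$gene_a, c("gA", "gB"))
})

test_that("buildNetwork finds a planted bimodal co-expressed pair", {
  sam <- designTable()
  set.seed(21)
  ns <- nrow(sam)
  f <- rnorm(ns)
  tshift <- ifelse(sam$tissue == "peel", 3, -3)
  v <- rbind(g1 = tshift + f + 0.4 * rnorm(ns),
             g2 = tshift + f + 0.4 * rnorm(ns),
             g3 = rnorm(ns), g4 = rnorm(ns))
  colnames(v) <- sam$sample_id
  gem <- GEM(v, sampleTable = sam, scale = "log2")
  edges <- buildNetwork(gem, seed = 5)
  tis <- edges[edges$gene_a == "g1" & edges$gene_b == "g2" &
                 startsWith(edges$condition_label, "tissue="), ]
  expect_gte(nrow(tis), 1L)
  expect_true(all(tis$condition_label %in%
                    c("tissue=cortex", "tissue=peel")))
  expect_true(all(tis$n >= 15))
  expect_true(all(abs(tis$r) > 0.5))
})

test_that("network construction is invariant to gene and sample order", {
  sim <- simulateGEM(simConfig(n_genes = 12, n_module_blocks = 2,
                               genes_per_block = 3, n_phased_pairs = 0,
                               n_informative_genes = 2,
                               n_hard_negative_pairs = 0, seed = 13))
  e1 <- buildNetwork(sim$gem, seed = 3)
  # permute genes and samples
  v <- exprValues(sim$gem)
  set.seed(1)
  v2 <- v[sample(nrow(v)), sample(ncol(v))]
  gem2 <- GEM(v2, sampleTable = sim$samples, scale = "log2")
  e2 <- buildNetwork(gem2, seed = 3)
  expect_identical(e1, e2)
})

test_that("an all-noise GEM yields almost no edges", {
  sam <- designTable()
  tot_edges <- 0L; tot_pairs <- 0L
  for (s in 1:3) {
    set.seed(s)
    v <- matrix(rnorm(30 * 80), 30, 80,
                dimnames = list(sprintf("g%02d", 1:30), sam$sample_id))
    gem <- GEM(v, sampleTable = sam, scale = "log2")
    e <- buildNetwork(gem, seed = s)
    tot_edges <- tot_edges + nrow(e)
    tot_pairs <- tot_pairs + choose(30, 2)
  }
  expect_lte(tot_edges / tot_pairs, 0.01)
})
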