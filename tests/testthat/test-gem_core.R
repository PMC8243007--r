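test_that("GEM TSV round trip preserves values, ids and missing mask", {
  m <- matrix(c(0, 1.5, 3, 2.25, NA, 7, 0.1, 4, 9, 1, 2, 3), 3, 4,
              dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  gem <- tinyGEM(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGEM(gem, f)
  back <- readGEM(f)
  expect_identical(dim(back), c(3L, 4L))
  expect_equal(exprValues(back), m)
  expect_true(is.na(exprValues(back)["gB", "s2"]))
  expect_identical(expressionScale(back), "rpkm")
})

test_that("malformed GEM files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(readGEM(f), "g1")
  writeLines(c("gene\ts1\ts2", "g1\t1\tfoo", "g2\t3\t4"), f)
  expect_error(readGEM(f), "foo")
  # NA token is not an error
  writeLines(c("gene\ts1\ts2", "g1\t1\tNA", "g2\t3\t4"), f)
  expect_true(is.na(exprValues(readGEM(f))["g1", "s2"]))
})

test_that("log transform is exact, monotone, and refuses to run twice", {
  m <- matrix(c(0, 3, 1, 7, 0, 15), 2, 3,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  m[2, 2] <- NA
  gem <- tinyGEM(m)
  lg <- logTransform(gem, pseudocount = 1)
  expect_identical(expressionScale(lg), "log2")
  expect_equal(exprValues(lg)["g1", "s1"], 0)       # log2(0 + 1)
  expect_equal(exprValues(lg)["g2", "s1"], 2)       # log2(3 + 1)
  expect_equal(exprValues(lg)["g2", "s3"], 4)       # log2(15 + 1)
  expect_true(is.na(exprValues(lg)["g2", "s2"]))    # missing preserved
  expect_error(logTransform(lg), "already log2")
  expect_error(logTransform(gem, pseudocount = 0), "positive")
  # strict monotonicity per cell
  v1 <- exprValues(gem); v2 <- exprValues(lg)
  ord <- order(v1, na.last = NA)
  expect_true(all(diff(v2[ord]) >= 0))
  # zeros stay zeros
  z <- tinyGEM(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))
  expect_true(all(exprValues(logTransform(z)) == 0))
})

test_that("GEM validity catches bad inputs", {
  m <- matrix(-1, 1, 1, dimnames = list("g", "s"))
  expect_error(GEM(m, scale = "rpkm"), "rpkm")
  expect_silent(GEM(m, scale = "log2"))
  m2 <- matrix(Inf, 1, 1, dimnames = list("g", "s"))
  expect_error(GEM(m2, scale = "log2"), "finite")
})

test_that("sample strings encode membership over all samples", {
  all_s <- paste0("s", 1:6)
  expect_identical(sampleString(c("s1", "s2", "s3"), all_s), "111000")
  expect_identical(sampleString(c("s1", "s3"), all_s, "s6"), "101009")
  dec <- decodeSampleString("101009", all_s)
  expect_identical(dec$mode_samples, c("s1", "s3"))
  expect_identical(dec$missing_samples, "s6")
  expect_error(decodeSampleString("10", all_s), "length")
})

test_that("tidy edge TSV round trip is exact, including the empty table", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTidyEdges(data.frame(), f)
  expect_identical(nrow(readTidyEdges(f)), 0L)
  expect_identical(length(readLines(f)), 1L)  # header only

  edges <- randomEdges(50, paste0("s", 1:12), seed = 7)
  writeTidyEdges(edges, f)
  back <- readTidyEdges(f)
  expect_equal(back, edges[, names(back)], tolerance = 0)
})

test_that("GraphML export is readable and carries attributes", {
  edges <- data.frame(gene_a = c("g1", "g2"), gene_b = c("g2", "g3"),
                      mode_index = 1L, n = 20L, r = c(0.9, -0.5),
                      condition_label = "tissue=peel",
                      proportion_p_A = 1e-5, proportion_p_B = 1e-6,
                      phase_p = c(1e-4, NA), rank_score = 5,
                      sample_string = "111", module = c("peel:1", "peel:2"),
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".graphml")
  ann <- data.frame(gene_id = c("g1", "g9"), de_flag = c(1L, 0L))
  expect_warning(writeGraphML(edges, f, nodeAnnotations = ann), "absent")
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$module, c("peel:1", "peel:2"))
  expect_equal(sort(igraph::E(g)$r), c(-0.5, 0.9))
})
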