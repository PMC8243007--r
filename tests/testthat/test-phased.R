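test_that("identical groups give T2 = 0 and p = 1", {
  A <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 5, 2)
  ht <- hotellingTwoSample(A, A)
  expect_equal(ht@T2, 0)
  expect_equal(ht@p.value, 1)
  expect_equal(ht@mean.shift, c(0, 0))
})

test_that("T2 on a fixed 5+5 example matches a long-hand computation", {
  A <- matrix(c(2.1, 3.3, 1.8, 2.9, 2.5,
                4.0, 5.1, 3.7, 4.8, 4.2), 5, 2)
  B <- matrix(c(3.0, 4.1, 2.7, 3.9, 3.4,
                5.5, 6.3, 5.0, 6.1, 5.8), 5, 2)
  ht <- hotellingTwoSample(A, B)
  # independent long-hand route: explicit sums, no cov()/solve() shortcuts
  m1 <- c(sum(A[, 1]), sum(A[, 2])) / 5
  m2 <- c(sum(B[, 1]), sum(B[, 2])) / 5
  cc <- function(M, m) {
    s11 <- sum((M[, 1] - m[1])^2); s22 <- sum((M[, 2] - m[2])^2)
    s12 <- sum((M[, 1] - m[1]) * (M[, 2] - m[2]))
    matrix(c(s11, s12, s12, s22), 2) / (nrow(M) - 1)
  }
  Sp <- (4 * cc(A, m1) + 4 * cc(B, m2)) / 8
  d <- m1 - m2
  det <- Sp[1, 1] * Sp[2, 2] - Sp[1, 2]^2
  Sinv <- matrix(c(Sp[2, 2], -Sp[1, 2], -Sp[1, 2], Sp[1, 1]), 2) / det
  T2_hand <- (5 * 5 / 10) * drop(d %*% Sinv %*% d)
  expect_equal(ht@T2, T2_hand, tolerance = 1e-10)
  expect_equal(ht@df1, 2)
  expect_equal(ht@df2, 7)
  F_hand <- (10 - 2 - 1) / (2 * (10 - 2)) * T2_hand
  expect_equal(ht@p.value, pf(F_hand, 2, 7, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("the 1-D case reduces to the squared two-sample t statistic", {
  set.seed(10)
  a <- matrix(rnorm(8), ncol = 1)
  b <- matrix(rnorm(9, 1), ncol = 1)
  ht <- hotellingTwoSample(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(ht@T2, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ht@p.value, tt$p.value, tolerance = 1e-10)
})

test_that("group swap negates the shift but fixes T2, F and p", {
  set.seed(11)
  A <- matrix(rnorm(24), 12, 2)
  B <- matrix(rnorm(16, 0.5), 8, 2)
  h1 <- hotellingTwoSample(A, B)
  h2 <- hotellingTwoSample(B, A)
  expect_identical(h1@T2, h2@T2)
  expect_identical(h1@F.stat, h2@F.stat)
  expect_identical(h1@p.value, h2@p.value)
  expect_equal(h1@mean.shift, -h2@mean.shift)
})

test_that("T2 is invariant under a common nonsingular linear map", {
  set.seed(12)
  A <- matrix(rnorm(30), 15, 2)
  B <- matrix(rnorm(30, 0.8), 15, 2)
  M <- matrix(c(2, 0.5, -1, 3), 2, 2)
  h1 <- hotellingTwoSample(A, B)
  h2 <- hotellingTwoSample(A %*% M, B %*% M)
  expect_equal(h1@T2, h2@T2, tolerance = 1e-8)
})

test_that("small groups and degenerate covariances are handled", {
  expect_error(hotellingTwoSample(matrix(rnorm(4), 2), matrix(rnorm(10), 5)),
               "at least 3")
  # perfectly collinear coordinates: ridge keeps the test defined
  a <- cbind(1:6, (1:6) * 2)
  b <- cbind(2:7, (2:7) * 2)
  ht <- hotellingTwoSample(a, b)
  expect_true(is.finite(ht@T2))
})

test_that("empirical power is monotone in the planted shift", {
  set.seed(13)
  deltas <- c(0, 1, 2)
  rej <- vapply(deltas, function(d) {
    mean(vapply(seq_len(300), function(i) {
      A <- matrix(rnorm(40), 20, 2)
      B <- matrix(rnorm(40, d / sqrt(2)), 20, 2)
      hotellingTwoSample(A, B)@p.value < 0.001
    }, TRUE))
  }, 1)
  expect_true(all(diff(rej) >= -0.02))
  expect_lt(rej[1], 0.02)
  expect_gt(rej[3], 0.8)
})

test_that("phased edges are detected in a planted network", {
  sim <- simulateGEM(simConfig(n_genes = 30, n_module_blocks = 2,
                               genes_per_block = 5, n_phased_pairs = 10,
                               n_informative_genes = 2,
                               n_hard_negative_pairs = 0, seed = 31))
  edges <- buildNetwork(sim$gem, seed = 131)
  annotated <- detectPhasedEdges(edges, sim$gem, retain = FALSE)
  expect_identical(nrow(annotated), nrow(edges))
  # only tissue-associated edges get a phase p-value
  expect_true(all(is.na(annotated$phase_p[
    !startsWith(annotated$condition_label, "tissue=")])))
  ph <- detectPhasedEdges(edges, sim$gem, retain = TRUE)
  expect_true(all(ph$phase_p < 0.001))
  expect_true(all(startsWith(ph$condition_label, "tissue=")))
  det <- unique(pairKey(ph$gene_a, ph$gene_b))
  tru <- pairKey(sim$truth$phased_pairs$gene_a, sim$truth$phased_pairs$gene_b)
  expect_gte(mean(tru %in% det), 0.7)   # most planted pairs recovered
})

test_that("analytic Hotelling power matches the noncentral F formula", {
  # spot-check against a direct one-liner
  lam <- (20 * 20 / 40) * sum(c(1.5, 0) * solve(diag(2), c(1.5, 0)))
  direct <- pf(qf(0.999, 2, 37), 2, 37, ncp = lam, lower.tail = FALSE)
  expect_equal(hotellingPower(c(1.5, 0), diag(2), 20, 20), direct,
               tolerance = 1e-12)
})
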