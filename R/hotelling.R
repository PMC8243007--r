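#' Two-sample Hotelling T-squared test
#'
#' Tests equality of the mean vectors of two multivariate samples under a
#' pooled covariance:
#' \deqn{T^2 = \frac{n_1 n_2}{n_1+n_2} (\bar x_1-\bar x_2)^\top
#'   S_p^{-1} (\bar x_1-\bar x_2)}
#' with \eqn{S_p = ((n_1-1)S_1 + (n_2-1)S_2)/(n_1+n_2-2)}, referred to an F
#' distribution via \eqn{F = \frac{n_1+n_2-p-1}{p(n_1+n_2-2)} T^2} with
#' \eqn{(p, n_1+n_2-p-1)} degrees of freedom. With p = 1 this reduces to the
#' squared pooled two-sample t statistic. A singular pooled covariance gets
#' one ridge of \eqn{10^{-8}\,\mathrm{tr}(S_p)} on the diagonal; if still
#' singular the p-value is `NA` (test undefined).
#'
#' @param A,B numeric matrices (rows = observations, columns = the p
#'   coordinates; vectors are treated as one-column matrices). Both groups
#'   need at least 3 observations and `n1 + n2 >= p + 2`.
#' @return a [HotellingTest-class] object.
#' @examples
#' set.seed(1)
#' ht <- hotellingTwoSample(matrix(rnorm(40), 20), matrix(rnorm(40), 20))
#' ht
#' @export
hotellingTwoSample <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B must have the same dimension")
  p <- ncol(A)
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 3 || n2 < 3) stop("each group needs at least 3 observations")
  if (n1 + n2 < p + 2) stop("n1 + n2 must be at least p + 2")
  xbar1 <- colMeans(A); xbar2 <- colMeans(B)
  d <- xbar1 - xbar2
  S1 <- stats::cov(A); S2 <- stats::cov(B)
  Sp <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
  Sinv <- tryCatch(solve(Sp), error = function(e) NULL)
  if (is.null(Sinv)) {
    Sp_r <- Sp + diag(1e-8 * sum(diag(Sp)), p)
    Sinv <- tryCatch(solve(Sp_r), error = function(e) NULL)
  }
  df1 <- p
  df2 <- n1 + n2 - p - 1
  if (is.null(Sinv)) {
    return(new("HotellingTest", T2 = NA_real_, F.stat = NA_real_, df1 = df1,
               df2 = df2, p.value = NA_real_, mean.shift = d,
               n1 = as.integer(n1), n2 = as.integer(n2), S.pooled = Sp))
  }
  T2 <- as.numeric((n1 * n2 / (n1 + n2)) * t(d) %*% Sinv %*% d)
  Fstat <- (df2 / (p * (n1 + n2 - 2))) * T2
  pval <- pf(Fstat, df1, df2, lower.tail = FALSE)
  new("HotellingTest", T2 = T2, F.stat = Fstat, df1 = df1, df2 = df2,
      p.value = pval, mean.shift = d, n1 = as.integer(n1),
      n2 = as.integer(n2), S.pooled = Sp)
}

#' Analytic power of the two-sample Hotelling test
#'
#' Closed-form noncentral-F power: with mean shift `delta` (a p-vector) and
#' common covariance `Sigma`, the noncentrality is
#' \eqn{\lambda = \frac{n_1 n_2}{n_1+n_2}\,\delta^\top\Sigma^{-1}\delta} and
#' power is \eqn{P(F_{p,\,n_1+n_2-p-1;\,\lambda} > F_{crit})}.
#'
#' @param delta true mean difference vector.
#' @param Sigma common covariance matrix.
#' @param n1,n2 group sizes.
#' @param alpha significance level (default 0.001).
#' @return power in \[0, 1\].
#' @export
hotellingPower <- function(delta, Sigma, n1, n2, alpha = 0.001) {
  delta <- as.numeric(delta)
  p <- length(delta)
  lambda <- (n1 * n2 / (n1 + n2)) *
    as.numeric(t(delta) %*% solve(Sigma) %*% delta)
  df1 <- p; df2 <- n1 + n2 - p - 1
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Detect phased edges in a condition-specific network
#'
#' For every tissue-associated edge, the mode's samples are split by
#' `splitFactor` (canopy position by default) and the two groups' 2-D
#' log-expression points for the edge's gene pair are compared with
#' [hotellingTwoSample()]; the p-value is stored in `phase_p`. Edges whose
#' two canopy-position subgroups have significantly different mean vectors
#' (overlapping variance notwithstanding) are "phased". Edges with a
#' subgroup smaller than 3 samples in the mode are skipped (`phase_p`
#' stays `NA`).
#'
#' @param edges edge data.frame from [buildNetwork()].
#' @param gem the [GEM-class] the network was built from.
#' @param samples sample annotation data.frame; defaults to the GEM's.
#' @param splitFactor factor splitting each mode in two (default
#'   `"position"`); must have exactly 2 levels.
#' @param alpha phased-edge significance level (default 0.001).
#' @param retain when `TRUE` (default) return only tissue-associated edges
#'   with `phase_p < alpha` (the phased network); when `FALSE` return all
#'   input edges with `phase_p` annotated where computable.
#' @return edge data.frame.
#' @export
detectPhasedEdges <- function(edges, gem, samples = NULL,
                              splitFactor = "position", alpha = 0.001,
                              retain = TRUE) {
  if (is.null(samples)) samples <- sampleInfo(gem)
  samples <- validateSampleTable(samples, colnames(gem))
  labs <- setNames(compositeFactorValue(samples, splitFactor),
                   samples$sample_id)
  lev <- sort(unique(labs))
  if (length(lev) != 2) stop("splitFactor must have exactly 2 levels")
  v <- exprValues(gem)
  all_samples <- colnames(v)
  edges$phase_p <- rep(NA_real_, nrow(edges))
  is_tissue <- startsWith(edges$condition_label, "tissue=")
  tis <- setNames(samples$tissue, samples$sample_id)
  for (i in which(is_tissue)) {
    dec <- decodeSampleString(edges$sample_string[i], all_samples)
    ms <- dec$mode_samples
    # the test is on canopy-specific samples within the tissue class: drop
    # stray samples of the other tissue that the GMM absorbed into the mode
    ms <- ms[tis[ms] == sub("^tissue=", "", edges$condition_label[i])]
    g1 <- ms[labs[ms] == lev[1L]]
    g2 <- ms[labs[ms] == lev[2L]]
    if (length(g1) < 3 || length(g2) < 3) next
    A <- cbind(v[edges$gene_a[i], g1], v[edges$gene_b[i], g1])
    B <- cbind(v[edges$gene_a[i], g2], v[edges$gene_b[i], g2])
    ht <- hotellingTwoSample(A, B)
    edges$phase_p[i] <- ht@p.value
  }
  if (retain) {
    keep <- is_tissue & !is.na(edges$phase_p) & edges$phase_p < alpha
    edges <- edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges
}
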