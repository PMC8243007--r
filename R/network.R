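#' Correlation of a gene pair within one expression mode
#'
#' Rank (default) or product-moment correlation restricted to the mode's
#' samples, with a two-sided p-value from the t approximation
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.
#'
#' @param x,y named expression vectors of the two genes.
#' @param modeSamples sample ids of the mode (length >= 3).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `r`, `p`, `n`; `r` is `NA` when a gene has zero
#'   variance within the mode (the edge is then dropped upstream).
#' @export
modeCorrelation <- function(x, y, modeSamples,
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(modeSamples) < 3) stop("a mode needs at least 3 samples")
  xs <- x[modeSamples]; ys <- y[modeSamples]
  n <- length(xs)
  if (sd(xs) == 0 || sd(ys) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- cor(xs, ys, method = method)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Minimum sample size to detect a correlation (Fisher-z power analysis)
#'
#' \eqn{n_{req} = \lceil ((z_{1-\alpha/2} + z_{power}) / \mathrm{artanh}|r|)^2
#' + 3 \rceil}; infinite when r = 0.
#'
#' @param r correlation (|r| < 1).
#' @param alpha significance level (default 0.001).
#' @param power target power (default 0.8).
#' @return required sample size (integer, or `Inf` for r = 0).
#' @examples
#' requiredSampleSize(0.9)  # 11
#' requiredSampleSize(0.5)  # 60
#' @export
requiredSampleSize <- function(r, alpha = 0.001, power = 0.8) {
  if (abs(r) >= 1) stop("|r| must be < 1")
  if (r == 0) return(Inf)
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  ceiling(((za + zb) / atanh(abs(r)))^2 + 3)
}

#' Power filter for a mode correlation
#'
#' Keeps a mode only when its size reaches the Fisher-z required sample size
#' for its correlation, so lowly powered clusters are removed.
#'
#' @param r within-mode correlation.
#' @param n mode size.
#' @param alpha,power filter parameters (defaults 0.001 and 0.8).
#' @return logical: keep the mode?
#' @export
powerFilter <- function(r, n, alpha = 0.001, power = 0.8) {
  if (is.na(r)) return(FALSE)
  if (abs(r) >= 1) return(TRUE)   # perfectly correlated: any n is powered
  n >= requiredSampleSize(r, alpha, power)
}

# composite tissue x position label of each sample
compositeFactorValue <- function(samples, factor) {
  switch(factor,
         tissue = samples$tissue,
         position = samples$position,
         tissue_position = paste(samples$position, samples$tissue, sep = "-"),
         stop("unknown factor: ", factor))
}

#' Condition-association tests of proportions for one mode
#'
#' For each level L of `factor`, two one-sided z-tests in the enrichment
#' direction: test A (composition) compares the fraction of mode samples
#' labelled L with the background fraction of L among the pair's complete
#' samples; test B (capture) compares the fraction of L samples that fall
#' inside the mode with the fraction of non-L samples inside the mode. A
#' level is associated when both p-values are below `alpha`. Levels with a
#' degenerate background fraction (0 or 1) are skipped.
#'
#' @param modeSamples sample ids of the mode.
#' @param samples sample annotation data.frame.
#' @param factor one of `"tissue"`, `"position"`, `"tissue_position"`.
#' @param backgroundSamples the pair's complete samples (default: all rows
#'   of `samples`).
#' @param alpha significance level (default 0.001).
#' @return data.frame with one row per tested level: `factor`, `level`,
#'   `label`, `p_in_cluster`, `p_background`, `z_A`, `p_A`, `z_B`, `p_B`,
#'   `significant`.
#' @export
proportionTests <- function(modeSamples, samples,
                            factor = c("tissue", "position",
                                       "tissue_position"),
                            backgroundSamples = samples$sample_id,
                            alpha = 0.001) {
  factor <- match.arg(factor)
  if (!length(modeSamples)) stop("mode is empty")
  labs <- setNames(compositeFactorValue(samples, factor), samples$sample_id)
  bg <- labs[backgroundSamples]
  inmode <- labs[modeSamples]
  N <- length(bg)
  nmode <- length(inmode)
  rows <- lapply(sort(unique(bg)), function(L) {
    p0 <- mean(bg == L)
    if (p0 <= 0 || p0 >= 1) return(NULL)   # degenerate background
    phat <- mean(inmode == L)
    z_A <- (phat - p0) / sqrt(p0 * (1 - p0) / nmode)
    p_A <- pnorm(z_A, lower.tail = FALSE)
    nL <- sum(bg == L)
    p1 <- sum(inmode == L) / nL                     # capture rate of L
    p2 <- (nmode - sum(inmode == L)) / (N - nL)     # capture rate of non-L
    pbar <- nmode / N
    z_B <- (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / nL + 1 / (N - nL)))
    p_B <- pnorm(z_B, lower.tail = FALSE)
    data.frame(factor = factor, level = L,
               label = paste0(factor, "=", L),
               p_in_cluster = phat, p_background = p0,
               z_A = z_A, p_A = p_A, z_B = z_B, p_B = p_B,
               significant = (p_A < alpha) && (p_B < alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}

#' Bias filter: reject correlations driven purely by subgroup mean shifts
#'
#' Given an edge's mode and the sub-levels nested inside its condition label
#' (e.g. the two canopy positions inside a tissue mode), the mode correlation
#' is recomputed after centring each subgroup (subtracting subgroup means of
#' both genes). The edge is kept when the centred correlation is still
#' significant at `alpha` with the same sign as the pooled correlation;
#' otherwise it is flagged as biased. Subgroups with fewer than 3 samples are
#' excluded from the centred check; with fewer than 2 usable subgroups the
#' filter keeps vacuously.
#'
#' @param x,y named expression vectors.
#' @param modeSamples sample ids of the mode.
#' @param subLabels named character vector: sub-level of every sample.
#' @param alpha significance level (default 0.001).
#' @param method correlation method (as in [modeCorrelation()]).
#' @return logical: keep the edge?
#' @export
biasFilter <- function(x, y, modeSamples, subLabels, alpha = 0.001,
                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  labs <- subLabels[modeSamples]
  keepGroups <- names(table(labs))[table(labs) >= 3]
  if (length(keepGroups) < 2) return(TRUE)   # vacuous: nothing to centre
  use <- modeSamples[labs %in% keepGroups]
  pooled <- cor(x[use], y[use], method = method)
  xc <- x[use]; yc <- y[use]
  for (g in keepGroups) {
    idx <- labs[use] == g
    xc[idx] <- xc[idx] - mean(xc[idx])
    yc[idx] <- yc[idx] - mean(yc[idx])
  }
  n <- length(use)
  if (sd(xc) == 0 || sd(yc) == 0) return(FALSE)
  rc <- cor(xc, yc, method = method)
  if (is.na(rc) || sign(rc) != sign(pooled)) return(FALSE)
  if (abs(rc) >= 1) return(TRUE)
  tstat <- rc * sqrt((n - 2) / (1 - rc^2))
  (2 * pt(-abs(tstat), n - 2)) < alpha
}

#' Rank network edges by importance
#'
#' Orders edges by `rank_score` = -log10 of the larger condition p-value,
#' then |r|, then mode size n (all descending), with ties broken by the
#' canonical gene-pair order; the sort is stable, so permuting the input
#' leaves the output unchanged.
#'
#' @param edges edge data.frame.
#' @return the same data.frame, ranked, with `rank_score` filled in.
#' @export
rankEdges <- function(edges) {
  if (!nrow(edges)) { edges$rank_score <- numeric(0); return(edges) }
  worst_p <- pmax(edges$proportion_p_A, edges$proportion_p_B)
  edges$rank_score <- -log10(worst_p)
  o <- order(-edges$rank_score, -abs(edges$r), -edges$n, edges$gene_a,
             edges$gene_b, edges$mode_index, method = "radix")
  out <- edges[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# sub-level factor nested inside a condition factor (for the bias filter)
nestedFactor <- function(factor) {
  switch(factor, tissue = "position", position = "tissue",
         tissue_position = NA_character_)
}

#' Build a condition-specific co-expression network
#'
#' For every unordered pair of `geneSubset` genes: fit the pairwise GMM
#' ([fitPairGMM()]), correlate each retained mode ([modeCorrelation()]),
#' drop underpowered modes ([powerFilter()]), test condition association
#' ([proportionTests()]) for tissue, position and combined tissue/position,
#' keep at most the most significant level per factor, screen each surviving
#' (mode, label) with the [biasFilter()], and rank the resulting edges. A
#' gene pair can contribute several edges (one per mode and associated
#' label). Results are invariant to gene input order and sample column order.
#'
#' @param gem a [GEM-class] (log2 scale recommended).
#' @param samples sample annotation data.frame; defaults to the GEM's.
#' @param geneSubset genes to consider (e.g. Boruta-confirmed); default all.
#' @param minClusterSize smallest usable GMM mode (default 15).
#' @param alpha significance level of the proportion and bias tests
#'   (default 0.001).
#' @param power target power of the correlation power filter (default 0.8).
#' @param maxK largest GMM component count (default 5).
#' @param method correlation method (default `"spearman"`).
#' @param factors condition factors to test.
#' @param seed integer seed for the GMM restarts.
#' @param verbose print progress every 1000 pairs.
#' @return ranked edge data.frame (tidy edge columns; `phase_p` is `NA`
#'   until [detectPhasedEdges()]).
#' @export
buildNetwork <- function(gem, samples = NULL, geneSubset = NULL,
                         minClusterSize = 15, alpha = 0.001, power = 0.8,
                         maxK = 5, method = c("spearman", "pearson"),
                         factors = c("tissue", "position", "tissue_position"),
                         seed = 1, verbose = FALSE) {
  method <- match.arg(method)
  if (is.null(samples)) samples <- sampleInfo(gem)
  samples <- validateSampleTable(samples, colnames(gem))
  v <- exprValues(gem)
  v <- v[, sort(colnames(v)), drop = FALSE]          # column-order invariance
  all_samples <- colnames(v)
  if (is.null(geneSubset)) geneSubset <- rownames(v)
  geneSubset <- sort(unique(geneSubset))
  if (!length(geneSubset)) stop("geneSubset is empty")
  bad <- setdiff(geneSubset, rownames(v))
  if (length(bad)) stop("genes not in GEM: ", paste(head(bad, 5), collapse = ", "))
  if (length(geneSubset) < 2) stop("need at least 2 genes")

  subLabelsOf <- lapply(c("tissue", "position"), function(f)
    setNames(compositeFactorValue(samples, f), samples$sample_id))
  names(subLabelsOf) <- c("tissue", "position")

  set.seed(seed)
  pairs <- combn(geneSubset, 2)
  rows <- vector("list", 256L)
  nr <- 0L
  for (j in seq_len(ncol(pairs))) {
    ga <- pairs[1L, j]; gb <- pairs[2L, j]
    x <- v[ga, ]; y <- v[gb, ]
    pm <- fitPairGMM(x, y, maxK = maxK, minClusterSize = minClusterSize)
    if (!length(pm$modes)) next
    for (m in pm$modes) {
      mc <- modeCorrelation(x, y, m$sample_set, method = method)
      if (is.na(mc$r)) next
      if (!powerFilter(mc$r, mc$n, alpha = alpha, power = power)) next
      sstr <- sampleString(m$sample_set, all_samples, pm$missing_samples)
      for (f in factors) {
        pt_ <- proportionTests(m$sample_set, samples, factor = f,
                               backgroundSamples = pm$complete_samples,
                               alpha = alpha)
        if (!nrow(pt_)) next
        sig <- pt_[pt_$significant, , drop = FALSE]
        if (!nrow(sig)) next
        # at most one associated level per factor: the most significant
        best <- sig[which.min(pmax(sig$p_A, sig$p_B)), , drop = FALSE]
        nf <- nestedFactor(f)
        if (!is.na(nf)) {
          if (!biasFilter(x, y, m$sample_set, subLabelsOf[[nf]],
                          alpha = alpha, method = method)) next
        }
        nr <- nr + 1L
        if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nr]] <- data.frame(
          gene_a = ga, gene_b = gb, mode_index = m$mode_index,
          n = mc$n, r = mc$r, condition_label = best$label,
          proportion_p_A = best$p_A, proportion_p_B = best$p_B,
          phase_p = NA_real_, rank_score = NA_real_,
          sample_string = sstr, stringsAsFactors = FALSE)
      }
    }
    if (verbose && j %% 1000L == 0L)
      message("  processed ", j, "/", ncol(pairs), " pairs, ", nr, " edges")
  }
  edges <- if (nr) do.call(rbind, rows[seq_len(nr)]) else emptyEdgeTable()
  rankEdges(edges)
}
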