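#' Compose per-sample class labels from design factors
#'
#' @param samples sample annotation data.frame.
#' @param factors non-empty subset of `c("tissue", "position", "timepoint")`.
#' @return named character vector of labels (concatenated factor values),
#'   one per sample.
#' @examples
#' ## tissue x position gives 4 classes of 20 in the default design
#' @export
compositeLabels <- function(samples, factors) {
  if (!length(factors)) stop("factors must be non-empty")
  allowed <- c("tissue", "position", "timepoint")
  bad <- setdiff(factors, allowed)
  if (length(bad)) stop("unknown factor(s): ", paste(bad, collapse = ", "))
  vals <- do.call(paste, c(lapply(factors, function(f) samples[[f]]),
                           sep = "."))
  setNames(vals, samples$sample_id)
}

#' Boruta all-relevant feature selection over random forests
#'
#' Implements the Boruta wrapper: each iteration appends one permuted
#' "shadow" copy of every still-undecided gene to the feature matrix (with a
#' floor of 5 shadows so the shadow maximum stays a meaningful bar when few
#' genes remain undecided), fits a random-forest classifier scored by
#' out-of-bag permutation importance (the null-calibrated choice: in-sample
#' impurity importance lets the luckiest noise gene beat its own shadows
#' consistently), and registers a hit for every undecided gene whose
#' importance strictly exceeds the maximum shadow importance. After each
#' iteration two one-sided binomial tests of the hit count against p = 0.5,
#' Bonferroni-corrected across the genes that entered selection, confirm
#' (upper tail) or reject (lower tail) each gene; rejected genes and their
#' shadows are dropped. The loop ends after `nIter` iterations or when no
#' gene is undecided; remaining genes are reported tentative.
#'
#' @param gem a [GEM-class] without missing values (impute or drop first).
#' @param labels per-sample class labels (named by sample id, or in GEM
#'   column order); at least 2 classes with at least 2 samples each.
#' @param nIter maximum Boruta iterations (default 1000).
#' @param alpha significance level of the binomial decision test
#'   (default 0.05).
#' @param numTrees trees per random forest (default 500).
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `status` (confirmed /
#'   rejected / tentative), `hit_count`, `n_trials`, `median_importance`.
#' @export
borutaSelect <- function(gem, labels, nIter = 1000, alpha = 0.05,
                         numTrees = 500, seed = 1) {
  v <- exprValues(gem)
  if (anyNA(v))
    stop("GEM contains missing values; impute or remove those genes before ",
         "feature selection")
  if (!is.null(names(labels))) labels <- labels[colnames(v)]
  if (length(labels) != ncol(v))
    stop("labels must cover every GEM sample")
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (min(table(labels)) < 2) stop("need at least 2 samples per class")
  X <- t(v)                                   # samples x genes
  genes <- colnames(X)
  status <- setNames(rep("tentative", length(genes)), genes)
  hits <- setNames(integer(length(genes)), genes)
  trials <- setNames(integer(length(genes)), genes)
  imp_hist <- setNames(vector("list", length(genes)), genes)

  set.seed(seed)
  for (it in seq_len(nIter)) {
    und <- names(status)[status == "tentative"]
    if (!length(und)) break
    keep <- names(status)[status != "rejected"]
    Xr <- X[, keep, drop = FALSE]
    # shadows: one permuted copy per undecided gene, topped up to >= 5
    shadow_src <- und
    if (length(shadow_src) < 5L)
      shadow_src <- c(shadow_src,
                      sample(keep, 5L - length(shadow_src), replace = TRUE))
    Xs <- X[, shadow_src, drop = FALSE]
    for (k in seq_len(ncol(Xs))) Xs[, k] <- Xs[sample(nrow(Xs)), k]
    colnames(Xs) <- paste0(".shadow.", seq_along(shadow_src))
    dat <- data.frame(Xr, Xs, check.names = FALSE)
    dat$.class <- labels
    rf <- ranger::ranger(dependent.variable.name = ".class", data = dat,
                         num.trees = numTrees, importance = "permutation",
                         num.threads = 1,
                         seed = sample.int(.Machine$integer.max, 1))
    imp <- rf$variable.importance
    shadow_max <- max(imp[startsWith(names(imp), ".shadow.")])
    for (g in und) {
      trials[g] <- trials[g] + 1L
      if (imp[g] > shadow_max) hits[g] <- hits[g] + 1L
      imp_hist[[g]] <- c(imp_hist[[g]], imp[g])
    }
    # decision step: two one-sided binomial tests against p = 0.5,
    # Bonferroni-corrected over the number of genes entering selection (the
    # correction must not weaken as genes are decided, or late confirmations
    # of in-sample-lucky noise genes slip through)
    m0 <- length(genes)
    for (g in und) {
      p_up <- pbinom(hits[g] - 1L, trials[g], 0.5, lower.tail = FALSE)
      p_dn <- pbinom(hits[g], trials[g], 0.5)
      if (p_up * m0 < alpha) status[g] <- "confirmed"
      else if (p_dn * m0 < alpha) status[g] <- "rejected"
    }
  }
  data.frame(gene_id = genes, status = unname(status[genes]),
             hit_count = unname(hits[genes]),
             n_trials = unname(trials[genes]),
             median_importance = vapply(imp_hist[genes], function(h)
               if (length(h)) stats::median(h) else NA_real_, 1),
             stringsAsFactors = FALSE)
}

#' Genes confirmed by a Boruta run
#' @param decisions output of [borutaSelect()]
#' @return character vector of confirmed gene ids (tentative genes are
#'   conservatively excluded)
#' @export
confirmedGenes <- function(decisions) {
  decisions$gene_id[decisions$status == "confirmed"]
}
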