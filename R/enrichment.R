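#' Read a gene-to-GO annotation TSV
#'
#' Expects two tab-separated columns (no header): gene id and a
#' comma-separated list of GO term ids. A line containing a term id that
#' does not match the `GO:` + 7 digit pattern is skipped with a warning;
#' duplicate gene lines are unioned.
#'
#' @param path TSV file path.
#' @return named list mapping gene id to a character vector of GO ids.
#' @export
readGene2GO <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("gene2go file is empty: ", path)
  go <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      warning("line ", i, ": no GO id column; skipped")
      next
    }
    ids <- trimws(strsplit(parts[2L], ",", fixed = TRUE)[[1L]])
    ids <- ids[nzchar(ids)]
    if (!length(ids) || !all(grepl("^GO:[0-9]{7}$", ids))) {
      warning("line ", i, ": malformed GO term id; line skipped")
      next
    }
    g <- parts[1L]
    go[[g]] <- union(go[[g]], ids)
  }
  if (!length(go)) stop("no valid gene2go lines in ", path)
  go
}

#' GO term enrichment by Fisher's exact test (classic mode)
#'
#' For every GO term annotating at least one module gene, a one-sided
#' (enrichment) Fisher's exact test of the 2x2 table (module x term) against
#' the background. The background is restricted to annotated genes; module
#' genes without annotation do not contribute. No GO hierarchy propagation
#' and no multiple-testing correction across terms are applied ("classic"
#' Fisher mode, raw alpha gate).
#'
#' @param moduleGenes character vector of module gene ids.
#' @param background character vector of background gene ids (the analyzed
#'   universe); restricted internally to annotated genes.
#' @param annotations gene-to-GO mapping (named list, see [readGene2GO()]).
#' @param alpha significance gate (default 0.05).
#' @return data.frame sorted by p-value with columns `term_id`, `k` (module
#'   genes with the term), `K` (background genes with the term), `n` (module
#'   size), `N` (background size), `odds_ratio`, `p_value`, `significant`.
#' @export
fisherEnrichment <- function(moduleGenes, background, annotations,
                             alpha = 0.05) {
  background <- intersect(background, names(annotations))
  moduleGenes <- intersect(moduleGenes, background)
  empty <- data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), odds_ratio = numeric(),
                      p_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (!length(moduleGenes)) return(empty)
  N <- length(background)
  n <- length(moduleGenes)
  term2genes <- split(rep(names(annotations[background]),
                          lengths(annotations[background])),
                      unlist(annotations[background], use.names = FALSE))
  rows <- lapply(sort(names(term2genes)), function(tt) {
    genes_t <- term2genes[[tt]]
    k <- length(intersect(genes_t, moduleGenes))
    if (k < 1L) return(NULL)
    K <- length(genes_t)
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2)
    ft <- fisher.test(tab, alternative = "greater")
    data.frame(term_id = tt, k = k, K = K, n = n, N = N,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               significant = ft$p.value < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
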