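#' Fit a bivariate Gaussian mixture to one gene pair
#'
#' Fits 2-D Gaussian mixtures with full covariances to the pairwise-complete
#' expression scatter of a gene pair for K = 1..`maxK` (EM, k-means++
#' initialisation, `nRestarts` restarts for K > 1, relative log-likelihood
#' tolerance `tol`, at most `maxIter` iterations), selects K by minimum BIC,
#' hard-assigns samples to their maximum-responsibility component, and
#' discards components smaller than `minClusterSize` samples.
#'
#' @param x,y named numeric vectors of the two genes' expression over the
#'   same samples (`NA` = missing); names are sample ids.
#' @param maxK largest number of mixture components considered (default 5).
#' @param minClusterSize smallest retained mode (default 15).
#' @param seed optional integer seed (`NULL`: use current RNG stream).
#' @param nRestarts,tol,maxIter EM control parameters.
#' @param earlyStop stop the K search after the first BIC deterioration
#'   (stepwise model search; BIC is effectively unimodal in K here, so the
#'   selected model is unchanged while large-K fits are skipped). Set
#'   `FALSE` to force fitting every K up to `maxK`.
#' @return a `PairModes` list: `modes` (list of `sample_set`, `mean`, `cov`,
#'   `mode_index`), `K_selected`, `bic` (per K), `assignment` (per complete
#'   sample), `responsibilities`, `complete_samples`, `missing_samples`.
#'   When fewer than `minClusterSize` complete samples exist the result has
#'   zero modes and `K_selected = 0`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(40), rnorm(40, 6)); y <- c(rnorm(40), rnorm(40, 6))
#' names(x) <- names(y) <- paste0("s", 1:80)
#' fitPairGMM(x, y, seed = 1)$K_selected
#' @export
fitPairGMM <- function(x, y, maxK = 5, minClusterSize = 15, seed = NULL,
                       nRestarts = 3, tol = 1e-6, maxIter = 200,
                       earlyStop = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.null(names(x))) names(x) <- names(y) <- as.character(seq_along(x))
  ok <- is.finite(x) & is.finite(y)
  empty <- list(modes = list(), K_selected = 0L, bic = rep(NA_real_, maxK),
                assignment = integer(), responsibilities = NULL,
                complete_samples = names(x)[ok],
                missing_samples = names(x)[!ok])
  class(empty) <- "PairModes"
  if (sum(ok) < minClusterSize) return(empty)
  if (!is.null(seed)) set.seed(seed)
  xs <- x[ok]; ys <- y[ok]
  fit <- .cpp_fit_pair_gmm(as.numeric(xs), as.numeric(ys), as.integer(maxK),
                           as.integer(nRestarts), tol, as.integer(maxIter),
                           1e-6, isTRUE(earlyStop))
  assign <- setNames(fit$assignment, names(xs))
  modes <- list()
  mi <- 0L
  for (k in seq_len(fit$K)) {
    members <- names(assign)[assign == k]
    if (length(members) < minClusterSize) next
    mi <- mi + 1L
    modes[[mi]] <- list(mode_index = mi, sample_set = members,
                        mean = fit$means[k, ], cov = fit$covariances[[k]],
                        component = k)
  }
  out <- list(modes = modes, K_selected = fit$K, bic = fit$bic,
              assignment = assign, responsibilities = fit$responsibilities,
              complete_samples = names(xs),
              missing_samples = names(x)[!ok])
  class(out) <- "PairModes"
  out
}

#' @export
print.PairModes <- function(x, ...) {
  cat(sprintf("PairModes: K = %d, %d retained mode(s) of sizes {%s}\n",
              x$K_selected, length(x$modes),
              paste(vapply(x$modes, function(m) length(m$sample_set), 1L),
                    collapse = ", ")))
  invisible(x)
}
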