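#' Simulation configuration for synthetic GEMs
#'
#' Returns the default configuration of [simulateGEM()], optionally
#' overridden. All effect sizes are expressed in units of `noise_sd`, the
#' within-mode marginal standard deviation of a gene on the log2 scale.
#'
#' @param n_genes total number of genes.
#' @param n_replicates biological replicates per tissue x position x
#'   timepoint cell (default 5; with 2 tissues, 2 positions and 4 timepoints
#'   this is the 80-sample design).
#' @param n_module_blocks number of planted co-expression blocks.
#' @param genes_per_block genes per block (each block shares one latent
#'   factor per tissue).
#' @param n_phased_pairs number of planted phased gene pairs; whole blocks
#'   are marked phased, so this must be a multiple of
#'   `choose(genes_per_block, 2)`.
#' @param tissue_mode_separation distance between the two tissue expression
#'   modes, in within-mode SD units.
#' @param phase_shift position-specific mean offset (delta) added to phased
#'   genes within their phased tissue mode, in within-mode SD units.
#' @param noise_sd within-mode marginal SD of a gene (log2 units).
#' @param block_cor within-tissue correlation between two genes of the same
#'   block (fraction of within-mode variance carried by the latent factor).
#' @param n_informative_genes tissue-separated singleton genes (predictive
#'   of tissue but not co-expressed); the planted truth for feature
#'   selection.
#' @param n_hard_negative_pairs uncorrelated gene pairs that receive the
#'   phased mean shift; they should be rejected at edge detection.
#' @param timepoint_trend amplitude (SD units) of a linear time trend shared
#'   by both positions, applied to block genes.
#' @param baseline baseline log2 expression level.
#' @param seed integer seed.
#' @return a named list with class `simConfig`.
#' @export
simConfig <- function(n_genes = 200, n_replicates = 5, n_module_blocks = 6,
                      genes_per_block = 5, n_phased_pairs = 20,
                      tissue_mode_separation = 6, phase_shift = 2,
                      noise_sd = 1, block_cor = 0.75,
                      n_informative_genes = 10, n_hard_negative_pairs = 2,
                      timepoint_trend = 0.3, baseline = 6, seed = 1) {
  cfg <- list(n_genes = n_genes, n_replicates = n_replicates,
              n_module_blocks = n_module_blocks,
              genes_per_block = genes_per_block,
              n_phased_pairs = n_phased_pairs,
              tissue_mode_separation = tissue_mode_separation,
              phase_shift = phase_shift, noise_sd = noise_sd,
              block_cor = block_cor,
              n_informative_genes = n_informative_genes,
              n_hard_negative_pairs = n_hard_negative_pairs,
              timepoint_trend = timepoint_trend, baseline = baseline,
              seed = seed)
  class(cfg) <- "simConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  counts <- c("n_genes", "n_replicates", "n_module_blocks", "genes_per_block",
              "n_phased_pairs", "n_informative_genes", "n_hard_negative_pairs")
  for (f in counts)
    if (cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop(f, " must be a non-negative integer")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$block_cor < 0 || cfg$block_cor >= 1)
    stop("block_cor must be in [0, 1)")
  if (cfg$n_phased_pairs > 0 && cfg$phase_shift == 0)
    stop("phase_shift = 0 with planted phased pairs would make them ",
         "indistinguishable from unphased pairs; refusing")
  if (cfg$n_module_blocks > 0 && cfg$genes_per_block < 2)
    stop("genes_per_block must be >= 2 when blocks are planted")
  structural <- cfg$n_module_blocks * cfg$genes_per_block +
    cfg$n_informative_genes + 2L * cfg$n_hard_negative_pairs
  if (structural > cfg$n_genes)
    stop("planted structure (", structural, " genes) exceeds n_genes (",
         cfg$n_genes, ")")
  if (cfg$n_phased_pairs > 0) {
    ppb <- choose(cfg$genes_per_block, 2)
    if (ppb == 0 || cfg$n_phased_pairs %% ppb != 0)
      stop("n_phased_pairs must be a multiple of choose(genes_per_block, 2) ",
           "(whole blocks are marked phased)")
    if (cfg$n_phased_pairs / ppb > cfg$n_module_blocks)
      stop("not enough blocks to host ", cfg$n_phased_pairs, " phased pairs")
  }
  invisible(cfg)
}

#' Generate a synthetic GEM with planted structure
#'
#' Emulates the study design (2 tissues x 2 canopy positions x 4 timepoints
#' x `n_replicates` biological replicates) on the log2 scale:
#' tissue-separated genes have bimodal expression with the two tissue modes
#' `tissue_mode_separation` within-mode SDs apart; genes of a module block
#' additionally share a per-tissue latent factor so block pairs are
#' co-expressed within each tissue mode; genes of phased blocks receive an
#' extra `phase_shift` SD mean offset for external-position samples within
#' one tissue (the same sign for every gene of the block, so pair shifts are
#' concordant); all remaining genes are independent noise. A small linear
#' time trend shared by both positions is added to block genes so phasing is
#' not confounded with time.
#'
#' @param config a [simConfig()] list.
#' @return list with elements `gem` ([GEM-class], log2 scale), `samples`
#'   (annotation data.frame) and `truth` (planted structure: `phased_pairs`,
#'   `phased_genes`, `module_blocks`, `informative_genes`,
#'   `hard_negative_pairs`, `sample_modes`).
#' @examples
#' sim <- simulateGEM(simConfig(n_genes = 50, n_module_blocks = 2,
#'                              n_phased_pairs = 10, seed = 7))
#' sim$gem
#' @export
simulateGEM <- function(config = simConfig()) {
  cfg <- validateSimConfig(config)
  set.seed(cfg$seed)
  sigma <- cfg$noise_sd

  samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                         timepoint = .TIMEPOINTS, position = .POSITIONS,
                         tissue = .TISSUES, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  samples <- samples[, c("tissue", "position", "timepoint", "replicate")]
  samples$sample_id <- sprintf("%s_%s_%s_r%d", samples$tissue,
                               samples$position, samples$timepoint,
                               samples$replicate)
  samples <- samples[, c("sample_id", "tissue", "position", "timepoint",
                         "replicate")]
  ns <- nrow(samples)

  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  nb <- cfg$n_module_blocks * cfg$genes_per_block
  block_genes <- if (nb) gene_ids[seq_len(nb)] else character()
  block_of <- if (nb) rep(seq_len(cfg$n_module_blocks),
                          each = cfg$genes_per_block) else integer()
  names(block_of) <- block_genes
  inf_genes <- if (cfg$n_informative_genes)
    gene_ids[nb + seq_len(cfg$n_informative_genes)] else character()
  nh <- 2L * cfg$n_hard_negative_pairs
  hard_genes <- if (nh)
    gene_ids[nb + cfg$n_informative_genes + seq_len(nh)] else character()

  n_phased_blocks <- if (cfg$n_phased_pairs)
    cfg$n_phased_pairs / choose(cfg$genes_per_block, 2) else 0L
  phased_blocks <- seq_len(n_phased_blocks)
  phased_genes <- block_genes[block_of %in% phased_blocks]

  tsep_genes <- c(block_genes, inf_genes, hard_genes)
  # random per-gene direction of the tissue separation
  tissue_sign <- setNames(sample(c(-1, 1), length(tsep_genes), replace = TRUE),
                          tsep_genes)
  # per-block phasing attributes: which tissue is phased, shift sign
  phased_tissue <- setNames(sample(.TISSUES, max(n_phased_blocks, 1),
                                   replace = TRUE)[seq_len(n_phased_blocks)],
                            as.character(phased_blocks))
  phase_sign <- setNames(sample(c(-1, 1), max(n_phased_blocks, 1),
                                replace = TRUE)[seq_len(n_phased_blocks)],
                         as.character(phased_blocks))
  block_trend <- if (cfg$n_module_blocks)
    rnorm(cfg$n_module_blocks, 0, cfg$timepoint_trend * sigma) else numeric()

  t_idx <- match(samples$timepoint, .TIMEPOINTS) - 1L
  is_cortex <- samples$tissue == "cortex"
  is_external <- samples$position == "external"

  # per-tissue latent factors, one per block, shared by the block's genes
  latent <- matrix(0, nrow = max(cfg$n_module_blocks, 1L), ncol = ns)
  if (cfg$n_module_blocks)
    for (b in seq_len(cfg$n_module_blocks))
      latent[b, ] <- rnorm(ns)

  a <- sigma * sqrt(cfg$block_cor)       # latent factor loading
  res_block <- sigma * sqrt(1 - cfg$block_cor)

  vals <- matrix(NA_real_, cfg$n_genes, ns,
                 dimnames = list(gene_ids, samples$sample_id))
  for (gi in seq_len(cfg$n_genes)) {
    g <- gene_ids[gi]
    mu <- rep(cfg$baseline, ns)
    res_sd <- sigma
    if (g %in% tsep_genes)
      mu <- mu + tissue_sign[[g]] * cfg$tissue_mode_separation * sigma / 2 *
        ifelse(is_cortex, 1, -1)
    if (g %in% block_genes) {
      b <- block_of[[g]]
      mu <- mu + block_trend[b] * (t_idx / 3 - 0.5)
      if (b %in% phased_blocks) {
        ph <- samples$tissue == phased_tissue[[as.character(b)]] & is_external
        mu <- mu + ph * phase_sign[[as.character(b)]] * cfg$phase_shift * sigma
      }
      vals[gi, ] <- mu + a * latent[b, ] + rnorm(ns, 0, res_block)
    } else {
      if (g %in% hard_genes) {
        pr <- (match(g, hard_genes) - 1L) %/% 2L + 1L   # pair index
        h_tissue <- .TISSUES[1L + pr %% 2L]             # shared within pair
        ph <- samples$tissue == h_tissue & is_external
        mu <- mu + ph * cfg$phase_shift * sigma
      }
      vals[gi, ] <- mu + rnorm(ns, 0, res_sd)
    }
  }

  canonicalPair <- function(g1, g2) {
    data.frame(gene_a = pmin(g1, g2), gene_b = pmax(g1, g2),
               stringsAsFactors = FALSE)
  }
  phased_pairs <- if (length(phased_genes)) {
    do.call(rbind, lapply(phased_blocks, function(b) {
      gs <- block_genes[block_of == b]
      cmb <- combn(gs, 2)
      canonicalPair(cmb[1L, ], cmb[2L, ])
    }))
  } else canonicalPair(character(), character())
  hard_pairs <- if (nh) {
    canonicalPair(hard_genes[seq(1L, nh, 2L)], hard_genes[seq(2L, nh, 2L)])
  } else canonicalPair(character(), character())

  truth <- list(phased_pairs = phased_pairs, phased_genes = phased_genes,
                phased_tissue = phased_tissue,
                module_blocks = block_of, informative_genes = inf_genes,
                hard_negative_pairs = hard_pairs,
                sample_modes = setNames(samples$tissue, samples$sample_id),
                config = cfg)
  gem <- GEM(vals, sampleTable = samples, scale = "log2")
  list(gem = gem, samples = samples, truth = truth)
}

#' Draw two null samples from one bivariate normal
#'
#' Test harness for the Hotelling null: two independent groups from the same
#' zero-mean bivariate normal.
#'
#' @param n1,n2 group sizes (>= 3).
#' @param covariance 2x2 positive semi-definite covariance matrix.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return list with matrices `A` (`n1` x 2) and `B` (`n2` x 2).
#' @export
simulateNullPair <- function(n1, n2, covariance = diag(2), seed = NULL) {
  if (n1 < 3 || n2 < 3) stop("n1 and n2 must both be >= 3")
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8)))
    stop("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1)))
    stop("covariance must be positive semi-definite")
  if (!is.null(seed)) set.seed(seed)
  L <- t(chol(covariance + diag(1e-12, nrow(covariance))))
  draw <- function(n) t(L %*% matrix(rnorm(2 * n), 2, n))
  list(A = draw(n1), B = draw(n2))
}

#' Generate a synthetic gene-to-GO annotation
#'
#' Plants one dedicated GO term per module block (annotating the block's
#' genes plus a small random background) and sprinkles additional random
#' terms, so that module enrichment has a recoverable signal. Synthetic
#' stand-in for a real genes2GO annotation file.
#'
#' @param gene_ids all gene ids of the GEM.
#' @param truth optional truth list from [simulateGEM()]; when given, one
#'   term per block is planted on that block's genes.
#' @param n_random_terms number of additional random terms.
#' @param background_rate probability that a background gene carries a
#'   planted block term.
#' @param seed integer seed.
#' @return named list mapping gene id to a character vector of GO ids.
#' @export
simulateGene2GO <- function(gene_ids, truth = NULL, n_random_terms = 20,
                            background_rate = 0.02, seed = 1) {
  set.seed(seed)
  go <- setNames(vector("list", length(gene_ids)), gene_ids)
  term_i <- 0L
  nextTerm <- function() {
    term_i <<- term_i + 1L
    sprintf("GO:%07d", term_i)
  }
  if (!is.null(truth) && length(truth$module_blocks)) {
    for (b in sort(unique(truth$module_blocks))) {
      tt <- nextTerm()
      members <- names(truth$module_blocks)[truth$module_blocks == b]
      extra <- gene_ids[runif(length(gene_ids)) < background_rate]
      for (g in union(members, extra)) go[[g]] <- c(go[[g]], tt)
    }
  }
  for (k in seq_len(n_random_terms)) {
    tt <- nextTerm()
    size <- sample(3:15, 1)
    for (g in sample(gene_ids, min(size, length(gene_ids))))
      go[[g]] <- c(go[[g]], tt)
  }
  go[vapply(go, length, 1L) > 0L]
}

#' Write a gene-to-GO mapping as TSV (gene id, comma-separated GO ids)
#' @param gene2go named list as returned by [simulateGene2GO()]
#' @param path output file path
#' @export
writeGene2GO <- function(gene2go, path) {
  df <- data.frame(gene_id = names(gene2go),
                   go_terms = vapply(gene2go, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
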