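# shared fixture builders (everything is generated in code)

pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# minimal GEM with named dims
tinyGEM <- function(values, scale = "rpkm", samples = NULL) {
  GEM(values, sampleTable = samples, scale = scale)
}

# a balanced 80-sample annotation table matching the study design
designTable <- function(n_replicates = 5) {
  d <- expand.grid(replicate = seq_len(n_replicates),
                   timepoint = c("T0", "T1", "T2", "T3"),
                   position = c("internal", "external"),
                   tissue = c("cortex", "peel"), stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_%s_r%d", d$tissue, d$position, d$timepoint,
                         d$replicate)
  d[, c("sample_id", "tissue", "position", "timepoint", "replicate")]
}

# random tidy edge table over a fixed sample universe
randomEdges <- function(n_edges, sample_ids, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", 1:40)
  ga <- sample(genes, n_edges, replace = TRUE)
  gb <- sample(genes, n_edges, replace = TRUE)
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  same <- ga == gb
  gb[same] <- paste0(gb[same], "x")
  ss <- vapply(seq_len(n_edges), function(i) {
    code <- sample(c("0", "1", "9"), length(sample_ids), replace = TRUE,
                   prob = c(.4, .5, .1))
    paste(code, collapse = "")
  }, "")
  data.frame(gene_a = ga, gene_b = gb,
             mode_index = sample(1:3, n_edges, TRUE),
             n = sample(15:40, n_edges, TRUE),
             r = round(runif(n_edges, -1, 1), 6),
             condition_label = sample(c("tissue=peel", "tissue=cortex",
                                        "position=external"), n_edges, TRUE),
             proportion_p_A = runif(n_edges, 0, 1e-3),
             proportion_p_B = runif(n_edges, 0, 1e-3),
             phase_p = ifelse(runif(n_edges) < .3, NA, runif(n_edges)),
             rank_score = runif(n_edges, 0, 10),
             sample_string = ss, stringsAsFactors = FALSE)
}

# adjusted Rand index (independent of any clustering package)
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nc2 <- choose(sum(tab), 2)
  expected <- ai * bj / nc2
  (sij - expected) / ((ai + bj) / 2 - expected)
}

# brute-force maximum partition density over all set partitions of <= 8 edges
bruteBestPartition <- function(pairs) {
  pairs$edge_id <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  M <- nrow(pairs)
  parts <- list(list(1L))
  for (i in seq_len(M)[-1]) {
    nxt <- list()
    for (p in parts) {
      for (j in seq_along(p)) {
        q <- p; q[[j]] <- c(q[[j]], i); nxt[[length(nxt) + 1L]] <- q
      }
      nxt[[length(nxt) + 1L]] <- c(p, list(i))
    }
    parts <- nxt
  }
  dens <- function(p) {
    comms <- lapply(p, function(idx) {
      sel <- pairs[idx, , drop = FALSE]
      list(m = nrow(sel),
           n_nodes = length(unique(c(sel$gene_a, sel$gene_b))))
    })
    partitionDensity(comms, M)
  }
  best <- which.max(vapply(parts, dens, 1))
  list(density = dens(parts[[best]]), partition = parts[[best]])
}
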