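# csGCN

Condition-specific gene co-expression networks with phased edge detection.

## What this is for

In factorial transcriptome designs — the motivating case is pear fruit
sampled from 2 tissues (cortex, peel) × 2 canopy positions (internal,
external) × 4 postharvest timepoints × 5 biological replicates, 80 samples
— gene pairs are often co-expressed only within a condition, and pooled
correlation either misses the relationship or manufactures one from
between-condition mean shifts. `csGCN` is for transcriptomics /
systems-biology analysts who want networks whose edges carry an explicit
condition: each edge is a gene pair, one expression *mode*, and a condition
label with association p-values. On top of the condition-specific network
it detects **phased edges**: tissue-specific co-expressed pairs whose two
canopy-position subgroups differ in mean vector while overlapping in
variance — structure a mixture model cannot split into separate modes but
that a multivariate mean test exposes.

## The method in brief

For every gene pair, the 2-D log2-expression scatter is clustered with
bivariate Gaussian mixtures (EM, k-means++ initialisation, BIC over
K = 1..5, modes under 15 samples discarded). Each mode is correlated
separately (Spearman by default) and kept only if its size reaches the
Fisher-z power requirement

> n ≥ ⌈((z₁₋α/₂ + z_power) / artanh|r|)² + 3⌉,  α = 0.001, power = 0.8,

then tested for condition association with two one-sided z-tests of
proportions (composition and capture, both at α = 0.001), screened by a
group-centred bias filter, and ranked. Tissue-associated edges are split
by canopy position and tested with the two-sample Hotelling T²:

> T² = (n₁n₂/(n₁+n₂)) (x̄₁−x̄₂)ᵀ S_p⁻¹ (x̄₁−x̄₂),
> F = ((n₁+n₂−p−1)/(p(n₁+n₂−2))) · T² ~ F(p, n₁+n₂−p−1),  p = 2;

edges with p < 0.001 form the phased network. Modules are found over
*edges* (link communities: Ahn-style edge similarity, McQuitty linkage,
partition-density cut, per connected component), then merged into
meta-modules by node-set Jaccard distance (study presets: threshold 0.3
for peel, 0.6 for cortex), so genes may belong to several modules.
Boruta all-relevant feature selection over random forests funnels the
gene set before network construction, and GO enrichment of meta-modules
uses classic one-sided Fisher's exact tests (α = 0.05). A seeded
synthetic-data generator reproduces the full factorial design with
planted tissue modes, co-expression blocks, phased pairs and informative
genes, so every stage is testable without any download.

## Worked example

```r
library(csGCN)

sim <- simulateGEM(simConfig(n_genes = 60, n_module_blocks = 4,
                             genes_per_block = 5, n_phased_pairs = 20,
                             n_informative_genes = 5, seed = 42))
sim$gem
#> GEM: 60 genes x 80 samples [log2 scale]
#>   sample annotations: sample_id, tissue, position, timepoint, replicate

edges <- buildNetwork(sim$gem, seed = 42)
summarizeNetwork(edges)
#>                         condition n_edges n_genes
#> 1                   tissue=cortex      39      21
#> 2   tissue_position=external-peel      35      22
#> 3                     tissue=peel      35      20
#> 4 tissue_position=external-cortex      33      21
#> 5 tissue_position=internal-cortex       6       6
#> 6   tissue_position=internal-peel       1       2

phased <- detectPhasedEdges(edges, sim$gem)
nrow(phased)
#> [1] 20
head(phased[, c("gene_a", "gene_b", "n", "r", "condition_label", "phase_p")], 3)
#>     gene_a   gene_b  n         r condition_label      phase_p
#> 1 gene0007 gene0009 40 0.9031895     tissue=peel 3.783867e-05
#> 2 gene0001 gene0005 40 0.9024390   tissue=cortex 1.669268e-04
#> 3 gene0008 gene0009 40 0.8900563     tissue=peel 1.354699e-04

lc <- linkCommunities(phased)
length(lc$communities); round(lc$partition_density, 3)
#> [1] 2
#> [1] 1
mergeMetaModules(lc$communities, mergeThresholdPresets["peel"]) |> length()
#> [1] 2
```

Reading the output: the edge taxonomy shows co-expression is dominated by
tissue-specific modes (39 cortex, 35 peel edges), each mode of n = 40
samples — one tissue — with strong within-mode correlation. The phased
network keeps the 20 edges whose position subgroups differ in mean at
α = 0.001; here they recover exactly the 20 planted phased pairs (both
phased blocks), which the link-community stage resolves into 2 modules of
10 edges each, at partition density 1.0 (both are cliques). With the peel
preset threshold the two node-disjoint modules stay separate meta-modules.

The full pipeline — simulate/read, select features, build network, detect
phased edges, find modules, enrich — is one call:

```r
res <- runPipeline(pipelineConfig(outputDir = "run1", seed = 7))
```

which writes tidy edge TSVs, a module table, an enrichment table, GraphML
for Cytoscape, and a manifest JSON with per-stage record counts.

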