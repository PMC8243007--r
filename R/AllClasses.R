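#' GEM: a gene expression matrix container
#'
#' An S4 container for a genes x samples matrix of normalized transcript
#' abundances, extending [SummarizedExperiment::SummarizedExperiment].
#' The single assay `"expr"` stores expression values with `NA` marking
#' missing cells; `colData` carries the sample annotation (tissue, canopy
#' position, timepoint, replicate when available); the `scale` slot records
#' whether values are raw normalized abundances (`"rpkm"`) or
#' `log2(x + pseudocount)` transformed (`"log2"`).
#'
#' @slot scale character, `"rpkm"` or `"log2"`.
#' @export
setClass("GEM", contains = "SummarizedExperiment",
         representation(scale = "character"),
         prototype(scale = "rpkm"))

setValidity("GEM", function(object) {
  msg <- character()
  if (length(object@scale) != 1L || !object@scale %in% c("rpkm", "log2"))
    msg <- c(msg, "scale must be one of 'rpkm', 'log2'")
  if (!"expr" %in% names(assays(object)))
    msg <- c(msg, "assay 'expr' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if ("expr" %in% names(assays(object))) {
    v <- assay(object, "expr")
    if (any(!is.finite(v) & !is.na(v)))
      msg <- c(msg, "non-missing expression values must be finite")
    if (identical(object@scale, "rpkm") && any(v < 0, na.rm = TRUE))
      msg <- c(msg, "rpkm-scale expression values must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GEM
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). `NA` marks missing cells.
#' @param sampleTable optional data.frame of per-sample annotations with a
#'   `sample_id` column (see [readSampleTable()]); rows are matched to the
#'   matrix columns by id.
#' @param scale `"rpkm"` (raw normalized abundance) or `"log2"`.
#' @return a [GEM-class] object.
#' @examples
#' m <- matrix(rexp(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' gem <- GEM(m)
#' dim(gem)
#' @export
GEM <- function(values, sampleTable = NULL, scale = c("rpkm", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene rownames and sample colnames")
  storage.mode(values) <- "double"
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(sampleTable)) {
    sampleTable <- validateSampleTable(sampleTable, colnames(values))
    cd <- DataFrame(sampleTable[match(colnames(values),
                                      sampleTable$sample_id), , drop = FALSE],
                    row.names = colnames(values))
  }
  se <- SummarizedExperiment(assays = list(expr = values), colData = cd)
  new("GEM", se, scale = scale)
}

#' @describeIn GEM expression values (genes x samples, `NA` = missing)
#' @param gem a [GEM-class] object
#' @export
exprValues <- function(gem) assay(gem, "expr")

#' @describeIn GEM the recorded expression scale (`"rpkm"` or `"log2"`)
#' @export
expressionScale <- function(gem) gem@scale

#' @describeIn GEM sample annotation as a data.frame (may have zero columns)
#' @export
sampleInfo <- function(gem) {
  df <- as.data.frame(colData(gem))
  if (!"sample_id" %in% names(df) && nrow(df))
    df <- cbind(sample_id = rownames(df), df)
  df
}

setMethod("show", "GEM", function(object) {
  v <- assay(object, "expr")
  cat(sprintf("GEM: %d genes x %d samples [%s scale]\n",
              nrow(v), ncol(v), object@scale))
  nmiss <- sum(is.na(v))
  if (nmiss) cat(sprintf("  missing cells: %d (%.2f%%)\n",
                         nmiss, 100 * nmiss / length(v)))
  if (ncol(colData(object)))
    cat("  sample annotations:",
        paste(colnames(colData(object)), collapse = ", "), "\n")
})

# Factor levels of the study design; enforced on sample tables.
.TISSUES    <- c("cortex", "peel")
.POSITIONS  <- c("internal", "external")
.TIMEPOINTS <- c("T0", "T1", "T2", "T3")

validateSampleTable <- function(samples, sample_ids = NULL) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "tissue", "position", "timepoint", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample table: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  bad <- setdiff(unique(samples$tissue), .TISSUES)
  if (length(bad)) stop("unknown tissue level(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$position), .POSITIONS)
  if (length(bad)) stop("unknown position level(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$timepoint), .TIMEPOINTS)
  if (length(bad)) stop("unknown timepoint level(s): ", paste(bad, collapse = ", "))
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, samples$sample_id)
    if (length(miss))
      stop("sample table lacks GEM sample id(s): ",
           paste(head(miss, 5L), collapse = ", "))
  }
  samples$replicate <- as.integer(samples$replicate)
  samples
}

#' Two-sample Hotelling T-squared test result
#'
#' Holds the statistic, its F transform, degrees of freedom, p-value, the
#' mean difference vector and pooled covariance of a two-sample Hotelling
#' test (see [hotellingTwoSample()]).
#'
#' @slot T2,F.stat,p.value numeric scalars
#' @slot df1,df2 degrees of freedom of the F reference distribution
#' @slot n1,n2 group sizes
#' @slot mean.shift numeric, \eqn{\bar x_1 - \bar x_2}
#' @slot S.pooled pooled covariance matrix
#' @export
setClass("HotellingTest",
         representation(T2 = "numeric", F.stat = "numeric", df1 = "numeric",
                        df2 = "numeric", p.value = "numeric",
                        mean.shift = "numeric", n1 = "integer", n2 = "integer",
                        S.pooled = "matrix"))

setMethod("show", "HotellingTest", function(object) {
  cat("Two-sample Hotelling T-squared test\n")
  cat(sprintf("  T2 = %.4g, F(%g, %g) = %.4g, p = %.4g\n",
              object@T2, object@df1, object@df2, object@F.stat,
              object@p.value))
  cat(sprintf("  n1 = %d, n2 = %d, mean shift = (%s)\n", object@n1,
              object@n2, paste(signif(object@mean.shift, 4), collapse = ", ")))
})
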