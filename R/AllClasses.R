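#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors metadata SimpleList
NULL

.SCALE_TAGS <- c("counts", "log2cpm", "external_normalized")

#' ExpressionMatrix: a gene-by-sample abundance grid with a declared scale
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] carrying a
#' single `"exprs"` assay plus a `scaleTag` declaring whether values are raw
#' counts, log2-CPM, or an externally normalized log-scale matrix.  The tag
#' guards against double normalization and lets downstream scoring enforce its
#' log-scale contract.
#'
#' @slot scaleTag one of `"counts"`, `"log2cpm"`, `"external_normalized"`.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(scaleTag = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@scaleTag) != 1L || !object@scaleTag %in% .SCALE_TAGS)
    msg <- c(msg, sprintf("scaleTag must be one of: %s",
                          paste(.SCALE_TAGS, collapse = ", ")))
  if (!"exprs" %in% names(assays(object)))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    v <- assay(object, "exprs")
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, "duplicate sample identifiers")
    if (is.null(rownames(v)) || is.null(colnames(v)))
      msg <- c(msg, "gene and sample identifiers are required")
    if (anyNA(v) || any(!is.finite(v)))
      msg <- c(msg, "expression values must be finite and non-missing")
    else if (identical(object@scaleTag, "counts") && any(v < 0))
      msg <- c(msg, "counts matrices must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param scaleTag declared scale of `values`.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' em <- ExpressionMatrix(m, "counts")
#' scaleTag(em)
#' @export
ExpressionMatrix <- function(values, scaleTag = c("counts", "log2cpm",
                                                  "external_normalized")) {
  scaleTag <- match.arg(scaleTag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = SimpleList(exprs = values))
  new("ExpressionMatrix", se, scaleTag = scaleTag)
}

#' @describeIn ExpressionMatrix the declared scale tag.
#' @param x,object an `ExpressionMatrix`.
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @rdname ExpressionMatrix
#' @export
setMethod("scaleTag", "ExpressionMatrix", function(x) x@scaleTag)

#' @describeIn ExpressionMatrix the expression values as a base matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) assay(x, "exprs"))

setMethod("show", "ExpressionMatrix", function(object) {
  v <- exprValues(object)
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(v), ncol(v), scaleTag(object)))
  callNextMethod()
})

#' ConfidentLRPairs: the result of confident ligand-receptor inference
#'
#' Holds the per-pair correlation statistics and pathway evidence produced by
#' [inferConfidentPairs()], together with the full evaluated table (needed to
#' audit the joint BH correction), the supporting-pathway detail, the funnel of
#' record counts through each filtering stage, and the parameters used.
#'
#' @slot results data.frame of confident pairs: `ligand`, `receptor`,
#'   `spearman_r`, `p_value`, `p_adjusted`, `evidence_kinds`,
#'   `n_supporting_pathways`, `supporting_pathways`.
#' @slot evaluated data.frame of every evaluated pair (pre-filter), carrying
#'   the jointly BH-adjusted p-values.
#' @slot supporting named list (by "ligand->receptor") of data.frames with one
#'   row per supporting pathway (`pathway_id`, `pathway_kind`, `n_correlated`,
#'   `n_targets`).
#' @slot funnel named integer vector of stage counts.
#' @slot params list of thresholds used.
#' @export
setClass("ConfidentLRPairs",
  representation(results = "data.frame", evaluated = "data.frame",
                 supporting = "list", funnel = "integer", params = "list")
)

setValidity("ConfidentLRPairs", function(object) {
  msg <- character()
  need <- c("ligand", "receptor", "spearman_r", "p_value", "p_adjusted",
            "evidence_kinds", "n_supporting_pathways", "supporting_pathways")
  if (!all(need %in% names(object@results)))
    msg <- c(msg, "results is missing required columns")
  else if (nrow(object@results)) {
    if (any(object@results$p_adjusted < object@results$p_value - 1e-12))
      msg <- c(msg, "adjusted p-values must be >= raw p-values")
    if (any(!nzchar(object@results$evidence_kinds)))
      msg <- c(msg, "every confident pair needs a non-empty evidence kind")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ConfidentLRPairs data.frame of confident pairs.
#' @param x,object a `ConfidentLRPairs`.
#' @export
setGeneric("confidentPairs", function(x) standardGeneric("confidentPairs"))

#' @rdname ConfidentLRPairs
#' @export
setMethod("confidentPairs", "ConfidentLRPairs", function(x) x@results)

#' @describeIn ConfidentLRPairs named integer vector of stage counts
#'   (`pairs_in`, `pairs_evaluated`, `after_correlation`, `confident_reactome`,
#'   `confident_gobp`, `confident_union`).
#' @export
setGeneric("funnel", function(x) standardGeneric("funnel"))

#' @rdname ConfidentLRPairs
#' @export
setMethod("funnel", "ConfidentLRPairs", function(x) x@funnel)

setMethod("show", "ConfidentLRPairs", function(object) {
  f <- object@funnel
  cat("ConfidentLRPairs\n")
  cat(sprintf("  %d pairs in -> %d evaluated -> %d after correlation filter -> %d confident\n",
              f[["pairs_in"]], f[["pairs_evaluated"]],
              f[["after_correlation"]], f[["confident_union"]]))
  cat(sprintf("  evidence: %d reactome-supported, %d gobp-supported\n",
              f[["confident_reactome"]], f[["confident_gobp"]]))
})

#' PhenotypeAssignment: two-group immune phenotype of a cohort
#'
#' Produced by [wardClusterTwo()].  Samples are cut into two clusters of the
#' Ward/Euclidean dendrogram on z-scored signature profiles; the cluster with
#' the higher mean immune signature score is labelled `immune_infiltrated`,
#' the other `immune_poor`.
#'
#' @slot labels named character vector, one of `"immune_infiltrated"` /
#'   `"immune_poor"` per sample.
#' @slot dendrogram the `hclust` merge structure.
#' @slot scores the z-scored populations-by-samples matrix used for distances.
#' @export
setClass("PhenotypeAssignment",
  representation(labels = "character", dendrogram = "ANY", scores = "matrix")
)

setValidity("PhenotypeAssignment", function(object) {
  msg <- character()
  if (!all(object@labels %in% c("immune_infiltrated", "immune_poor")))
    msg <- c(msg, "labels must be immune_infiltrated or immune_poor")
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by sample id")
  if (length(unique(object@labels)) > 2L)
    msg <- c(msg, "at most two phenotype labels")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhenotypeAssignment named phenotype labels.
#' @param x,object a `PhenotypeAssignment`.
#' @export
setGeneric("phenotypeLabels", function(x) standardGeneric("phenotypeLabels"))

#' @rdname PhenotypeAssignment
#' @export
setMethod("phenotypeLabels", "PhenotypeAssignment", function(x) x@labels)

setMethod("show", "PhenotypeAssignment", function(object) {
  tab <- table(object@labels)
  cat("PhenotypeAssignment:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})
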