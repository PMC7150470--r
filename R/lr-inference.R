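# Confident ligand-receptor inference: correlation filter + downstream
# pathway evidence.  Thresholds are strict inequalities (r > r_min,
# adjusted p < fdr_max), following the printed criteria.

#' Correlation filter over candidate LR pairs
#'
#' For every pair with both genes present in the matrix, computes the Spearman
#' correlation between ligand and receptor expression across samples and a
#' two-sided p-value ([spearmanTest()]), adjusts the p-values jointly across
#' all evaluated pairs with Benjamini-Hochberg, and retains pairs with
#' `r > rMin` and adjusted `p < fdrMax` (both strict).  Pairs whose ligand or
#' receptor is absent from the matrix are dropped, not errors (LR databases
#' always exceed the detected transcriptome); the dropped count is carried as
#' an attribute and messaged.
#'
#' @param em an [ExpressionMatrix-class] (any scale; ranks are used).
#' @param pairs data.frame with columns `ligand`, `receptor` (and optionally
#'   `source`).
#' @param rMin strict lower bound on Spearman r (default 0.5).
#' @param fdrMax strict upper bound on the BH-adjusted p (default 0.01).
#' @return data.frame of retained pairs with columns `ligand`, `receptor`,
#'   `spearman_r`, `p_value`, `p_adjusted`, `n`.  Attributes: `evaluated`
#'   (the full pre-filter table, on which BH was computed) and `nDropped`.
#' @export
correlationFilter <- function(em, pairs, rMin = 0.5, fdrMax = 0.01) {
  stopifnot(is(em, "ExpressionMatrix"))
  pairs <- .validateLRTable(pairs)
  v <- exprValues(em)
  present <- pairs$ligand %in% rownames(v) & pairs$receptor %in% rownames(v)
  nDropped <- sum(!present)
  if (nDropped)
    message(nDropped, " pair(s) dropped: ligand or receptor absent from matrix")
  pairs <- pairs[present, , drop = FALSE]
  if (!nrow(pairs)) {
    out <- data.frame(ligand = character(), receptor = character(),
                      spearman_r = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), n = integer())
    attr(out, "evaluated") <- out
    attr(out, "nDropped") <- nDropped
    return(out)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    spearmanTest(v[pairs$ligand[i], ], v[pairs$receptor[i], ])
  })
  ev <- data.frame(
    ligand = pairs$ligand, receptor = pairs$receptor,
    spearman_r = vapply(res, `[[`, numeric(1L), "r"),
    p_value = vapply(res, `[[`, numeric(1L), "p"),
    n = vapply(res, `[[`, integer(1L), "n"),
    stringsAsFactors = FALSE
  )
  defined <- !is.na(ev$spearman_r)
  ev$p_adjusted <- NA_real_
  ev$p_adjusted[defined] <- bhAdjust(ev$p_value[defined])
  keep <- defined & .strictlyAbove(ev$spearman_r, rMin) &
    ev$p_adjusted < fdrMax
  out <- ev[keep, c("ligand", "receptor", "spearman_r", "p_value",
                    "p_adjusted", "n")]
  rownames(out) <- NULL
  attr(out, "evaluated") <- ev
  attr(out, "nDropped") <- nDropped
  out
}

#' Downstream pathway evidence for receptor activity
#'
#' A pathway containing the receptor supports it when enough of the pathway's
#' downstream target/controlled genes correlate with the receptor across
#' samples: with `n_targets >= 4` available targets, at least 4 must show
#' Spearman `r > rMin`; with only 2 or 3 available targets, all of them must;
#' pathways with 0 or 1 available targets can never support.  Downstream genes
#' absent from the matrix are excluded from `n_targets` (the criterion applies
#' to available targets); the receptor itself is never counted as its own
#' target.
#'
#' @param em an [ExpressionMatrix-class].
#' @param receptor receptor gene id.
#' @param topologies list of topology records (see [readTopology()]).
#' @param rMin strict Spearman threshold for a target to count (default 0.5).
#' @return data.frame of supporting pathways with columns `pathway_id`,
#'   `pathway_kind`, `n_correlated`, `n_targets` (zero rows if none).
#' @export
downstreamEvidence <- function(em, receptor, topologies, rMin = 0.5) {
  stopifnot(is(em, "ExpressionMatrix"))
  v <- exprValues(em)
  if (!receptor %in% rownames(v))
    stop("receptor '", receptor, "' absent from expression matrix")
  rvec <- v[receptor, ]
  rows <- list()
  for (rec in topologies) {
    if (!identical(rec$receptor, receptor)) next
    targets <- setdiff(unique(rec$downstream), receptor)
    targets <- targets[targets %in% rownames(v)]
    nT <- length(targets)
    if (nT <= 1L) next
    rho <- vapply(targets, function(g) .spearmanRho(rvec, v[g, ]), numeric(1L))
    nC <- sum(.strictlyAbove(rho, rMin))
    supports <- (nT >= 4L && nC >= 4L) || (nT %in% 2:3 && nC == nT)
    if (supports)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = rec$pathway_id, pathway_kind = rec$pathway_kind,
        n_correlated = nC, n_targets = nT, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(pathway_id = character(), pathway_kind = character(),
                      n_correlated = integer(), n_targets = integer()))
  do.call(rbind, rows)
}

# pure form of the piecewise support rule, exposed for exhaustive testing
.evidenceRule <- function(nTargets, nCorrelated) {
  (nTargets >= 4L & nCorrelated >= 4L) |
    (nTargets %in% 2:3 & nCorrelated == nTargets)
}

#' Infer confident ligand-receptor pairs
#'
#' The two-stage selection: (1) the joint correlation filter
#' ([correlationFilter()]): ligand-receptor Spearman `r > rMin` with
#' BH-adjusted `p < fdrMax` across all evaluated pairs; (2) downstream
#' receptor-activity evidence ([downstreamEvidence()]) from at least one
#' pathway of either kind (`reactome` pathways or `gobp` terms treated as
#' ad-hoc pathways).  The confident set is the union over evidence kinds; a
#' pair supported by both kinds appears once with both kinds recorded.
#'
#' @param em an [ExpressionMatrix-class] (log scale recommended; ranks used).
#' @param pairs candidate LR table (`ligand`, `receptor`, optional `source`).
#' @param topologies list of topology records.
#' @param rMin strict Spearman threshold for the ligand-receptor correlation
#'   (default 0.5).
#' @param fdrMax strict BH-adjusted p threshold (default 0.01).
#' @param evidenceRMin strict Spearman threshold for receptor-target
#'   correlations (default 0.5).
#' @param skipEvidence if `TRUE`, stage 2 is bypassed and every
#'   correlation-filtered pair is reported (evidence kind `"none"`); used to
#'   audit the funnel.
#' @return a [ConfidentLRPairs-class] object.
#' @export
inferConfidentPairs <- function(em, pairs, topologies, rMin = 0.5,
                                fdrMax = 0.01, evidenceRMin = 0.5,
                                skipEvidence = FALSE) {
  pairs <- .validateLRTable(pairs)
  cf <- correlationFilter(em, pairs, rMin = rMin, fdrMax = fdrMax)
  evaluated <- attr(cf, "evaluated")
  supporting <- list()
  keep <- logical(nrow(cf))
  kinds <- character(nrow(cf))
  nsup <- integer(nrow(cf))
  supIds <- character(nrow(cf))
  if (nrow(cf)) {
    for (i in seq_len(nrow(cf))) {
      if (skipEvidence) {
        keep[i] <- TRUE
        kinds[i] <- "none"
        next
      }
      ev <- downstreamEvidence(em, cf$receptor[i], topologies,
                               rMin = evidenceRMin)
      if (nrow(ev)) {
        keep[i] <- TRUE
        kinds[i] <- paste(sort(unique(ev$pathway_kind)), collapse = ",")
        nsup[i] <- nrow(ev)
        supIds[i] <- paste(ev$pathway_id, collapse = ";")
        supporting[[paste0(cf$ligand[i], "->", cf$receptor[i])]] <- ev
      }
    }
  }
  results <- data.frame(
    ligand = cf$ligand[keep], receptor = cf$receptor[keep],
    spearman_r = cf$spearman_r[keep], p_value = cf$p_value[keep],
    p_adjusted = cf$p_adjusted[keep],
    evidence_kinds = kinds[keep],
    n_supporting_pathways = nsup[keep],
    supporting_pathways = supIds[keep],
    stringsAsFactors = FALSE
  )
  rownames(results) <- NULL
  hasKind <- function(k) sum(grepl(k, results$evidence_kinds, fixed = TRUE))
  funnel <- c(
    pairs_in = nrow(pairs),
    pairs_evaluated = nrow(evaluated),
    after_correlation = nrow(cf),
    confident_reactome = if (skipEvidence) NA_integer_ else hasKind("reactome"),
    confident_gobp = if (skipEvidence) NA_integer_ else hasKind("gobp"),
    confident_union = nrow(results)
  )
  new("ConfidentLRPairs", results = results, evaluated = evaluated,
      supporting = supporting,
      funnel = vapply(funnel, as.integer, integer(1L)),
      params = list(rMin = rMin, fdrMax = fdrMax, evidenceRMin = evidenceRMin,
                    skipEvidence = skipEvidence))
}

#' Write confident pairs as TSV
#' @param x a [ConfidentLRPairs-class].
#' @param path output path.
#' @export
writeConfidentPairs <- function(x, path) {
  stopifnot(is(x, "ConfidentLRPairs"))
  utils::write.table(confidentPairs(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
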