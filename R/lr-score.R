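# Per-sample LR co-occurrence scores, signature scoring, immune-correlated
# pair selection, phenotype clustering and the display winsorization.

#' Per-sample ligand-receptor co-occurrence score
#'
#' The regularized geometric mean
#' `score_s = sqrt(l_s * r_s) / (mu + sqrt(l_s * r_s))`,
#' with `l_s`, `r_s` the (non-negative, log-scale) expressions of ligand and
#' receptor in sample `s` and `mu` a cohort-level regularizer defaulting to
#' the mean of all matrix values.  The score is bounded in `[0, 1)`, symmetric
#' in ligand and receptor, monotone in each, zero when either gene is silent,
#' and equals 0.5 exactly when `sqrt(l * r) = mu`.  A plain geometric mean
#' (`method = "geometric"`, unbounded) is available for sensitivity analysis.
#'
#' @param em an [ExpressionMatrix-class] on a log scale with non-negative
#'   values.
#' @param ligand,receptor gene ids, both present in `em`.
#' @param mu positive regularizer; default `mean(exprValues(em))`.
#' @param method `"regularized"` (default) or `"geometric"`.
#' @return named numeric vector of per-sample scores.
#' @export
lrScore <- function(em, ligand, receptor, mu = NULL,
                    method = c("regularized", "geometric")) {
  stopifnot(is(em, "ExpressionMatrix"))
  method <- match.arg(method)
  v <- exprValues(em)
  for (g in c(ligand, receptor))
    if (!g %in% rownames(v)) stop("gene '", g, "' absent from matrix")
  if (any(v[c(ligand, receptor), ] < 0))
    stop("negative expression values: lrScore requires a non-negative log scale")
  if (is.null(mu)) mu <- mean(v)
  stopifnot(is.numeric(mu), length(mu) == 1L, mu > 0)
  g <- sqrt(v[ligand, ] * v[receptor, ])
  if (method == "geometric") g else g / (mu + g)
}

#' LR-score matrix for a set of pairs
#'
#' @param em an [ExpressionMatrix-class] (log scale).
#' @param pairs data.frame with `ligand`, `receptor`.
#' @param ... passed to [lrScore()] (`mu`, `method`).
#' @return numeric matrix, pairs (named `"ligand->receptor"`) by samples.
#' @export
lrScoreMatrix <- function(em, pairs, ...) {
  stopifnot(nrow(pairs) > 0)
  out <- t(vapply(seq_len(nrow(pairs)), function(i) {
    lrScore(em, pairs$ligand[i], pairs$receptor[i], ...)
  }, numeric(ncol(em))))
  rownames(out) <- paste0(pairs$ligand, "->", pairs$receptor)
  colnames(out) <- colnames(em)
  out
}

#' Cell-type signature score
#'
#' Per-sample arithmetic mean of log-scale expression over the signature's
#' marker genes present in the matrix.  Absent markers are excluded with a
#' message; a signature with no marker present is an error naming the
#' population.
#'
#' @param em an [ExpressionMatrix-class] (log scale).
#' @param markers character vector of marker gene ids.
#' @param population population label (for error messages).
#' @return named numeric vector of per-sample scores.
#' @export
signatureScore <- function(em, markers, population = "signature") {
  stopifnot(is(em, "ExpressionMatrix"), length(markers) > 0)
  v <- exprValues(em)
  present <- intersect(markers, rownames(v))
  if (!length(present))
    stop("no marker of population '", population, "' present in matrix")
  if (length(present) < length(markers))
    message(length(markers) - length(present), " marker(s) of '", population,
            "' absent from matrix")
  colMeans(v[present, , drop = FALSE])
}

#' Signature score matrix (populations x samples)
#'
#' @param em an [ExpressionMatrix-class] (log scale).
#' @param signatures named list of marker vectors (as from [readGMT()]).
#' @param standardize z-score each population across samples (default `TRUE`;
#'   cohort-internal standardization replaces any external reference
#'   normalization).
#' @return numeric matrix, populations by samples.
#' @export
signatureScoreMatrix <- function(em, signatures, standardize = TRUE) {
  stopifnot(length(signatures) > 0, !is.null(names(signatures)))
  out <- t(vapply(names(signatures), function(p) {
    signatureScore(em, signatures[[p]], p)
  }, numeric(ncol(em))))
  colnames(out) <- colnames(em)
  if (standardize) out <- .zscoreRows(out)
  out
}

# z-score rows across samples; constant rows become all-zero
.zscoreRows <- function(m) {
  mu <- rowMeans(m)
  sd_ <- apply(m, 1L, stats::sd)
  sd_[sd_ == 0] <- 1
  sweep(sweep(m, 1L, mu, `-`), 1L, sd_, `/`)
}

#' Select LR pairs correlated with immune signatures
#'
#' Emits every (pair, population) combination whose per-sample LR-score has
#' Spearman `r > rMin` (strict) with the population's signature score.  A pair
#' is selected when it passes for at least one immune population.
#'
#' @param lrScores pairs-by-samples matrix ([lrScoreMatrix()]).
#' @param sigScores populations-by-samples matrix ([signatureScoreMatrix()]);
#'   column order must match `lrScores`.
#' @param rMin strict Spearman threshold (default 0.6).
#' @return data.frame with `pair`, `population`, `spearman_r` (one row per
#'   passing combination); attribute `selected` holds the unique selected
#'   pair names.
#' @export
immuneCorrelatedPairs <- function(lrScores, sigScores, rMin = 0.6) {
  if (!identical(colnames(lrScores), colnames(sigScores)))
    stop("sample ids/order of LR-score and signature-score matrices differ")
  rows <- list()
  for (pr in rownames(lrScores)) {
    for (pop in rownames(sigScores)) {
      r <- .spearmanRho(lrScores[pr, ], sigScores[pop, ])
      if (.strictlyAbove(r, rMin))
        rows[[length(rows) + 1L]] <- data.frame(
          pair = pr, population = pop, spearman_r = r,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character(), population = character(),
               spearman_r = numeric())
  rownames(out) <- NULL
  attr(out, "selected") <- unique(out$pair)
  out
}

#' Two-group immune phenotype by Ward clustering
#'
#' Z-scores each population across samples, computes Euclidean distances
#' between sample profiles, applies Ward linkage (`ward.D2`), cuts the tree
#' into two clusters, and labels the cluster with the higher mean immune
#' signature score `immune_infiltrated` (the other `immune_poor`).  Non-immune
#' populations (e.g. fibroblasts, endothelial cells) can be scored yet
#' excluded from the clustering distance via `excludePopulations`.
#'
#' @param sigMatrix populations-by-samples score matrix (raw or standardized;
#'   rows are z-scored here regardless).
#' @param immunePopulations rows used to orient the labels (default: all rows
#'   used for clustering).
#' @param excludePopulations rows dropped from the distance computation.
#' @return a [PhenotypeAssignment-class].
#' @export
wardClusterTwo <- function(sigMatrix, immunePopulations = NULL,
                           excludePopulations = NULL) {
  stopifnot(is.matrix(sigMatrix))
  if (ncol(sigMatrix) < 2L) stop("need at least 2 samples to cluster")
  use <- setdiff(rownames(sigMatrix), excludePopulations)
  if (!length(use)) stop("no populations left after exclusion")
  z <- .zscoreRows(sigMatrix[use, , drop = FALSE])
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2L)
  if (is.null(immunePopulations)) immunePopulations <- use
  imm <- intersect(immunePopulations, rownames(z))
  if (!length(imm)) stop("no immune population available for label orientation")
  meanScore <- vapply(1:2, function(k) {
    mean(z[imm, cl == k, drop = FALSE])
  }, numeric(1L))
  lab <- if (meanScore[1L] >= meanScore[2L])
    c("immune_infiltrated", "immune_poor") else
    c("immune_poor", "immune_infiltrated")
  labels <- stats::setNames(lab[cl], colnames(sigMatrix))
  new("PhenotypeAssignment", labels = labels, dendrogram = hc,
      scores = z)
}

#' Winsorize values for heat-map display
#'
#' Clips to the `q` and `1 - q` empirical quantiles (type-7), so extreme
#' values no longer dominate a color scale.  `q = 0` is the identity.
#'
#' @param values numeric vector.
#' @param q quantile fraction in `[0, 0.5)` (default 0.025, i.e. a 2.5%
#'   threshold at each end).
#' @return clipped values, same length and order.
#' @export
winsorizeForDisplay <- function(values, q = 0.025) {
  stopifnot(is.numeric(values), q >= 0, q < 0.5)
  if (q == 0 || !length(values)) return(values)
  qs <- stats::quantile(values, c(q, 1 - q), names = FALSE, type = 7)
  pmin(pmax(values, qs[1L]), qs[2L])
}
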