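# Differential-expression post-filters and hypergeometric gene-set
# enrichment.  The model fits producing p, FDR and fold-change (edgeR/limma
# style) are consumed as inputs, never recomputed here.

.checkDE <- function(records, need) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  num <- records[, setdiff(need, c("gene_id", "protein_id")), drop = FALSE]
  if (nrow(records) && any(!vapply(num, is.numeric, logical(1L))))
    stop("non-numeric filter column")
  if (nrow(records) && any(!is.finite(as.matrix(num))))
    stop("non-finite values in filter columns")
  if (nrow(records) && any(records$fold_change < 1))
    stop("fold_change must be expressed as max/min >= 1 (use a direction flag)")
  invisible(records)
}

#' Post-filter differential gene records
#'
#' Keeps genes with `p_value < pMax` and `fdr < fdrMax` (strict) and
#' `fold_change >= fcMin` and `total_normalized_counts >= countsMin`
#' (inclusive: printed as minima).  Defaults are p < 0.01, FDR < 0.01,
#' fold-change >= 2, >= 20 normalized read counts over all samples.
#' Fold-changes are expected as `max(a, b) / min(a, b) >= 1` with direction
#' carried separately.
#'
#' @param records data.frame with `gene_id`, `p_value`, `fdr`, `fold_change`,
#'   `total_normalized_counts`.
#' @param pMax,fdrMax,fcMin,countsMin thresholds.
#' @return the retained rows, input order preserved.
#' @export
filterDEGenes <- function(records, pMax = 0.01, fdrMax = 0.01, fcMin = 2,
                          countsMin = 20) {
  .checkDE(records, c("gene_id", "p_value", "fdr", "fold_change",
                      "total_normalized_counts"))
  keep <- records$p_value < pMax & records$fdr < fdrMax &
    records$fold_change >= fcMin &
    records$total_normalized_counts >= countsMin
  records[keep, , drop = FALSE]
}

#' Post-filter differential protein records
#'
#' Keeps proteins with `p_value < pMax` (strict), `fold_change >= fcMin` and
#' `mean_log10_signal >= signalMin` (inclusive minima).  Defaults are
#' p < 0.05, fold-change >= 1.25, mean log10 signal >= 3.
#'
#' @param records data.frame with `protein_id`, `p_value`, `fold_change`,
#'   `mean_log10_signal`.
#' @param pMax,fcMin,signalMin thresholds.
#' @return the retained rows, input order preserved.
#' @export
filterDEProteins <- function(records, pMax = 0.05, fcMin = 1.25,
                             signalMin = 3) {
  .checkDE(records, c("protein_id", "p_value", "fold_change",
                      "mean_log10_signal"))
  keep <- records$p_value < pMax & records$fold_change >= fcMin &
    records$mean_log10_signal >= signalMin
  records[keep, , drop = FALSE]
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` when drawing `n` items without replacement from a universe of
#' `N` containing `K` successes.  Summed in log space over the point masses
#' to stay accurate for extreme tails (overlap p-values far below 1e-20 occur
#' routinely in gene/protein overlap tests).
#'
#' @param k observed overlap (successes drawn).
#' @param K successes in the universe (e.g. gene-set size).
#' @param n draws (e.g. query size).
#' @param N universe size.
#' @return the tail probability in `[0, 1]`.
#' @examples
#' hypergeometricTail(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeometricTail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N || k > min(K, n))
    stop("inconsistent arguments: need 0 <= k <= min(K, n) <= N")
  if (k == 0) return(1)
  kk <- k:min(K, n)
  lp <- stats::dhyper(kk, m = K, n = N - K, k = n, log = TRUE)
  mx <- max(lp)
  min(1, exp(mx + log(sum(exp(lp - mx)))))
}

#' Hypergeometric gene-set enrichment with the minimum-overlap rule
#'
#' Each gene set is intersected with the universe and tested for
#' over-representation of the query via [hypergeometricTail()].  Only sets
#' with at least `minQueryInSet` query genes are testable; the rule is applied
#' before BH correction, so only testable sets enter the family.  Reported
#' sets satisfy BH-FDR `< fdrMax` (strict).
#'
#' @param query character vector of query genes; must be a subset of
#'   `universe`.
#' @param sets named list of character vectors (e.g. from [readGMT()]).
#' @param universe character vector of background genes.
#' @param minQueryInSet inclusive minimum query genes in a set (default 5).
#' @param fdrMax strict BH-FDR threshold (default 0.05).
#' @param onlySignificant if `FALSE`, return every testable set with its FDR.
#' @return data.frame with `set_id`, `n_query_in_set`, `set_size`,
#'   `universe_size`, `query_size`, `p_value`, `fdr`, sorted by `fdr` then
#'   `set_id`.
#' @export
enrich <- function(query, sets, universe, minQueryInSet = 5, fdrMax = 0.05,
                   onlySignificant = TRUE) {
  query <- unique(query)
  universe <- unique(universe)
  off <- setdiff(query, universe)
  if (length(off))
    stop("query genes outside the universe: ", paste(off, collapse = ", "))
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  N <- length(universe)
  n <- length(query)
  tab <- do.call(rbind, lapply(names(sets), function(id) {
    s <- intersect(unique(sets[[id]]), universe)
    data.frame(set_id = id, n_query_in_set = length(intersect(s, query)),
               set_size = length(s), universe_size = N, query_size = n,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[tab$n_query_in_set >= minQueryInSet, , drop = FALSE]
  if (!nrow(tab)) {
    tab$p_value <- numeric(0)
    tab$fdr <- numeric(0)
    return(tab)
  }
  tab$p_value <- vapply(seq_len(nrow(tab)), function(i) {
    hypergeometricTail(tab$n_query_in_set[i], tab$set_size[i], n, N)
  }, numeric(1L))
  tab$fdr <- bhAdjust(tab$p_value)
  if (onlySignificant) tab <- tab[tab$fdr < fdrMax, , drop = FALSE]
  tab <- tab[order(tab$fdr, tab$set_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
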