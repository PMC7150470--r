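# Independent oracles used to cross-check package computations.  These are
# deliberately naive (enumeration, hand formulas, explicit loops) and share
# no code with the implementation paths they verify.

# all permutations of 1..n, one per row
permsAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permsAll(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    m <- matrix(0L, nrow(sub), n)
    m[, pos] <- n
    m[, -pos] <- sub
    m
  }))
}

# exact two-sided Spearman permutation p by enumerating all n! orderings of y
oracleSpearmanExactP <- function(x, y) {
  n <- length(x)
  robs <- cor(x, y, method = "spearman")
  perms <- permsAll(n)
  rall <- apply(perms, 1L, function(p) cor(x, y[p], method = "spearman"))
  mean(abs(rall) >= abs(robs) - 1e-12)
}

# BH step-up by the textbook formula, written as an explicit loop
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# hypergeometric upper tail by direct summation of binomial-coefficient
# ratios
oracleHyperTail <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# hand-computed Spearman rho (Pearson on mean ranks) and t-approximation p
handSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

handTApproxP <- function(r, n) {
  if (1 - r^2 < .Machine$double.eps) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tt), df = n - 2)
}

# from-scratch reimplementation of the confident-pair selection: hand ranks,
# hand t p-values, hand BH, explicit evidence loops.  Returns the sorted
# "ligand->receptor" keys of confident pairs.
oracleConfidentPairs <- function(mat, pairs, topologies, rMin = 0.5,
                                 fdrMax = 0.01, evRMin = 0.5) {
  ok <- pairs$ligand %in% rownames(mat) & pairs$receptor %in% rownames(mat)
  pairs <- pairs[ok, , drop = FALSE]
  n <- ncol(mat)
  rs <- ps <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    rs[i] <- handSpearman(mat[pairs$ligand[i], ], mat[pairs$receptor[i], ])
    ps[i] <- handTApproxP(rs[i], n)
  }
  adj <- oracleBH(ps)
  keys <- character(0)
  for (i in seq_len(nrow(pairs))) {
    if (!(rs[i] > rMin && adj[i] < fdrMax)) next
    rec <- pairs$receptor[i]
    supported <- FALSE
    for (tp in topologies) {
      if (tp$receptor != rec) next
      targets <- setdiff(unique(tp$downstream), rec)
      targets <- targets[targets %in% rownames(mat)]
      nT <- length(targets)
      if (nT <= 1) next
      nC <- 0
      for (tg in targets)
        if (handSpearman(mat[rec, ], mat[tg, ]) > evRMin) nC <- nC + 1
      if ((nT >= 4 && nC >= 4) || (nT %in% 2:3 && nC == nT)) {
        supported <- TRUE
        break
      }
    }
    if (supported) keys <- c(keys, paste0(pairs$ligand[i], "->", rec))
  }
  sort(keys)
}

# small expression fixture: deterministic log-scale matrix
fixtureExpression <- function(values, genes, samples,
                              tag = "external_normalized") {
  m <- matrix(values, length(genes), length(samples), byrow = TRUE,
              dimnames = list(genes, samples))
  ExpressionMatrix(m, tag)
}
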