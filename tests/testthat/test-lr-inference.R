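# small helper: matrix where chosen pairs are perfectly rank-correlated
.monotoneMatrix <- function(genes, n = 24, seed = 5) {
  set.seed(seed)
  m <- t(vapply(genes, function(g) rnorm(n), numeric(n)))
  dimnames(m) <- list(genes, sprintf("s%02d", seq_len(n)))
  m
}

test_that("correlation filter keeps planted pairs and applies strict thresholds", {
  set.seed(5)
  n <- 24
  rec <- rnorm(n)
  m <- rbind(L1 = exp(rec), R1 = rec, L2 = rnorm(n), R2 = rnorm(n))
  m <- m - min(m)
  colnames(m) <- sprintf("s%02d", 1:n)
  em <- ExpressionMatrix(m, "external_normalized")
  pairs <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"),
                      source = "x")
  out <- correlationFilter(em, pairs)
  expect_identical(out$ligand, "L1")   # monotone transform -> r = 1
  expect_equal(out$spearman_r, 1)
})

test_that("pairs at exactly r = rMin are dropped (strict inequality)", {
  # engineered vectors with Spearman exactly 0.5 at n = 4:
  # ranks (1,2,3,4) vs (2,1,4,3) -> r = 1 - 6*4/(4*15) = 0.6; use threshold 0.6
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  expect_equal(cor(x, y, method = "spearman"), 0.6)
  m <- rbind(L = x, R = y)
  colnames(m) <- paste0("s", 1:4)
  em <- ExpressionMatrix(m, "external_normalized")
  pairs <- data.frame(ligand = "L", receptor = "R", source = "x")
  out <- correlationFilter(em, pairs, rMin = 0.6, fdrMax = 1)
  expect_equal(nrow(out), 0L)  # r == rMin is not r > rMin
  out2 <- correlationFilter(em, pairs, rMin = 0.59, fdrMax = 1.0)
  expect_equal(nrow(out2), 1L)
})

test_that("pairs with absent genes are dropped with a message, not an error", {
  m <- .monotoneMatrix(c("A", "B"))
  em <- ExpressionMatrix(m - min(m), "external_normalized")
  pairs <- data.frame(ligand = c("A", "ZZ"), receptor = c("B", "B"),
                      source = "x")
  expect_message(out <- correlationFilter(em, pairs, fdrMax = 1),
                 "dropped")
  expect_equal(attr(out, "nDropped"), 1L)
  expect_equal(nrow(attr(out, "evaluated")), 1L)
})

test_that("retained count on pure-noise pairs matches the brute-force oracle", {
  set.seed(77)
  n <- 24
  genes <- sprintf("G%03d", 1:200)
  m <- matrix(rnorm(200 * n), 200, n, dimnames = list(genes, paste0("s", 1:n)))
  em <- ExpressionMatrix(m - min(m), "external_normalized")
  pairs <- data.frame(ligand = genes[1:100], receptor = genes[101:200],
                      source = "noise")
  out <- correlationFilter(em, pairs, rMin = 0.3, fdrMax = 0.25)
  ev <- attr(out, "evaluated")
  radj <- oracleBH(vapply(1:100, function(i)
    handTApproxP(handSpearman(m[pairs$ligand[i], ], m[pairs$receptor[i], ]),
                 n), numeric(1)))
  rs <- vapply(1:100, function(i)
    handSpearman(m[pairs$ligand[i], ], m[pairs$receptor[i], ]), numeric(1))
  expect_equal(nrow(out), sum(rs > 0.3 & radj < 0.25))
  expect_equal(ev$p_adjusted, radj)
})

test_that("evidence rule is the exact piecewise criterion over all target counts", {
  # receptor expression strictly increasing; correlated targets are monotone
  # transforms (r = 1), uncorrelated targets are reversed (r = -1)
  n <- 12
  recv <- seq_len(n)
  for (nT in 0:8) {
    for (nC in 0:nT) {
      rows <- list(REC = recv)
      targets <- character(0)
      if (nT > 0) {
        for (j in seq_len(nT)) {
          g <- sprintf("T%d", j)
          rows[[g]] <- if (j <= nC) recv^(1 + j / 10) else rev(recv) + j
          targets <- c(targets, g)
        }
      }
      m <- do.call(rbind, rows)
      colnames(m) <- paste0("s", seq_len(n))
      em <- ExpressionMatrix(m, "external_normalized")
      # an extra absent target checks that unavailable genes reduce n_targets
      topo <- list(list(pathway_id = "P1", pathway_kind = "reactome",
                        receptor = "REC",
                        downstream = c(targets, "ABSENT")))
      ev <- downstreamEvidence(em, "REC", topo)
      expected <- (nT >= 4 && nC >= 4) || (nT %in% 2:3 && nC == nT)
      expect_identical(nrow(ev) == 1L, expected,
                       label = sprintf("nT=%d nC=%d", nT, nC))
      if (expected) {
        expect_equal(ev$n_targets, nT)
        expect_equal(ev$n_correlated, nC)
      }
    }
  }
})

test_that("receptor absent from every pathway yields empty evidence", {
  em <- ExpressionMatrix(.monotoneMatrix(c("A", "B")) + 10,
                         "external_normalized")
  expect_equal(nrow(downstreamEvidence(em, "A", list())), 0L)
})

test_that("evidence kinds union: pairs supported by both kinds appear once", {
  n <- 12
  recv <- seq_len(n)
  m <- rbind(LIG = recv + 0.5, REC = recv,
             T1 = recv^1.1, T2 = recv^1.2, T3 = recv^1.3, T4 = recv^1.4)
  colnames(m) <- paste0("s", seq_len(n))
  em <- ExpressionMatrix(m, "external_normalized")
  pairs <- data.frame(ligand = "LIG", receptor = "REC", source = "x")
  topo <- list(
    list(pathway_id = "R1", pathway_kind = "reactome", receptor = "REC",
         downstream = c("T1", "T2", "T3", "T4")),
    list(pathway_id = "G1", pathway_kind = "gobp", receptor = "REC",
         downstream = c("T1", "T2", "T3", "T4"))
  )
  res <- inferConfidentPairs(em, pairs, topo)
  tab <- confidentPairs(res)
  expect_equal(nrow(tab), 1L)
  expect_identical(tab$evidence_kinds, "gobp,reactome")
  expect_equal(tab$n_supporting_pathways, 2L)
  f <- funnel(res)
  expect_equal(f[["confident_reactome"]], 1L)
  expect_equal(f[["confident_gobp"]], 1L)
  expect_equal(f[["confident_union"]], 1L)
})

test_that("confident-pair count is monotone in the thresholds", {
  sc <- simulateCohort(syntheticCohortSpec(nBackgroundGenes = 20, seed = 9))
  em <- normalizeLog2CPM(sc$expression)
  n1 <- funnel(inferConfidentPairs(em, sc$lrPairs, sc$topologies,
                                   rMin = 0.5, fdrMax = 0.01))[["confident_union"]]
  n2 <- funnel(inferConfidentPairs(em, sc$lrPairs, sc$topologies,
                                   rMin = 0.7, fdrMax = 0.01))[["confident_union"]]
  n3 <- funnel(inferConfidentPairs(em, sc$lrPairs, sc$topologies,
                                   rMin = 0.5, fdrMax = 0.001))[["confident_union"]]
  expect_lte(n2, n1)
  expect_lte(n3, n1)
})

test_that("results are independent of pair order (joint BH over the same set)", {
  sc <- simulateCohort(syntheticCohortSpec(nBackgroundGenes = 20, seed = 13))
  em <- normalizeLog2CPM(sc$expression)
  a <- confidentPairs(inferConfidentPairs(em, sc$lrPairs, sc$topologies))
  shuffled <- sc$lrPairs[rev(seq_len(nrow(sc$lrPairs))), ]
  b <- confidentPairs(inferConfidentPairs(em, shuffled, sc$topologies))
  keyA <- paste0(a$ligand, "->", a$receptor)
  keyB <- paste0(b$ligand, "->", b$receptor)
  expect_setequal(keyA, keyB)
  expect_equal(a$p_adjusted[order(keyA)], b$p_adjusted[order(keyB)])
})
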