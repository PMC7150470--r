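test_that("expression TSV round-trips and preserves file order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2",
               "GENE_B\t1\t2",
               "GENE_A\t3.5\t0",
               "GENE_C\t0\t7"), f)
  em <- readExpression(f, "counts")
  expect_s4_class(em, "ExpressionMatrix")
  expect_identical(rownames(em), c("GENE_B", "GENE_A", "GENE_C"))
  expect_identical(colnames(em), c("s1", "s2"))
  expect_equal(exprValues(em)["GENE_A", "s1"], 3.5)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(em, f2)
  em2 <- readExpression(f2, "counts")
  expect_identical(rownames(em2), rownames(em))
  expect_equal(exprValues(em2), exprValues(em), tolerance = 1e-9)
})

test_that("duplicate gene rows collapse by sum for counts, error when normalized", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "GENE_X\t5", "GENE_X\t7"), f)
  em <- readExpression(f, "counts")
  expect_equal(unname(exprValues(em)["GENE_X", "s1"]), 12)
  expect_error(readExpression(f, "log2cpm"), "duplicate gene")
})

test_that("malformed expression input is rejected with informative errors", {
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts1", "G1\t1\t2"), dup)
  expect_error(readExpression(dup, "counts"), "duplicate sample")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "G1\t1\tabc"), bad)
  expect_error(readExpression(bad, "counts"), "s2")

  na <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "G1\tNA"), na)
  expect_error(readExpression(na, "counts"), "missing")
})

test_that("log2-CPM normalization follows the stated formula", {
  m <- matrix(c(10, 0, 0, 0), 2, 2,
              dimnames = list(c("G1", "G2"), c("s1", "s2")))
  m[2, 2] <- 5  # avoid zero library size in s2
  em <- normalizeLog2CPM(ExpressionMatrix(m, "counts"))
  expect_identical(scaleTag(em), "log2cpm")
  # single expressed gene takes the whole library: count*1e6/10 for count 10
  expect_equal(unname(exprValues(em)["G1", "s1"]), log2(1 + 1e6))
  # all-zero gene in a sample maps to log2(1) = 0
  expect_equal(unname(exprValues(em)["G2", "s1"]), 0)
})

test_that("normalization is idempotent-guarded, scale-invariant and monotone", {
  set.seed(11)
  m <- matrix(rpois(60, 40), 6, 10,
              dimnames = list(paste0("G", 1:6), paste0("s", 1:10)))
  em <- ExpressionMatrix(m, "counts")
  norm <- normalizeLog2CPM(em)
  expect_error(normalizeLog2CPM(norm), "counts")
  # doubling all counts of a sample leaves its CPM column unchanged
  m2 <- m; m2[, 3] <- 2 * m2[, 3]
  norm2 <- normalizeLog2CPM(ExpressionMatrix(m2, "counts"))
  expect_equal(exprValues(norm2)[, 3], exprValues(norm)[, 3])
  # monotone within each sample
  for (s in 1:10) {
    o <- order(m[, s])
    expect_true(all(diff(exprValues(norm)[o, s]) >= 0))
  }
  # zero library size names the offending sample
  m3 <- m; m3[, 2] <- 0
  expect_error(normalizeLog2CPM(ExpressionMatrix(m3, "counts")), "s2")
})

test_that("ExpressionMatrix validity rejects NA, duplicates and negative counts", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("x", "y")))
  expect_s4_class(ExpressionMatrix(m, "counts"), "ExpressionMatrix")
  mneg <- m; mneg[1, 1] <- -1
  expect_error(ExpressionMatrix(mneg, "counts"), "non-negative")
  mdup <- m; rownames(mdup) <- c("A", "A")
  expect_error(ExpressionMatrix(mdup, "counts"), "duplicate")
  mna <- m; mna[2, 2] <- NA
  expect_error(ExpressionMatrix(mna, "counts"), "finite")
})

test_that("GMT signatures round-trip and reject degenerate sets", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T_cells\tdesc\tCD3D\tCD3E",
               "B_cells\tdesc\tCD19\tMS4A1\tCD79A"), f)
  sigs <- readGMT(f)
  expect_named(sigs, c("T_cells", "B_cells"))
  expect_identical(sigs$T_cells, c("CD3D", "CD3E"))
  f2 <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(sigs, f2)
  expect_identical(readGMT(f2), sigs)

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines("NK_cells\tdesc", empty)
  expect_error(readGMT(empty), "empty marker set")
})

test_that("LR tables round-trip and duplicates are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ligand\treceptor\tsource",
               "CD274\tPDCD1\tliterature",
               "LGALS9\tHAVCR2\tliterature"), f)
  tab <- readLRTable(f)
  expect_identical(tab$ligand, c("CD274", "LGALS9"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLRTable(tab, f2)
  expect_identical(readLRTable(f2), tab)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ligand\treceptor\tsource", "A\tB\tx", "A\tB\ty"), dup)
  expect_error(readLRTable(dup), "duplicate")
})

test_that("topologies round-trip and self-regulating receptors are rejected", {
  topo <- list(
    list(pathway_id = "R-1", pathway_kind = "reactome", receptor = "EGFR",
         downstream = c("MYC", "FOS", "JUN")),
    list(pathway_id = "GO-1", pathway_kind = "gobp", receptor = "PDCD1",
         downstream = "BATF")
  )
  f <- withr::local_tempfile(fileext = ".json")
  writeTopology(topo, f)
  back <- readTopology(f)
  expect_length(back, 2L)
  expect_identical(back[[1]]$downstream, c("MYC", "FOS", "JUN"))
  expect_identical(back[[2]]$downstream, "BATF")

  bad <- list(list(pathway_id = "R-2", pathway_kind = "reactome",
                   receptor = "EGFR", downstream = c("EGFR", "MYC")))
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE)
  expect_error(readTopology(f2), "own downstream")
})
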