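#' Read a gene-by-sample expression TSV
#'
#' Expects a tab-delimited file whose header row holds sample ids and whose
#' first column holds gene ids.  Duplicate gene rows are collapsed by summing
#' when `scaleTag = "counts"`; on a normalized scale duplicates are an error
#' (summing log values has no meaning).  Missing or non-numeric cells are
#' rejected: correlation semantics with missing values are undefined here.
#'
#' @param path path to the TSV file.
#' @param scaleTag declared scale of the stored values.
#' @return an [ExpressionMatrix-class].
#' @export
readExpression <- function(path, scaleTag = c("counts", "log2cpm",
                                              "external_normalized")) {
  scaleTag <- match.arg(scaleTag)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header in ", path, ": need a gene-id column plus >=1 sample")
  samples <- header[-1L]
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop("duplicate sample id in header of ", path, ": ",
         paste(unique(dup), collapse = ", "))
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) != length(samples) + 1L)
    stop("malformed row(s) in ", path, ": column count differs from header")
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing cell '%s' at gene row %d, sample '%s'",
                 raw[bad[1L], bad[2L]], bad[1L], samples[bad[2L]]))
  }
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    if (scaleTag != "counts")
      stop("duplicate gene rows in a normalized matrix: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    vals <- rowsum(vals, group = genes, reorder = FALSE)
    genes <- rownames(vals)
  }
  rownames(vals) <- genes
  colnames(vals) <- samples
  ExpressionMatrix(vals, scaleTag)
}

#' Write an expression matrix as TSV (inverse of [readExpression()])
#' @param em an [ExpressionMatrix-class].
#' @param path output path.
#' @export
writeExpression <- function(em, path) {
  v <- exprValues(em)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Library-size normalize counts to log2-CPM
#'
#' `value = log2(1 + count * 1e6 / library_size)` with the library size taken
#' per sample.  Normalization is idempotent-guarded: the input must carry
#' `scaleTag = "counts"`, so renormalizing an already-normalized matrix is an
#' error rather than a silent corruption.
#'
#' @param em an [ExpressionMatrix-class] with `scaleTag = "counts"`.
#' @param pseudocount positive value added inside the log (default 1).
#' @return an [ExpressionMatrix-class] with `scaleTag = "log2cpm"`.
#' @export
normalizeLog2CPM <- function(em, pseudocount = 1) {
  stopifnot(is(em, "ExpressionMatrix"))
  if (scaleTag(em) != "counts")
    stop("normalizeLog2CPM requires a counts matrix; got scaleTag '",
         scaleTag(em), "' (already normalized?)")
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L, pseudocount > 0)
  v <- exprValues(em)
  libsize <- colSums(v)
  if (any(libsize <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(v)[libsize <= 0], collapse = ", "))
  out <- log2(pseudocount + sweep(v, 2L, 1e6 / libsize, `*`))
  ExpressionMatrix(out, "log2cpm")
}

# ---- cell-type signatures (GMT) ----------------------------------------

#' Read cell-type marker signatures from a GMT file
#'
#' Standard GMT: one set per line, tab-delimited `name`, `description`,
#' then marker genes.  Population names must be unique and marker sets
#' non-empty.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (population -> marker genes).
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[`, character(1L), 1L)
  if (anyDuplicated(names_))
    stop("duplicate population names in ", path, ": ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sigs <- lapply(parts, function(p) {
    g <- p[-(1:2)]
    g <- g[nzchar(g)]
    if (!length(g)) stop("empty marker set for population '", p[1L], "'")
    g
  })
  names(sigs) <- names_
  sigs
}

#' Write signatures to GMT (inverse of [readGMT()])
#' @param sigs named list of character vectors.
#' @param path output path.
#' @param description description field, recycled (default `"na"`).
#' @export
writeGMT <- function(sigs, path, description = "na") {
  lines <- vapply(seq_along(sigs), function(i) {
    paste(c(names(sigs)[i], description, sigs[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# ---- ligand-receptor pair tables ---------------------------------------

.validateLRTable <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  need <- c("ligand", "receptor")
  if (!all(need %in% names(pairs)))
    stop("LR table needs columns 'ligand' and 'receptor'")
  if (!"source" %in% names(pairs)) pairs$source <- NA_character_
  key <- paste(pairs$ligand, pairs$receptor, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (ligand, receptor) pair(s): ",
         paste(unique(sub("\r", "->", key[duplicated(key)])), collapse = ", "))
  auto <- pairs$ligand == pairs$receptor
  if (any(auto) && !isTRUE(attr(pairs, "allow_autocrine_same_gene")))
    stop("ligand equals receptor for: ",
         paste(pairs$ligand[auto], collapse = ", "),
         " (set attr 'allow_autocrine_same_gene' to permit)")
  pairs[, c("ligand", "receptor", "source")]
}

#' Read a ligand-receptor pair table
#'
#' Three-column TSV with header `ligand`, `receptor`, `source`.  The
#' (ligand, receptor) key must be unique; a pair with ligand equal to its
#' receptor is rejected unless the table carries the attribute
#' `allow_autocrine_same_gene` (same-gene autocrine loops are rare and almost
#' always data errors).
#'
#' @param path path to the TSV.
#' @return data.frame with columns `ligand`, `receptor`, `source`.
#' @export
readLRTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  .validateLRTable(df)
}

#' Write an LR pair table (inverse of [readLRTable()])
#' @param pairs data.frame with `ligand`, `receptor`, `source`.
#' @param path output path.
#' @export
writeLRTable <- function(pairs, path) {
  utils::write.table(pairs[, c("ligand", "receptor", "source")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- pathway topologies -------------------------------------------------

.validateTopology <- function(topo) {
  stopifnot(is.list(topo))
  need <- c("pathway_id", "pathway_kind", "receptor", "downstream")
  for (rec in topo) {
    if (!all(need %in% names(rec)))
      stop("topology record missing fields: ",
           paste(setdiff(need, names(rec)), collapse = ", "))
    if (!rec$pathway_kind %in% c("reactome", "gobp"))
      stop("pathway_kind must be 'reactome' or 'gobp' in ", rec$pathway_id)
    if (!length(rec$downstream))
      stop("empty downstream set in pathway ", rec$pathway_id)
    if (rec$receptor %in% rec$downstream)
      stop("receptor '", rec$receptor, "' listed in its own downstream set (",
           rec$pathway_id, ")")
  }
  topo
}

#' Read pathway topologies (receptor -> downstream gene sets) from JSON
#'
#' A JSON array of records with fields `pathway_id`, `pathway_kind`
#' (`"reactome"` or `"gobp"`), `receptor`, and `downstream` (array of gene
#' ids).  A receptor may not appear in its own downstream set.
#'
#' @param path path to the JSON file.
#' @return list of topology records.
#' @export
readTopology <- function(path) {
  topo <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  topo <- lapply(topo, function(rec) {
    rec$downstream <- as.character(unlist(rec$downstream))
    rec
  })
  .validateTopology(topo)
}

#' Write pathway topologies to JSON (inverse of [readTopology()])
#' @param topo list of topology records.
#' @param path output path.
#' @export
writeTopology <- function(topo, path) {
  jsonlite::write_json(topo, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
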