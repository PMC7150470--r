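# Config-driven orchestration of the transcriptome and IF pipelines with
# deterministic JSON reports.  Every threshold defaults to the printed value
# the analysis is defined with; reports embed the resolved config and the
# package version so a run can be audited and reproduced byte-identically.

#' Build a run configuration
#'
#' Flat named list of every tunable threshold, each defaulting to the value
#' the analysis is defined with: ligand-receptor Spearman `rMin = 0.5` at
#' BH-FDR `fdrMax = 0.01`, downstream-evidence Spearman 0.5, immune-signature
#' Spearman `rImmune = 0.6`, DE gene filters (p < 0.01, FDR < 0.01,
#' fold-change >= 2, >= 20 counts), DE protein filters (p < 0.05,
#' fold-change >= 1.25, signal >= 3), enrichment (>= 5 query genes,
#' FDR < 0.05), particle filters (circularity > 0.3, area > 50 px^2), crown
#' scale 2, display winsorization 2.5%, M2/M high threshold 0.5, DSR bin
#' edges 5/15/50, ifLR positivity threshold 0.3.
#'
#' @param ... overrides of any default, by name.
#' @param seed integer seed recorded in reports (default 1).
#' @return classed list (`lr_run_config`).
#' @export
runConfig <- function(..., seed = 1) {
  cfg <- list(
    rMin = 0.5, fdrMax = 0.01, evidenceRMin = 0.5, skipEvidence = FALSE,
    rImmune = 0.6,
    deGene = list(pMax = 0.01, fdrMax = 0.01, fcMin = 2, countsMin = 20),
    deProtein = list(pMax = 0.05, fcMin = 1.25, signalMin = 3),
    minQueryInSet = 5, enrichFdrMax = 0.05,
    minCircularity = 0.3, minArea = 50, circularityCap = 1.1,
    crownScale = 2, diameterStat = "median",
    ifLower = 20, ifUpper = 250, ifBinarize = 100, iflrThreshold = 0.3,
    winsorQ = 0.025, m2mHigh = 0.5, dsrBreaks = c(5, 15, 50),
    pseudocount = 1,
    seed = seed
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "lr_run_config")
}

#' Read / write a run configuration as YAML (lossless round-trip)
#' @param path YAML file path.
#' @return for `readRunConfig`, an `lr_run_config`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(runConfig, cfg)
}

#' @rdname readRunConfig
#' @param cfg an `lr_run_config`.
#' @export
writeRunConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "lr_run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the transcriptome pipeline end to end
#'
#' Normalize (when counts are supplied) -> confident-LR inference ->
#' per-sample LR-scores -> signature scores -> two-group phenotype ->
#' immune-correlated pair selection.  The report mirrors the pair funnel:
#' pairs in, pairs evaluated, after the correlation filter, confident by
#' evidence kind, confident union, immune-correlated.
#'
#' @param em an [ExpressionMatrix-class] (counts or log scale).
#' @param lrPairs candidate LR table.
#' @param topologies topology records.
#' @param signatures named list of marker vectors.
#' @param cfg an [runConfig()] object.
#' @return list with `confident` ([ConfidentLRPairs-class]), `lrScores`,
#'   `sigScores`, `phenotype` ([PhenotypeAssignment-class]), `immunePairs`,
#'   and `report` (funnel + resolved config + package version).
#' @export
runTranscriptomePipeline <- function(em, lrPairs, topologies, signatures,
                                     cfg = runConfig()) {
  stopifnot(is(em, "ExpressionMatrix"), inherits(cfg, "lr_run_config"))
  if (scaleTag(em) == "counts")
    em <- normalizeLog2CPM(em, pseudocount = cfg$pseudocount)
  confident <- inferConfidentPairs(em, lrPairs, topologies,
                                   rMin = cfg$rMin, fdrMax = cfg$fdrMax,
                                   evidenceRMin = cfg$evidenceRMin,
                                   skipEvidence = cfg$skipEvidence)
  res <- confidentPairs(confident)
  lrS <- if (nrow(res)) lrScoreMatrix(em, res) else
    matrix(numeric(0), 0, ncol(em), dimnames = list(NULL, colnames(em)))
  sigS <- signatureScoreMatrix(em, signatures)
  phen <- wardClusterTwo(sigS)
  imm <- if (nrow(lrS)) immuneCorrelatedPairs(lrS, sigS, rMin = cfg$rImmune)
    else data.frame(pair = character(), population = character(),
                    spearman_r = numeric())
  fun <- funnel(confident)
  report <- list(
    pipeline = "transcriptome",
    funnel = c(as.list(fun),
               list(immune_correlated = length(unique(imm$pair)))),
    n_samples = ncol(em),
    phenotype_counts = as.list(table(phenotypeLabels(phen))),
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("LRcrosstalk"))
  )
  list(confident = confident, lrScores = lrS, sigScores = sigS,
       phenotype = phen, immunePairs = imm, report = report)
}

#' Run the IF pipeline end to end
#'
#' Preprocess -> detect -> crown averaging -> ifLR-score -> positivity calls
#' ([quantifyIF()]), with the thresholds taken from the config.
#'
#' @param receptorImg,ligandImg native-scale channel matrices.
#' @param cfg an [runConfig()] object.
#' @return list with `cells` and `report` (n_cells, percent_positive,
#'   median_diameter_px, resolved config, package version).
#' @export
runIFPipeline <- function(receptorImg, ligandImg, cfg = runConfig()) {
  stopifnot(inherits(cfg, "lr_run_config"))
  q <- quantifyIF(receptorImg, ligandImg,
                  lower = cfg$ifLower, upper = cfg$ifUpper,
                  binarizeThresh = cfg$ifBinarize,
                  minArea = cfg$minArea, minCircularity = cfg$minCircularity,
                  crownScale = cfg$crownScale,
                  diameterStat = cfg$diameterStat,
                  threshold = cfg$iflrThreshold)
  report <- list(
    pipeline = "if",
    n_cells = q$n_cells,
    percent_positive = q$percent_positive,
    median_diameter_px = q$median_diameter_px,
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("LRcrosstalk"))
  )
  list(cells = q$cells, report = report)
}

#' Write a pipeline report as deterministic JSON
#'
#' No timestamps; identical runs produce byte-identical files.
#'
#' @param report a report list from a pipeline run.
#' @param path output path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
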