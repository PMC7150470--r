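# Seeded synthetic-data generators.  The cohort generator plants rank
# correlations through a Gaussian copula mapped to negative-binomial counts
# (rank structure survives the monotone quantile map, matching the
# pipeline's Spearman machinery); the image generator plants disk-shaped
# receptor-positive cells with or without a ligand halo covering the
# default crown.  Both emit ground truth for recovery testing.

#' Specification for a synthetic expression cohort
#'
#' Defaults describe the benchmark cohort used throughout the package's
#' tests: 24 samples (a bulk-transcriptome cohort of the size the LR
#' inference is designed for), 10 planted ligand-receptor pairs at target
#' Spearman 0.85 with 5 downstream targets each at 0.8, 50 null pairs whose
#' receptors carry 5 uncorrelated targets (so the evidence stage is exercised
#' on them too), a latent immune-infiltration factor splitting the cohort in
#' half with a 3-sd signature shift on 3 populations x 10 markers, 3 checkpoint
#' pairs loaded at 0.8 on the factor, and NB counts with gene means
#' log-uniform on [20, 500] at dispersion 0.4 (moderate bulk RNA-seq
#' overdispersion).
#'
#' @param nSamples samples in the cohort (default 24).
#' @param nBackgroundGenes unstructured NB genes (default 200).
#' @param nPlantedPairs,plantedRho planted LR pairs and their target Spearman.
#' @param nTargets,targetsRho downstream targets per planted receptor and
#'   their receptor correlation.
#' @param nNullPairs independent-noise pairs (each receptor gets `nTargets`
#'   uncorrelated targets and a topology entry).
#' @param infiltratedFraction fraction of samples in the infiltrated group.
#' @param signatureShift between-group shift applied to every immune marker
#'   gene, in units of the within-group marker sd.  Marker noise is a 25%-sd
#'   shared immune-activity fluctuation plus independent noise; the shared
#'   part plus the shift form the latent infiltration factor that checkpoint
#'   pairs load on.
#' @param nPopulations,markersPerPopulation immune signature layout.
#' @param nCheckpointPairs,checkpointLoading checkpoint pairs loaded on the
#'   infiltration factor.
#' @param nbMeanRange,nbDispersion NB marginal parameters (means drawn
#'   log-uniformly from the range; `size = 1/dispersion`).
#' @param seed mandatory integer seed.
#' @return a classed list (`synthetic_cohort_spec`).
#' @export
syntheticCohortSpec <- function(nSamples = 24, nBackgroundGenes = 200,
                                nPlantedPairs = 10, plantedRho = 0.85,
                                nTargets = 5, targetsRho = 0.8,
                                nNullPairs = 50,
                                infiltratedFraction = 0.5,
                                signatureShift = 3,
                                nPopulations = 3, markersPerPopulation = 10,
                                nCheckpointPairs = 3, checkpointLoading = 0.8,
                                nbMeanRange = c(20, 500), nbDispersion = 0.4,
                                seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(abs(plantedRho) < 1, abs(targetsRho) < 1,
            abs(checkpointLoading) < 1 || checkpointLoading == 0,
            infiltratedFraction >= 0, infiltratedFraction <= 1,
            nSamples >= 3)
  structure(as.list(environment()), class = "synthetic_cohort_spec")
}

# latent Pearson correlation giving a target Spearman under bivariate
# normality (inverse of rho_s = (6/pi) asin(rho/2))
.latentFromSpearman <- function(rhoS) 2 * sin(pi * rhoS / 6)

#' Simulate an expression cohort with planted LR structure
#'
#' Draws a latent Gaussian layer with the requested rank-correlation
#' structure and maps every gene through NB quantiles
#' (`qnbinom(pnorm(z), mu, size)`), preserving ranks.  Planted pairs share a
#' latent factor at Pearson `2*sin(pi*rho/6)` so their count-scale Spearman
#' approaches `rho`; each planted receptor's targets correlate with it at
#' `targetsRho` and get a matching `reactome` topology entry (every other
#' planted receptor also gets a duplicate `gobp` entry, exercising the
#' evidence-kind union).  Null receptors get topology entries with
#' uncorrelated targets.  Infiltrated samples shift a latent factor that
#' drives the signature markers and checkpoint pairs.
#'
#' @param spec a [syntheticCohortSpec()].
#' @return list with `expression` (counts [ExpressionMatrix-class]),
#'   `lrPairs`, `topologies`, `signatures`, and `truth` (planted/null pair
#'   tables, checkpoint pairs, infiltration labels and factor values).
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$nSamples
  latent <- list()
  pairRows <- list()
  topo <- list()

  addGene <- function(name, z) latent[[name]] <<- z

  # background genes
  for (i in seq_len(spec$nBackgroundGenes))
    addGene(sprintf("BG%04d", i), stats::rnorm(n))

  # planted pairs with correlated downstream targets
  a <- .latentFromSpearman(spec$plantedRho)
  b <- .latentFromSpearman(spec$targetsRho)
  for (i in seq_len(spec$nPlantedPairs)) {
    rec <- sprintf("REC%02d", i); lig <- sprintf("LIG%02d", i)
    zr <- stats::rnorm(n)
    addGene(rec, zr)
    addGene(lig, a * zr + sqrt(1 - a^2) * stats::rnorm(n))
    targets <- sprintf("%s_T%d", rec, seq_len(spec$nTargets))
    for (tg in targets)
      addGene(tg, b * zr + sqrt(1 - b^2) * stats::rnorm(n))
    pairRows[[length(pairRows) + 1L]] <-
      data.frame(ligand = lig, receptor = rec, source = "planted")
    topo[[length(topo) + 1L]] <- list(
      pathway_id = paste0("RPW_", rec), pathway_kind = "reactome",
      receptor = rec, downstream = targets)
    if (i %% 2L == 0L)
      topo[[length(topo) + 1L]] <- list(
        pathway_id = paste0("GPW_", rec), pathway_kind = "gobp",
        receptor = rec, downstream = targets)
  }

  # null pairs: independent noise, uncorrelated targets
  for (i in seq_len(spec$nNullPairs)) {
    rec <- sprintf("NREC%02d", i); lig <- sprintf("NLIG%02d", i)
    addGene(rec, stats::rnorm(n))
    addGene(lig, stats::rnorm(n))
    targets <- sprintf("%s_T%d", rec, seq_len(spec$nTargets))
    for (tg in targets) addGene(tg, stats::rnorm(n))
    pairRows[[length(pairRows) + 1L]] <-
      data.frame(ligand = lig, receptor = rec, source = "null")
    topo[[length(topo) + 1L]] <- list(
      pathway_id = paste0("RPW_", rec), pathway_kind = "reactome",
      receptor = rec, downstream = targets)
  }

  # infiltration: a group split plus a shared continuous immune-activity
  # fluctuation.  Marker-gene noise decomposes into the shared fluctuation
  # (25% sd) and independent per-marker noise, so the group shift is in
  # units of the total within-group marker sd; checkpoint pairs load on the
  # same shared factor, which is what couples their LR-scores to the
  # signature scores.
  nInf <- round(spec$infiltratedFraction * n)
  infiltrated <- stats::setNames(rep(FALSE, n), sprintf("S%02d", seq_len(n)))
  infiltrated[sample.int(n, nInf)] <- TRUE
  zShared <- stats::rnorm(n)
  sharedSd <- 0.25
  fRaw <- spec$signatureShift * infiltrated + sharedSd * zShared
  f <- as.vector(scale(fRaw))
  popNames <- c("T_cells", "B_cells", "Monocytic_lineage",
                sprintf("POP%d", seq_len(max(0, spec$nPopulations - 3))))
  popNames <- popNames[seq_len(spec$nPopulations)]
  signatures <- list()
  for (p in seq_along(popNames)) {
    markers <- sprintf("SIG%d_M%d", p, seq_len(spec$markersPerPopulation))
    for (mk in markers) {
      zm <- fRaw + sqrt(1 - sharedSd^2) * stats::rnorm(n)
      # standardize before the NB quantile map (affine, rank-preserving):
      # an uncentered latent saturates pnorm() and compresses the shifted
      # group into the top count quantiles
      addGene(mk, as.vector(scale(zm)))
    }
    signatures[[popNames[p]]] <- markers
  }
  ac <- spec$checkpointLoading
  b <- .latentFromSpearman(spec$targetsRho)
  for (i in seq_len(spec$nCheckpointPairs)) {
    lig <- sprintf("CPL%02d", i); rec <- sprintf("CPR%02d", i)
    zr <- ac * f + sqrt(1 - ac^2) * stats::rnorm(n)
    addGene(lig, ac * f + sqrt(1 - ac^2) * stats::rnorm(n))
    addGene(rec, zr)
    targets <- sprintf("%s_T%d", rec, seq_len(spec$nTargets))
    for (tg in targets)
      addGene(tg, b * zr + sqrt(1 - b^2) * stats::rnorm(n))
    pairRows[[length(pairRows) + 1L]] <-
      data.frame(ligand = lig, receptor = rec, source = "checkpoint")
    topo[[length(topo) + 1L]] <- list(
      pathway_id = paste0("RPW_", rec), pathway_kind = "reactome",
      receptor = rec, downstream = targets)
  }

  # NB quantile mapping
  genes <- names(latent)
  mu <- exp(stats::runif(length(genes), log(spec$nbMeanRange[1L]),
                         log(spec$nbMeanRange[2L])))
  size <- 1 / spec$nbDispersion
  counts <- t(vapply(seq_along(genes), function(g) {
    stats::qnbinom(stats::pnorm(latent[[g]]), mu = mu[g], size = size)
  }, numeric(n)))
  dimnames(counts) <- list(genes, names(infiltrated))

  pairs <- do.call(rbind, pairRows)
  list(
    expression = ExpressionMatrix(counts, "counts"),
    lrPairs = pairs,
    topologies = .validateTopology(topo),
    signatures = signatures,
    truth = list(
      plantedPairs = pairs[pairs$source == "planted", ],
      nullPairs = pairs[pairs$source == "null", ],
      checkpointPairs = pairs[pairs$source == "checkpoint", ],
      infiltrated = infiltrated,
      factorValues = stats::setNames(f, names(infiltrated))
    ),
    spec = spec
  )
}

#' Specification for a synthetic IF image pair
#'
#' Defaults emulate a 384x384 field of ~20 receptor-positive cells of radius
#' 9 +/- 1.5 px at receptor intensity 180/255, a ligand halo of intensity 160
#' covering the default crown (annulus from the cell radius out to twice the
#' planted median radius) for positive cells, Gaussian read noise of sd 8
#' added before 8-bit clipping, and clutter (sub-area specks, low-circularity
#' streaks) that the particle filters must remove.
#'
#' @param imageSize `(rows, cols)` in pixels.
#' @param nPositive,nNegative planted cells with / without a ligand halo.
#' @param cellRadiusMean,cellRadiusSd radius distribution (clipped to
#'   `[5, 14]` px).
#' @param receptorIntensity,ligandIntensity disk / halo gray levels (native
#'   0..255 scale).
#' @param backgroundNoiseSd Gaussian read-noise sd.
#' @param nSpecks,nStreaks clutter counts (specks: radius <= 3 disks, area
#'   below the 50 px^2 filter; streaks: 3 px wide bars of length ~50,
#'   circularity below 0.3).
#' @param crownScale crown outer-radius multiple the halo must cover.
#' @param seed mandatory integer seed.
#' @return a classed list (`synthetic_image_spec`).
#' @export
syntheticImageSpec <- function(imageSize = c(384, 384), nPositive = 10,
                               nNegative = 10, cellRadiusMean = 9,
                               cellRadiusSd = 1.5, receptorIntensity = 180,
                               ligandIntensity = 160, backgroundNoiseSd = 8,
                               nSpecks = 4, nStreaks = 2, crownScale = 2,
                               seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(imageSize) == 2L, all(imageSize >= 64),
            nPositive >= 0, nNegative >= 0, crownScale > 1)
  structure(as.list(environment()), class = "synthetic_image_spec")
}

# draw a filled disk of given intensity (0-based center coords)
.paintDisk <- function(img, r0, c0, radius, value) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- max(0, floor(r0 - radius)):min(nr - 1, ceiling(r0 + radius))
  ci <- max(0, floor(c0 - radius)):min(nc - 1, ceiling(c0 + radius))
  d2 <- outer((ri - r0)^2, (ci - c0)^2, `+`)
  sub <- img[ri + 1, ci + 1]
  sub[d2 <= radius^2] <- value
  img[ri + 1, ci + 1] <- sub
  img
}

.paintAnnulus <- function(img, r0, c0, rInner, rOuter, value) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- max(0, floor(r0 - rOuter)):min(nr - 1, ceiling(r0 + rOuter))
  ci <- max(0, floor(c0 - rOuter)):min(nc - 1, ceiling(c0 + rOuter))
  d2 <- outer((ri - r0)^2, (ci - c0)^2, `+`)
  sub <- img[ri + 1, ci + 1]
  sub[d2 > rInner^2 & d2 <= rOuter^2] <- value
  img[ri + 1, ci + 1] <- sub
  img
}

#' Simulate a receptor/ligand IF image pair with ground truth
#'
#' Places non-overlapping disk cells by rejection sampling (centroid
#' separation at least twice the crown outer radius, so no cell's halo can
#' contaminate a neighbour's crown), paints receptor disks for all cells and
#' ligand halos for the positive ones, adds clutter violating the
#' area/circularity filters by construction, then Gaussian read noise
#' clipped to `[0, 255]`.
#'
#' @param spec a [syntheticImageSpec()].
#' @return list with `receptor` and `ligand` image matrices (native 0..255
#'   scale) and `truth` (per-cell centroid, radius, positivity;
#'   `medianDiameter` of the planted cells).
#' @export
simulateIFImage <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  set.seed(spec$seed)
  nr <- spec$imageSize[1L]; nc <- spec$imageSize[2L]
  nCells <- spec$nPositive + spec$nNegative
  radii <- pmin(pmax(stats::rnorm(nCells, spec$cellRadiusMean,
                                  spec$cellRadiusSd), 5), 14)
  Dmed <- stats::median(2 * radii)
  outerR <- spec$crownScale * Dmed / 2 + 2
  margin <- ceiling(outerR) + 2
  minSep <- 2 * outerR + 3
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < nCells) {
    if ((tries <- tries + 1L) > 20000L)
      stop("cannot place ", nCells, " non-overlapping cells in a ",
           nr, "x", nc, " image")
    cand <- c(stats::runif(1, margin, nr - 1 - margin),
              stats::runif(1, margin, nc - 1 - margin))
    if (nrow(centers) == 0L ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= minSep))
      centers <- rbind(centers, cand)
  }
  positive <- rep(c(TRUE, FALSE), c(spec$nPositive, spec$nNegative))

  receptor <- matrix(0, nr, nc)
  ligand <- matrix(0, nr, nc)
  for (i in seq_len(nCells)) {
    receptor <- .paintDisk(receptor, centers[i, 1], centers[i, 2], radii[i],
                           spec$receptorIntensity)
    if (positive[i])
      ligand <- .paintAnnulus(ligand, centers[i, 1], centers[i, 2],
                              min(radii[i], Dmed / 2) - 0.5, outerR,
                              spec$ligandIntensity)
  }

  # clutter on the receptor channel, kept clear of the cells (their disks
  # and crowns must stay uncontaminated) and of earlier clutter, with
  # bounded retries.  Clearance uses the object's real footprint (a box),
  # not a bounding disk: a 50 px streak only blocks a thin band.
  placedBoxes <- matrix(numeric(0), 0, 4)  # rmin, rmax, cmin, cmax
  pointBoxDist <- function(p, box) {
    dr <- max(box[1] - p[1], 0, p[1] - box[2])
    dc <- max(box[3] - p[2], 0, p[2] - box[4])
    sqrt(dr^2 + dc^2)
  }
  placeBox <- function(halfRows, halfCols) {
    for (t in seq_len(5000L)) {
      cand <- c(stats::runif(1, halfRows + 2, nr - 3 - halfRows),
                stats::runif(1, halfCols + 2, nc - 3 - halfCols))
      box <- c(cand[1] - halfRows, cand[1] + halfRows,
               cand[2] - halfCols, cand[2] + halfCols)
      clearCells <- nrow(centers) == 0L ||
        all(vapply(seq_len(nrow(centers)), function(i)
          pointBoxDist(centers[i, ], box), numeric(1)) >= outerR + 3)
      clearExtra <- nrow(placedBoxes) == 0L ||
        all(box[1] > placedBoxes[, 2] + 3 | box[2] < placedBoxes[, 1] - 3 |
            box[3] > placedBoxes[, 4] + 3 | box[4] < placedBoxes[, 3] - 3)
      if (clearCells && clearExtra) {
        placedBoxes <<- rbind(placedBoxes, box)
        return(cand)
      }
    }
    stop("cannot place clutter without touching cells; enlarge the image")
  }
  for (i in seq_len(spec$nSpecks)) {
    p <- placeBox(4, 4)
    receptor <- .paintDisk(receptor, p[1], p[2], stats::runif(1, 1, 3),
                           spec$receptorIntensity)
  }
  for (i in seq_len(spec$nStreaks)) {
    len <- round(stats::runif(1, 40, 55))
    horizontal <- stats::runif(1) < 0.5
    p <- if (horizontal) placeBox(3, len / 2 + 2) else placeBox(len / 2 + 2, 3)
    rr <- round(p[1]); cc <- round(p[2])
    if (horizontal) {
      receptor[rr + (0:2) + 1, cc + seq_len(len) - round(len / 2)] <-
        spec$receptorIntensity
    } else {
      receptor[rr + seq_len(len) - round(len / 2), cc + (0:2) + 1] <-
        spec$receptorIntensity
    }
  }

  clip8 <- function(img) {
    img <- img + stats::rnorm(length(img), 0, spec$backgroundNoiseSd)
    round(pmin(pmax(img, 0), 255))
  }
  truth <- data.frame(cell = seq_len(nCells),
                      centroid_row = centers[, 1],
                      centroid_col = centers[, 2],
                      radius_px = radii, positive = positive)
  list(receptor = clip8(receptor), ligand = clip8(ligand),
       truth = list(cells = truth, medianDiameter = Dmed,
                    fractionPositive = if (nCells) mean(positive) else
                      NA_real_),
       spec = spec)
}
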