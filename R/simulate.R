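## Seeded synthetic-study generator. Produces an internally consistent
## desk-scale dataset with planted structure at every stage the pipeline
## tests: one causal pathway whose genes share high-confidence interactions,
## load on a common expression factor (driving |r| above the co-expression
## threshold), and peak in one (region, epoch) cell inside one circuit; and a
## cohort in which CNV carriers of those genes show a shifted behavioral
## item.

#' @importFrom stats rnorm runif rbeta
NULL

#' SimulationDesign: parameters of the synthetic study
#'
#' Defaults are the study conditions the pipeline is exercised under:
#' 47 normal-microarray and 90 CNV subjects, a 1200-gene universe with 30
#' pathways, a 12-gene causal pathway with mean interaction confidence 0.95,
#' a latent-factor loading giving pairwise causal co-expression
#' \eqn{\lambda^2/(\lambda^2+\sigma^2) = 0.8}, a planted expression peak in
#' the striatum during the second trimester, and a one-pooled-SD shift of
#' the anxiety item (pcq_3) in carriers.
#'
#' @slot nGenes Universe size.
#' @slot nPathways Total pathways (one causal + decoys).
#' @slot pathwaySizeRange Min/max decoy pathway size.
#' @slot causalPathwaySize Causal pathway size.
#' @slot ppiWithinConfidence Mean interaction confidence among causal genes.
#' @slot ppiBackgroundConfidence Mean confidence of background edges.
#' @slot nBackgroundEdges Number of random background PPI edges.
#' @slot coexprLatentLoading Shared-factor loading of causal genes.
#' @slot noiseSd Expression noise standard deviation.
#' @slot baselineExpression Mean expression level of the flat baseline.
#' @slot targetBoost Added mean expression in the planted peak cell.
#' @slot regions Brain region vocabulary of the expression grid.
#' @slot samplesPerCell Expression samples per (region, epoch) cell.
#' @slot targetCircuit,targetRegion,targetEpoch The planted peak site; the
#'   region must belong to the circuit.
#' @slot nNormal,nCnv Cohort group sizes.
#' @slot carrierFraction Fraction of CNV subjects whose CNV spans a causal
#'   gene.
#' @slot effectSizeSd Behavioral shift of carriers on the target item, in
#'   latent pooled-SD units.
#' @slot nNeurodev Size of the synthetic neurodevelopmental gene list
#'   (contains the causal pathway).
#' @slot nPcqItems,nVinelandItems Behavioral item counts.
#' @slot targetItem Item receiving the planted shift.
#' @slot rngSeed Integer seed driving all randomness.
#' @export
setClass("SimulationDesign",
  representation(nGenes = "integer", nPathways = "integer",
                 pathwaySizeRange = "integer", causalPathwaySize = "integer",
                 ppiWithinConfidence = "numeric",
                 ppiBackgroundConfidence = "numeric",
                 nBackgroundEdges = "integer",
                 coexprLatentLoading = "numeric", noiseSd = "numeric",
                 baselineExpression = "numeric", targetBoost = "numeric",
                 regions = "character", samplesPerCell = "integer",
                 targetCircuit = "character", targetRegion = "character",
                 targetEpoch = "character",
                 nNormal = "integer", nCnv = "integer",
                 carrierFraction = "numeric", effectSizeSd = "numeric",
                 nNeurodev = "integer", nPcqItems = "integer",
                 nVinelandItems = "integer", targetItem = "character",
                 rngSeed = "integer"))

setValidity("SimulationDesign", function(object) {
  msgs <- character(0)
  pos <- c(nGenes = object@nGenes, nPathways = object@nPathways,
           causalPathwaySize = object@causalPathwaySize,
           nNormal = object@nNormal, nCnv = object@nCnv,
           samplesPerCell = object@samplesPerCell,
           nNeurodev = object@nNeurodev)
  if (any(pos <= 0))
    msgs <- c(msgs, paste("must be positive:",
                          paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@causalPathwaySize > object@nGenes)
    msgs <- c(msgs, "causalPathwaySize must not exceed nGenes")
  if (object@nNeurodev > object@nGenes)
    msgs <- c(msgs, "nNeurodev must not exceed nGenes")
  if (object@nNeurodev < object@causalPathwaySize)
    msgs <- c(msgs, "the neurodevelopmental list must hold the causal pathway")
  if (length(object@pathwaySizeRange) != 2 ||
      object@pathwaySizeRange[1] < 2 ||
      object@pathwaySizeRange[2] > object@nGenes ||
      object@pathwaySizeRange[1] > object@pathwaySizeRange[2])
    msgs <- c(msgs, "pathwaySizeRange must be increasing within [2, nGenes]")
  if (object@carrierFraction < 0 || object@carrierFraction > 1)
    msgs <- c(msgs, "carrierFraction must lie in [0, 1]")
  lam <- object@coexprLatentLoading; sig <- object@noiseSd
  if (lam^2 / (lam^2 + sig^2) <= 0.7)
    msgs <- c(msgs, paste0("implied causal co-expression ",
                           "loading^2/(loading^2+noise^2) must exceed 0.7"))
  if (!object@targetEpoch %in% epochLevels())
    msgs <- c(msgs, "targetEpoch must be one of the four epoch labels")
  if (!object@targetRegion %in% object@regions)
    msgs <- c(msgs, "targetRegion must be in the region vocabulary")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationDesign
#'
#' @param nGenes,nPathways,pathwaySizeRange,causalPathwaySize Universe and
#'   pathway structure.
#' @param ppiWithinConfidence,ppiBackgroundConfidence,nBackgroundEdges PPI
#'   structure.
#' @param coexprLatentLoading,noiseSd Co-expression factor model; the
#'   implied pairwise causal correlation is
#'   \code{loading^2 / (loading^2 + noiseSd^2)}.
#' @param baselineExpression,targetBoost Expression mean structure.
#' @param regions,samplesPerCell Expression sampling grid.
#' @param targetCircuit,targetRegion,targetEpoch Planted peak site.
#' @param nNormal,nCnv,carrierFraction,effectSizeSd Cohort structure.
#' @param nNeurodev,nPcqItems,nVinelandItems,targetItem Gene list and items.
#' @param rngSeed Integer seed.
#' @return A [SimulationDesign-class] object.
#' @export
SimulationDesign <- function(nGenes = 1200L, nPathways = 30L,
                             pathwaySizeRange = c(10L, 40L),
                             causalPathwaySize = 12L,
                             ppiWithinConfidence = 0.95,
                             ppiBackgroundConfidence = 0.4,
                             nBackgroundEdges = 2000L,
                             coexprLatentLoading = 2, noiseSd = 1,
                             baselineExpression = 10, targetBoost = 8,
                             regions = rdocRegions(), samplesPerCell = 3L,
                             targetCircuit = "Positive Valence",
                             targetRegion = "STR",
                             targetEpoch = "trimester2",
                             nNormal = 47L, nCnv = 90L,
                             carrierFraction = 0.5, effectSizeSd = 1,
                             nNeurodev = 120L, nPcqItems = 12L,
                             nVinelandItems = 2L, targetItem = "pcq_3",
                             rngSeed = 1L) {
  new("SimulationDesign", nGenes = as.integer(nGenes),
      nPathways = as.integer(nPathways),
      pathwaySizeRange = as.integer(pathwaySizeRange),
      causalPathwaySize = as.integer(causalPathwaySize),
      ppiWithinConfidence = ppiWithinConfidence,
      ppiBackgroundConfidence = ppiBackgroundConfidence,
      nBackgroundEdges = as.integer(nBackgroundEdges),
      coexprLatentLoading = coexprLatentLoading, noiseSd = noiseSd,
      baselineExpression = baselineExpression, targetBoost = targetBoost,
      regions = regions, samplesPerCell = as.integer(samplesPerCell),
      targetCircuit = targetCircuit, targetRegion = targetRegion,
      targetEpoch = targetEpoch, nNormal = as.integer(nNormal),
      nCnv = as.integer(nCnv), carrierFraction = carrierFraction,
      effectSizeSd = effectSizeSd, nNeurodev = as.integer(nNeurodev),
      nPcqItems = as.integer(nPcqItems),
      nVinelandItems = as.integer(nVinelandItems), targetItem = targetItem,
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "SimulationDesign", function(object) {
  cat("SimulationDesign:", object@nGenes, "genes,", object@nPathways,
      "pathways (causal size", object@causalPathwaySize, "),",
      object@nNormal, "normal +", object@nCnv, "CNV subjects, seed",
      object@rngSeed, "\n")
})

## representative donor ages per epoch (pcw for trimesters)
epochAges <- function() {
  data.frame(epoch = epochLevels(),
             age_value = c(9, 20, 32, 200),
             age_unit = c("pcw", "pcw", "pcw", "postnatal_days"),
             stringsAsFactors = FALSE)
}

## run fn under a seed without disturbing the caller's RNG stream
withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate the synthetic gene universe
#'
#' Lays the genes on synthetic chromosomes with non-overlapping intervals
#' and emits the pathway collection (first set is the causal pathway), the
#' PPI edge list (a high-confidence clique over the causal genes plus random
#' background edges), the expression bundle (causal genes share a latent
#' factor and peak in the design's target cell), the circuit map, the causal
#' gene set, and a neurodevelopmental gene list containing the causal
#' pathway. Deterministic under the design seed.
#'
#' @param design A [SimulationDesign-class] object.
#' @return List: annotation, geneSets, ppiEdges, expression, circuitMap,
#'   causalGenes, neurodevGenes, design.
#' @export
simulateUniverse <- function(design) {
  validObject(design)
  cmap <- defaultCircuitMap()
  if (!design@targetCircuit %in% names(circuitRegions(cmap)))
    stop("infeasible design: unknown target circuit ", design@targetCircuit)
  if (!design@targetRegion %in%
      circuitRegions(cmap)[[design@targetCircuit]])
    stop("infeasible design: target region not in target circuit")
  withSeed(design@rngSeed, function() {
    nG <- design@nGenes
    symbols <- sprintf("G%04d", seq_len(nG))
    perChrom <- 200L
    chrom <- sprintf("chrS%d", (seq_len(nG) - 1L) %/% perChrom + 1L)
    within <- (seq_len(nG) - 1L) %% perChrom
    start <- within * 10000L + 2001L
    annotation <- geneAnnotation(symbols, chrom, start, start + 4999L)

    causal <- sort(sample(symbols, design@causalPathwaySize))
    sets <- list(PWY_CAUSAL = causal)
    for (i in seq_len(design@nPathways - 1L)) {
      sz <- sample(design@pathwaySizeRange[1]:design@pathwaySizeRange[2], 1)
      sets[[sprintf("PWY_%03d", i)]] <- sort(sample(symbols, sz))
    }
    geneSetsObj <- GeneSetCollection(sets, background = symbols)

    neurodev <- sort(unique(c(causal,
      sample(setdiff(symbols, causal),
             design@nNeurodev - length(causal)))))

    ## causal clique at high confidence
    pairs <- t(utils::combn(causal, 2))
    wconf <- pmin(1, pmax(0, stats::rnorm(nrow(pairs),
                                          design@ppiWithinConfidence, 0.02)))
    ## background edges at low mean confidence (Beta, concentration 10)
    m <- design@ppiBackgroundConfidence
    a <- sample(symbols, design@nBackgroundEdges, replace = TRUE)
    b <- sample(symbols, design@nBackgroundEdges, replace = TRUE)
    keep <- a != b
    bconf <- stats::rbeta(sum(keep), m * 10, (1 - m) * 10)
    ppi <- data.frame(
      gene_a = c(pairs[, 1], a[keep]),
      gene_b = c(pairs[, 2], b[keep]),
      confidence = c(wconf, bconf), stringsAsFactors = FALSE)
    ppi <- ppi[!duplicated(cbind(pmin(ppi$gene_a, ppi$gene_b),
                                 pmax(ppi$gene_a, ppi$gene_b))), ]
    rownames(ppi) <- NULL

    ## expression grid: regions x epochs x samplesPerCell
    ages <- epochAges()
    grid <- expand.grid(rep = seq_len(design@samplesPerCell),
                        region = design@regions, epoch = ages$epoch,
                        stringsAsFactors = FALSE)
    meta <- data.frame(
      sample_id = sprintf("S%03d", seq_len(nrow(grid))),
      region_code = grid$region,
      age_value = ages$age_value[match(grid$epoch, ages$epoch)],
      age_unit = ages$age_unit[match(grid$epoch, ages$epoch)],
      stringsAsFactors = FALSE)
    nS <- nrow(meta)
    isTarget <- grid$region == design@targetRegion &
                grid$epoch == design@targetEpoch
    causalIdx <- match(causal, symbols)
    ## per-gene per-cell baselines for non-causal genes; flat for causal
    cellId <- paste(grid$epoch, grid$region, sep = "|")
    cells <- unique(cellId)
    base <- matrix(stats::runif(nG * length(cells),
                                design@baselineExpression - 2,
                                design@baselineExpression + 2),
                   nrow = nG)
    base[causalIdx, ] <- design@baselineExpression
    expr <- base[, match(cellId, cells), drop = FALSE] +
      matrix(stats::rnorm(nG * nS, 0, design@noiseSd), nrow = nG)
    f <- stats::rnorm(nS)  # shared latent factor, one value per sample
    expr[causalIdx, ] <- expr[causalIdx, ] +
      rep(design@coexprLatentLoading * f, each = length(causalIdx))
    expr[causalIdx, isTarget] <- expr[causalIdx, isTarget] +
      design@targetBoost
    expr <- pmax(expr, 0)
    dimnames(expr) <- list(symbols, meta$sample_id)
    bundle <- BrainExpression(expr, meta)

    list(annotation = annotation, geneSets = geneSetsObj, ppiEdges = ppi,
         expression = bundle, circuitMap = cmap, causalGenes = causal,
         neurodevGenes = neurodev, design = design)
  })
}

#' Generate the synthetic subject cohort
#'
#' Emits \code{nNormal} normal-microarray subjects without CNVs and
#' \code{nCnv} CNV subjects with one CNV interval each. A
#' \code{carrierFraction} share of CNV subjects carries a CNV anchored on a
#' causal gene (plus 0--5 contiguous bystander genes); the remainder carry
#' CNVs over non-causal genes only. Behavioral items are latent-normal;
#' PCQ items are discretized to the 1--5 Likert range and Vineland scores
#' are scaled to mean 75, SD 10. Carriers' target item is shifted by
#' \code{effectSizeSd} latent pooled-SD units. Deterministic under the
#' design seed (offset from the universe stream).
#'
#' @param design A [SimulationDesign-class] object.
#' @param annotation Gene annotation \code{GRanges} from
#'   [simulateUniverse()].
#' @param causalGenes Character vector of causal gene symbols (subset of
#'   the annotation).
#' @return A [SubjectCohort-class]; attribute \code{"carriers"} lists the
#'   designed carrier subject ids.
#' @export
simulateCohort <- function(design, annotation, causalGenes) {
  validObject(design)
  if (any(!toupper(causalGenes) %in% toupper(names(annotation))))
    stop("causal genes must be a subset of the annotation symbols")
  withSeed(design@rngSeed + 1013L, function() {
    symbols <- names(annotation)
    chrom <- as.character(GenomicRanges::seqnames(annotation))
    nCarrier <- round(design@carrierFraction * design@nCnv)
    ids <- c(sprintf("N%03d", seq_len(design@nNormal)),
             sprintf("C%03d", seq_len(design@nCnv)))
    status <- rep(c("normal", "cnv"), c(design@nNormal, design@nCnv))
    carrierIds <- ids[status == "cnv"][seq_len(nCarrier)]

    causalIdx <- which(symbols %in% causalGenes)
    annStart <- GenomicRanges::start(annotation)
    annEnd <- GenomicRanges::end(annotation)
    drawCnv <- function(anchorIdx, avoidCausal) {
      for (attempt in 1:50) {
        nb <- sample(0:5, 1)
        left <- sample(0:nb, 1)
        lo <- anchorIdx - left
        hi <- anchorIdx + (nb - left)
        idx <- seq(max(1L, lo), min(length(symbols), hi))
        idx <- idx[chrom[idx] == chrom[anchorIdx]]
        if (!avoidCausal || !any(idx %in% causalIdx) ||
            identical(idx, anchorIdx)) break
      }
      if (avoidCausal && any(idx %in% causalIdx)) idx <- anchorIdx
      span <- range(c(annStart[idx], annEnd[idx]))
      c(chrom = chrom[anchorIdx], start = max(1, span[1] - 500),
        end = span[2] + 500)
    }
    cnvIds <- ids[status == "cnv"]
    rows <- lapply(cnvIds, function(id) {
      if (id %in% carrierIds)
        drawCnv(sample(causalIdx, 1), avoidCausal = FALSE)
      else
        drawCnv(sample(setdiff(seq_along(symbols), causalIdx), 1),
                avoidCausal = TRUE)
    })
    allCnv <- GenomicRanges::GRanges(
      vapply(rows, `[[`, character(1), "chrom"),
      IRanges::IRanges(as.numeric(vapply(rows, `[[`, character(1), "start")),
                       as.numeric(vapply(rows, `[[`, character(1), "end"))))
    ## normals first (empty elements), then one CNV per CNV subject
    part <- IRanges::PartitioningByEnd(
      cumsum(c(rep(0L, design@nNormal), rep(1L, design@nCnv))), names = ids)
    cnvList <- IRanges::relist(allCnv, part)

    items <- c(sprintf("pcq_%d", seq_len(design@nPcqItems)),
               c("vineland_adl", "vineland_motor",
                 sprintf("vineland_%d", seq_len(max(0, design@nVinelandItems - 2L))
                 ))[seq_len(design@nVinelandItems)])
    z <- matrix(stats::rnorm(length(ids) * length(items)),
                nrow = length(ids), dimnames = list(ids, items))
    if (design@targetItem %in% items)
      z[carrierIds, design@targetItem] <-
        z[carrierIds, design@targetItem] + design@effectSizeSd
    scores <- as.data.frame(z)
    for (it in items) {
      if (startsWith(it, "pcq_"))
        scores[[it]] <- findInterval(z[, it], c(-1, 0, 1, 2)) + 1L
      else
        scores[[it]] <- 75 + 10 * z[, it]
    }
    cohort <- SubjectCohort(
      data.frame(subject_id = ids, microarray_status = status,
                 stringsAsFactors = FALSE),
      cnvList, scores)
    attr(cohort, "carriers") <- carrierIds
    cohort
  })
}

#' Generate the full synthetic study
#'
#' [simulateUniverse()] plus [simulateCohort()] under one design.
#'
#' @param design A [SimulationDesign-class] object.
#' @return The universe list with an added \code{cohort} element.
#' @export
simulateStudy <- function(design = SimulationDesign()) {
  uni <- simulateUniverse(design)
  uni$cohort <- simulateCohort(design, uni$annotation, uni$causalGenes)
  uni
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits genes.bed, pathways.gmt, ppi.tsv, expression.tsv + samples.tsv,
#' circuits.tsv, subjects.tsv, neurodev_genes.txt, causal_genes.txt and a
#' manifest.json recording the design and seed.
#'
#' @param study List from [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeIntervals(study$annotation, p("genes.bed"), dialect = "bed")
  writeGmt(study$geneSets, p("pathways.gmt"))
  writePpiEdges(study$ppiEdges, p("ppi.tsv"))
  writeExpressionBundle(study$expression, p("expression.tsv"),
                        p("samples.tsv"))
  writeCircuitMap(study$circuitMap, p("circuits.tsv"))
  writeSubjects(study$cohort, p("subjects.tsv"))
  writeLines(study$neurodevGenes, p("neurodev_genes.txt"))
  writeLines(study$causalGenes, p("causal_genes.txt"))
  d <- study$design
  manifest <- list(
    design = list(nGenes = d@nGenes, nPathways = d@nPathways,
                  causalPathwaySize = d@causalPathwaySize,
                  ppiWithinConfidence = d@ppiWithinConfidence,
                  coexprLatentLoading = d@coexprLatentLoading,
                  noiseSd = d@noiseSd,
                  targetCircuit = d@targetCircuit,
                  targetRegion = d@targetRegion,
                  targetEpoch = d@targetEpoch,
                  nNormal = d@nNormal, nCnv = d@nCnv,
                  carrierFraction = d@carrierFraction,
                  effectSizeSd = d@effectSizeSd,
                  targetItem = d@targetItem),
    seed = d@rngSeed,
    files = c("genes.bed", "pathways.gmt", "ppi.tsv", "expression.tsv",
              "samples.tsv", "circuits.tsv", "subjects.tsv",
              "neurodev_genes.txt", "causal_genes.txt"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(genes = p("genes.bed"), gmt = p("pathways.gmt"),
             ppi = p("ppi.tsv"), expression = p("expression.tsv"),
             samples = p("samples.tsv"), circuits = p("circuits.tsv"),
             subjects = p("subjects.tsv"),
             neurodev = p("neurodev_genes.txt"),
             causal = p("causal_genes.txt"), manifest = p("manifest.json"))
  invisible(files)
}
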