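#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

## ---- vocabularies ----------------------------------------------------------

#' Brain region vocabulary
#'
#' The twelve brain-region codes used throughout the pipeline: anterior
#' cingulate cortex (ACC), amygdala (Amy), striatum (STR), occipital cortex
#' (Ocx), dorsolateral prefrontal cortex (DLPFC), mediodorsal thalamus (MD),
#' primary auditory cortex (A1C), inferior parietal cortex (IPC), primary
#' visual cortex (V1C), inferolateral temporal cortex (ITC), ventrolateral
#' prefrontal cortex (VLPFC), and medial prefrontal cortex (MPFC). The
#' vocabulary is a seed, not a fence: readers accept additional codes.
#'
#' @return Character vector of region codes.
#' @export
rdocRegions <- function() {
  c("ACC", "Amy", "STR", "Ocx", "DLPFC", "MD",
    "A1C", "IPC", "V1C", "ITC", "VLPFC", "MPFC")
}

#' Developmental epoch labels
#'
#' The four developmental epochs, ordered: first, second and third trimester
#' (post-conceptional weeks), then postnatal.
#'
#' @return Character vector of the four epoch labels in developmental order.
#' @export
epochLevels <- function() {
  c("trimester1", "trimester2", "trimester3", "postnatal")
}

#' Age units accepted by expression sample metadata
#' @return Character vector of valid age units.
#' @export
ageUnits <- function() c("pcw", "postnatal_days")

## ---- GeneSetCollection -----------------------------------------------------

#' GeneSetCollection: named gene sets over a background universe
#'
#' Holds named pathways (character vectors of gene symbols) and an optional
#' background universe used as the reference set for over-representation
#' tests. Gene symbols are case-preserved but compared case-insensitively.
#'
#' @slot sets Named list of character vectors (pathway name -> gene symbols).
#' @slot background Character vector of background gene symbols; length 0
#'   means "unset" (the union of the sets is used as background).
#'
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", background = "character"),
  prototype(sets = list(), background = character(0))
)

setValidity("GeneSetCollection", function(object) {
  msgs <- character(0)
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || any(!nzchar(names(s))))
      msgs <- c(msgs, "every gene set must be named")
    if (anyDuplicated(names(s)))
      msgs <- c(msgs, "gene set names must be unique")
    if (!all(vapply(s, is.character, logical(1))))
      msgs <- c(msgs, "gene sets must be character vectors")
    if (any(vapply(s, length, integer(1)) == 0L))
      msgs <- c(msgs, "every gene set must be non-empty")
    if (length(object@background)) {
      bg <- toupper(object@background)
      stray <- vapply(s, function(g) any(!(toupper(g) %in% bg)), logical(1))
      if (any(stray))
        msgs <- c(msgs, paste0("sets not contained in background: ",
                               paste(names(s)[stray], collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets Named list of character vectors of gene symbols. Duplicate
#'   symbols within a set are removed (case-insensitively, first spelling
#'   kept).
#' @param background Optional character vector: the reference gene universe.
#' @return A [GeneSetCollection-class] object.
#' @examples
#' gsc <- GeneSetCollection(list(P1 = c("A", "B"), P2 = c("B", "C")))
#' geneSets(gsc)
#' @export
GeneSetCollection <- function(sets = list(), background = character(0)) {
  sets <- lapply(sets, dedupSymbols)
  new("GeneSetCollection", sets = sets,
      background = dedupSymbols(as.character(background)))
}

#' @describeIn GeneSetCollection-class Named list of gene sets.
#' @param x A GeneSetCollection.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection-class Background universe (possibly empty,
#'   meaning unset).
#' @export
background <- function(x) x@background

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "set(s); background:",
      if (length(object@background)) length(object@background) else "unset",
      "\n")
})

## drop duplicate symbols case-insensitively, keeping the first spelling
dedupSymbols <- function(x) x[!duplicated(toupper(x))]

## ---- BrainExpression -------------------------------------------------------

#' BrainExpression: genes x samples expression with region/age metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one non-negative
#' assay (\code{"expression"}) and per-sample metadata columns
#' \code{region_code}, \code{age_value} (> 0) and \code{age_unit}
#' (\code{"pcw"} or \code{"postnatal_days"}).
#'
#' @export
setClass("BrainExpression", contains = "SummarizedExperiment")

setValidity("BrainExpression", function(object) {
  msgs <- character(0)
  if (!"expression" %in% SummarizedExperiment::assayNames(object))
    return("assay 'expression' is required")
  m <- SummarizedExperiment::assay(object, "expression")
  if (any(!is.finite(m))) msgs <- c(msgs, "expression values must be finite")
  else if (any(m < 0)) msgs <- c(msgs, "expression values must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  need <- c("region_code", "age_value", "age_unit")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing sample metadata column(s):",
                 paste(miss, collapse = ", ")))
  if (any(!cd$age_unit %in% ageUnits()))
    msgs <- c(msgs, paste("age_unit must be one of:",
                          paste(ageUnits(), collapse = ", ")))
  if (any(!is.finite(cd$age_value)) || any(cd$age_value <= 0))
    msgs <- c(msgs, "age_value must be positive")
  if (any(!nzchar(as.character(cd$region_code))))
    msgs <- c(msgs, "region_code must be non-empty")
  if (is.null(rownames(object)) || anyDuplicated(toupper(rownames(object))))
    msgs <- c(msgs, "gene (row) names must be present and unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BrainExpression object
#'
#' @param matrix Numeric genes x samples matrix, non-negative, with unique
#'   rownames (gene symbols) and colnames (sample ids).
#' @param meta data.frame with columns \code{sample_id}, \code{region_code},
#'   \code{age_value}, \code{age_unit}; one row per matrix column, matched by
#'   \code{sample_id}.
#' @return A [BrainExpression-class] object; sample order follows the matrix.
#' @export
BrainExpression <- function(matrix, meta) {
  meta <- as.data.frame(meta)
  if (is.null(colnames(matrix)))
    stop("expression matrix must have sample ids as column names")
  extra <- setdiff(colnames(matrix), meta$sample_id)
  missing <- setdiff(meta$sample_id, colnames(matrix))
  if (length(extra) || length(missing))
    stop("sample id mismatch between matrix and metadata; ",
         "in matrix only: [", paste(extra, collapse = ", "),
         "]; in metadata only: [", paste(missing, collapse = ", "), "]")
  meta <- meta[match(colnames(matrix), meta$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(region_code = as.character(meta$region_code),
                             age_value = as.numeric(meta$age_value),
                             age_unit = as.character(meta$age_unit),
                             row.names = meta$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = matrix), colData = cd)
  new("BrainExpression", se)
}

#' Expression matrix of a BrainExpression object
#' @param x A BrainExpression object.
#' @return Numeric genes x samples matrix.
#' @export
expressionMatrix <- function(x) SummarizedExperiment::assay(x, "expression")

#' Per-sample metadata of a BrainExpression object
#' @param x A BrainExpression object.
#' @return data.frame with sample_id, region_code, age_value, age_unit.
#' @export
sampleMeta <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = rownames(cd),
             region_code = cd$region_code,
             age_value = cd$age_value,
             age_unit = cd$age_unit,
             stringsAsFactors = FALSE, row.names = NULL)
}

## ---- CircuitMap ------------------------------------------------------------

#' CircuitMap: neural circuit -> brain region memberships
#'
#' Maps named neural circuits (e.g. the five RDoC systems) to sets of brain
#' region codes. A region may belong to several circuits.
#'
#' @slot circuits Named list of character vectors of region codes.
#' @export
setClass("CircuitMap", representation(circuits = "list"))

setValidity("CircuitMap", function(object) {
  cc <- object@circuits
  msgs <- character(0)
  if (is.null(names(cc)) || any(!nzchar(names(cc))))
    msgs <- c(msgs, "circuits must be named")
  if (anyDuplicated(names(cc))) msgs <- c(msgs, "circuit names must be unique")
  if (length(cc) && any(vapply(cc, length, integer(1)) == 0L))
    msgs <- c(msgs, "every circuit must have at least one region")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CircuitMap
#' @param circuits Named list of character vectors of region codes.
#' @return A [CircuitMap-class] object.
#' @export
CircuitMap <- function(circuits) {
  new("CircuitMap", circuits = lapply(circuits, function(r) unique(as.character(r))))
}

#' @describeIn CircuitMap-class Named list of circuit region sets.
#' @param x A CircuitMap.
#' @export
circuitRegions <- function(x) x@circuits

setMethod("show", "CircuitMap", function(object) {
  cat("CircuitMap with", length(object@circuits), "circuit(s)\n")
  for (nm in names(object@circuits))
    cat("  ", nm, ": ", paste(object@circuits[[nm]], collapse = ", "), "\n",
        sep = "")
})

#' Default RDoC circuit map
#'
#' Region memberships for the five RDoC systems over the twelve-code region
#' vocabulary. Positive Valence, Cognitive and Social Processes follow the
#' printed clinical-analysis region lists; Negative Valence and Sensorimotor
#' are seeded from standard RDoC constructs restricted to the same
#' vocabulary and may be extended by the user.
#'
#' @return A [CircuitMap-class] object with five circuits.
#' @export
defaultCircuitMap <- function() {
  CircuitMap(list(
    `Negative Valence`  = c("Amy", "ACC", "MPFC"),
    `Positive Valence`  = c("MPFC", "ACC", "Amy", "STR"),
    `Cognitive`         = c("ACC", "Ocx", "DLPFC", "MD", "A1C", "IPC",
                            "STR", "V1C", "VLPFC"),
    `Social Processes`  = c("IPC", "ACC", "Ocx", "ITC", "V1C", "A1C", "STR"),
    `Sensorimotor`      = c("STR", "MD")
  ))
}

## ---- SubjectCohort ---------------------------------------------------------

#' SubjectCohort: subjects, microarray status, CNVs and behavioral scores
#'
#' @slot subjects data.frame with columns \code{subject_id} (unique) and
#'   \code{microarray_status} ("normal" or "cnv").
#' @slot cnv \code{GRangesList}, one element per subject (same order as
#'   \code{subjects}); empty ranges iff the subject's microarray is normal.
#' @slot scores data.frame of behavioral scores, one row per subject
#'   (rownames = subject ids); columns prefixed \code{pcq_} hold ordinal
#'   Likert items, columns prefixed \code{vineland_} hold standard scores.
#' @export
setClass("SubjectCohort",
  representation(subjects = "data.frame", cnv = "GRangesList",
                 scores = "data.frame"))

setValidity("SubjectCohort", function(object) {
  msgs <- character(0)
  sub <- object@subjects
  if (!all(c("subject_id", "microarray_status") %in% colnames(sub)))
    return("subjects needs columns subject_id, microarray_status")
  if (anyDuplicated(sub$subject_id))
    msgs <- c(msgs, "subject ids must be unique")
  if (any(!sub$microarray_status %in% c("normal", "cnv")))
    msgs <- c(msgs, "microarray_status must be 'normal' or 'cnv'")
  if (length(object@cnv) != nrow(sub))
    msgs <- c(msgs, "one CNV range set per subject required")
  else {
    n <- S4Vectors::elementNROWS(object@cnv)
    if (any(n > 0 & sub$microarray_status == "normal"))
      msgs <- c(msgs, "normal-microarray subjects must carry no CNV intervals")
    if (any(n == 0 & sub$microarray_status == "cnv"))
      msgs <- c(msgs, "CNV subjects must carry at least one interval")
  }
  if (nrow(object@scores) != nrow(sub) ||
      !identical(rownames(object@scores), sub$subject_id))
    msgs <- c(msgs, "scores must have one row per subject, in subject order")
  pcq <- grep("^pcq_", colnames(object@scores), value = TRUE)
  for (cl in pcq) {
    v <- object@scores[[cl]]
    if (any(!is.na(v) & (v < 1 | v > 5 | v != round(v))))
      msgs <- c(msgs, paste0(cl, ": PCQ items must be integers in 1..5"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SubjectCohort
#' @param subjects data.frame with subject_id and microarray_status.
#' @param cnv GRangesList of CNV intervals, one element per subject.
#' @param scores data.frame of behavioral scores (rownames = subject ids).
#' @return A [SubjectCohort-class] object.
#' @export
SubjectCohort <- function(subjects, cnv, scores) {
  subjects <- as.data.frame(subjects)
  scores <- as.data.frame(scores)
  new("SubjectCohort", subjects = subjects, cnv = cnv, scores = scores)
}

#' @describeIn SubjectCohort-class Subject table.
#' @param x A SubjectCohort.
#' @export
subjectTable <- function(x) x@subjects

#' @describeIn SubjectCohort-class GRangesList of per-subject CNV intervals.
#' @export
cnvIntervals <- function(x) x@cnv

#' @describeIn SubjectCohort-class Behavioral score table.
#' @export
behaviorScores <- function(x) x@scores

setMethod("show", "SubjectCohort", function(object) {
  st <- table(object@subjects$microarray_status)
  cat("SubjectCohort:", nrow(object@subjects), "subject(s) (",
      paste(names(st), st, sep = "=", collapse = ", "), ");",
      ncol(object@scores), "behavioral item(s)\n")
})

## ---- PipelineConfig --------------------------------------------------------

#' PipelineConfig: thresholds and settings for the full pipeline
#'
#' Defaults match the published analysis settings: hypergeometric
#' significance level 0.001, protein-protein interaction confidence 0.9
#' (inclusive), absolute co-expression Pearson threshold 0.7 (strict), any
#' base-pair overlap counts a gene as CNV-spanned, and trimester boundaries
#' at 13/26/38 post-conceptional weeks.
#'
#' @slot enrichmentAlpha Significance level for pathway over-representation.
#' @slot ppiMinConfidence Minimum interaction confidence, in \[0,1\].
#' @slot coexprThreshold Absolute Pearson correlation threshold (strict >).
#' @slot minOverlapBp Minimum CNV/gene overlap in base pairs (>= 1).
#' @slot epochBoundaries Three increasing PCW cut points (trimester ends).
#' @slot testMethod "welch" or "pooled" two-sample t-test.
#' @slot mtcMethod "none" or "bh" (Benjamini-Hochberg across the scan).
#' @slot rngSeed Integer seed recorded in reports.
#' @export
setClass("PipelineConfig",
  representation(enrichmentAlpha = "numeric", ppiMinConfidence = "numeric",
                 coexprThreshold = "numeric", minOverlapBp = "integer",
                 epochBoundaries = "numeric", testMethod = "character",
                 mtcMethod = "character", rngSeed = "integer"),
  prototype(enrichmentAlpha = 0.001, ppiMinConfidence = 0.9,
            coexprThreshold = 0.7, minOverlapBp = 1L,
            epochBoundaries = c(13, 26, 38), testMethod = "welch",
            mtcMethod = "none", rngSeed = 1L))

setValidity("PipelineConfig", function(object) {
  msgs <- character(0)
  if (object@enrichmentAlpha <= 0 || object@enrichmentAlpha > 1)
    msgs <- c(msgs, "enrichmentAlpha must be in (0, 1]")
  if (object@ppiMinConfidence < 0 || object@ppiMinConfidence > 1)
    msgs <- c(msgs, "ppiMinConfidence must be in [0, 1]")
  if (object@coexprThreshold < 0 || object@coexprThreshold >= 1)
    msgs <- c(msgs, "coexprThreshold must be in [0, 1)")
  if (object@minOverlapBp < 1L)
    msgs <- c(msgs, "minOverlapBp must be >= 1")
  if (length(object@epochBoundaries) != 3 ||
      is.unsorted(object@epochBoundaries, strictly = TRUE) ||
      any(object@epochBoundaries <= 0))
    msgs <- c(msgs, "epochBoundaries must be three increasing positive PCW values")
  if (!object@testMethod %in% c("welch", "pooled"))
    msgs <- c(msgs, "testMethod must be 'welch' or 'pooled'")
  if (!object@mtcMethod %in% c("none", "bh"))
    msgs <- c(msgs, "mtcMethod must be 'none' or 'bh'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PipelineConfig
#'
#' @param enrichmentAlpha Significance level (default 0.001).
#' @param ppiMinConfidence PPI confidence threshold (default 0.9, inclusive).
#' @param coexprThreshold Absolute Pearson threshold (default 0.7, strict).
#' @param minOverlapBp Minimum CNV/gene overlap in bp (default 1).
#' @param epochBoundaries Trimester cut points in PCW (default 13, 26, 38).
#' @param testMethod "welch" (default) or "pooled".
#' @param mtcMethod "none" (default) or "bh".
#' @param rngSeed Integer seed recorded in pipeline reports.
#' @return A [PipelineConfig-class] object.
#' @export
PipelineConfig <- function(enrichmentAlpha = 0.001, ppiMinConfidence = 0.9,
                           coexprThreshold = 0.7, minOverlapBp = 1L,
                           epochBoundaries = c(13, 26, 38),
                           testMethod = "welch", mtcMethod = "none",
                           rngSeed = 1L) {
  new("PipelineConfig", enrichmentAlpha = enrichmentAlpha,
      ppiMinConfidence = ppiMinConfidence, coexprThreshold = coexprThreshold,
      minOverlapBp = as.integer(minOverlapBp),
      epochBoundaries = as.numeric(epochBoundaries),
      testMethod = testMethod, mtcMethod = mtcMethod,
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: alpha=", object@enrichmentAlpha,
      ", ppi>=", object@ppiMinConfidence,
      ", |r|>", object@coexprThreshold,
      ", overlap>=", object@minOverlapBp, "bp",
      ", epochs at ", paste(object@epochBoundaries, collapse = "/"), " pcw",
      ", test=", object@testMethod, ", mtc=", object@mtcMethod,
      ", seed=", object@rngSeed, "\n", sep = "")
})

## ---- FilterReport ----------------------------------------------------------

#' FilterReport: outcome of an evidence filter
#'
#' @slot stage "ppi" or "coexpression".
#' @slot inputGenes Genes submitted to the filter.
#' @slot retainedGenes Genes kept (always a subset of the input).
#' @slot threshold The score threshold applied.
#' @slot supportingEdges data.frame (gene_a, gene_b, score) of qualifying
#'   within-set edges.
#' @export
setClass("FilterReport",
  representation(stage = "character", inputGenes = "character",
                 retainedGenes = "character", threshold = "numeric",
                 supportingEdges = "data.frame"))

setValidity("FilterReport", function(object) {
  msgs <- character(0)
  if (!object@stage %in% c("ppi", "coexpression"))
    msgs <- c(msgs, "stage must be 'ppi' or 'coexpression'")
  if (any(!toupper(object@retainedGenes) %in% toupper(object@inputGenes)))
    msgs <- c(msgs, "retained genes must be a subset of the input genes")
  e <- object@supportingEdges
  if (!all(c("gene_a", "gene_b", "score") %in% colnames(e)))
    msgs <- c(msgs, "supportingEdges needs columns gene_a, gene_b, score")
  else if (length(object@retainedGenes)) {
    touched <- toupper(c(e$gene_a, e$gene_b))
    if (any(!toupper(object@retainedGenes) %in% touched))
      msgs <- c(msgs, "every retained gene must appear in a supporting edge")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FilterReport-class Genes retained by the filter.
#' @param x A FilterReport.
#' @export
retainedGenes <- function(x) x@retainedGenes

#' @describeIn FilterReport-class Genes submitted to the filter.
#' @export
inputGenes <- function(x) x@inputGenes

#' @describeIn FilterReport-class Qualifying edges (gene_a, gene_b, score).
#' @export
supportingEdges <- function(x) x@supportingEdges

#' @describeIn FilterReport-class Filter stage label.
#' @export
filterStage <- function(x) x@stage

#' @describeIn FilterReport-class Threshold applied by the filter.
#' @export
filterThreshold <- function(x) x@threshold

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport [", object@stage, "]: ",
      length(object@retainedGenes), "/", length(object@inputGenes),
      " gene(s) retained at threshold ", object@threshold, " (",
      nrow(object@supportingEdges), " supporting edge(s))\n", sep = "")
})
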