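## End-to-end orchestration: CNV gene extraction -> initial dataset ->
## pathway over-representation -> PPI filter -> co-expression filter ->
## developmental expression mapping -> circuit assignment -> behavioral
## association scan. Every stage persists its output so single stages can be
## re-run in isolation, and the stage-count trail is the audit record.

#' PipelineReport: stage counts and provenance of a pipeline run
#'
#' @slot stageCounts Named integer vector: gene counts at initial,
#'   post_enrichment, post_ppi, post_coexpression, mapped and
#'   circuit_assigned stages. The enrichment-to-co-expression counts are
#'   non-increasing by construction.
#' @slot config The resolved [PipelineConfig-class].
#' @slot outputs Named character vector of files written.
#' @slot results List of in-memory stage results (enrichment table, filter
#'   reports, sites, assignments, associations).
#' @export
setClass("PipelineReport",
  representation(stageCounts = "integer", config = "PipelineConfig",
                 outputs = "character", results = "list"))

#' @describeIn PipelineReport-class Named stage-count trail.
#' @param x A PipelineReport.
#' @export
stageCounts <- function(x) x@stageCounts

#' @describeIn PipelineReport-class Files written by the run.
#' @export
pipelineOutputs <- function(x) x@outputs

#' @describeIn PipelineReport-class In-memory stage results.
#' @export
pipelineResults <- function(x) x@results

setMethod("show", "PipelineReport", function(object) {
  cat("PipelineReport (seed ", object@config@rngSeed, ")\n", sep = "")
  sc <- object@stageCounts
  cat("  gene-count trail:",
      paste(names(sc), sc, sep = "=", collapse = " -> "), "\n")
  cat("  outputs:", length(object@outputs), "file(s)\n")
})

#' Run the analysis stages on in-memory study objects
#'
#' The computational core of [runPipeline()], without file IO: CNV gene
#' union, initial-dataset assembly, over-representation, PPI and
#' co-expression filters, expression-site mapping, circuit assignment and
#' the association scan. Accepts the list returned by [simulateStudy()]
#' (elements \code{cohort}, \code{annotation}, \code{geneSets},
#' \code{ppiEdges}, \code{expression}, \code{circuitMap},
#' \code{neurodevGenes}).
#'
#' @param study Named list of study objects.
#' @param config A [PipelineConfig-class] object.
#' @return List: cnvGenes, initial, enrichment, enriched, ppi,
#'   coexpression, sites, assignments, associations, stageCounts.
#' @export
analyzeStudy <- function(study, config = PipelineConfig()) {
  validObject(config)
  neurodev <- if (is.null(study$neurodevGenes)) character(0)
              else study$neurodevGenes
  cnvGenes <- cohortGeneUnion(study$cohort, study$annotation,
                              config@minOverlapBp)
  initial <- assembleInitialDataset(cnvGenes, neurodev, quiet = TRUE)
  enr <- suppressMessages(
    enrich(initial, study$geneSets, alpha = config@enrichmentAlpha,
           mtc = config@mtcMethod))
  enriched <- significantGeneUnion(enr, config@enrichmentAlpha)
  ppiReport <- filterByPPI(enriched, study$ppiEdges,
                           config@ppiMinConfidence)
  coexReport <- suppressMessages(
    filterByCoexpression(retainedGenes(ppiReport), study$expression,
                         config@coexprThreshold))
  sites <- mapGeneSet(retainedGenes(coexReport), study$expression,
                      config@epochBoundaries)
  assignments <- suppressMessages(assignCircuits(sites, study$circuitMap))
  scan <- runAssociationScan(study$cohort, assignments, study$circuitMap,
                             study$annotation, config = config)
  counts <- c(initial = length(initial),
              post_enrichment = length(enriched),
              post_ppi = length(retainedGenes(ppiReport)),
              post_coexpression = length(retainedGenes(coexReport)),
              mapped = nrow(sites),
              circuit_assigned = sum(vapply(assignments$circuits, length,
                                            integer(1)) > 0))
  list(cnvGenes = cnvGenes, initial = initial, enrichment = enr,
       enriched = enriched, ppi = ppiReport, coexpression = coexReport,
       sites = sites, assignments = assignments, associations = scan,
       stageCounts = counts)
}

#' Run the full pipeline from a file manifest
#'
#' Executes, in order: CNV-to-gene mapping, initial-dataset assembly,
#' hypergeometric pathway over-representation, PPI confidence filtering,
#' co-expression filtering, maximal-expression-site mapping, circuit
#' assignment and the behavioral association scan. Each stage's output is
#' written under \code{outDir}; identical inputs, config and seed give
#' byte-identical outputs. Any stage error aborts with the stage name.
#'
#' @param inputs Named list/vector of paths: \code{subjects}, \code{genes}
#'   (BED), \code{gmt}, \code{ppi}, \code{expression}, \code{samples},
#'   \code{circuits}, \code{neurodev} (one symbol per line; optional). The
#'   manifest written by [writeStudy()] has exactly these names.
#' @param config A [PipelineConfig-class] object.
#' @param outDir Output directory (created if needed).
#' @return A [PipelineReport-class] object.
#' @export
runPipeline <- function(inputs, config = PipelineConfig(),
                        outDir = tempfile("pipeline")) {
  validObject(config)
  need <- c("subjects", "genes", "gmt", "ppi", "expression", "samples",
            "circuits")
  miss <- setdiff(need, names(inputs))
  if (length(miss))
    stop("missing input file(s): ", paste(miss, collapse = ", "))
  for (f in unlist(inputs[need]))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  done <- character(0)
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", name, "' (completed: ",
           paste(done, collapse = ", "), "): ", conditionMessage(e),
           call. = FALSE))
    done <<- c(done, name)
    r
  }

  cohort <- stage("read-subjects", readSubjects(inputs$subjects))
  annotation <- stage("read-genes",
                      readIntervals(inputs$genes, dialect = "bed"))
  gsc <- stage("read-gmt", readGmt(inputs$gmt))
  gsc@background <- names(annotation)
  validObject(gsc)
  edges <- stage("read-ppi", readPpiEdges(inputs$ppi))
  bundle <- stage("read-expression",
                  readExpressionBundle(inputs$expression, inputs$samples))
  cmap <- stage("read-circuits", readCircuitMap(inputs$circuits))
  neurodev <- if (!is.null(inputs$neurodev) && nzchar(inputs$neurodev))
    readLines(inputs$neurodev) else character(0)

  cnvGenes <- stage("map-genes",
                    cohortGeneUnion(cohort, annotation, config@minOverlapBp))
  writeLines(cnvGenes, p("cnv_genes.txt"))
  initial <- stage("assemble",
                   assembleInitialDataset(cnvGenes, neurodev, quiet = TRUE))
  writeLines(initial, p("initial_genes.txt"))

  enr <- stage("enrich", suppressMessages(
    enrich(initial, gsc, alpha = config@enrichmentAlpha,
           mtc = config@mtcMethod)))
  utils::write.table(flattenEnrichment(enr), p("enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enriched <- stage("enrich-union",
                    significantGeneUnion(enr, config@enrichmentAlpha))
  writeLines(enriched, p("enriched_genes.txt"))

  ppiReport <- stage("filter-ppi",
                     filterByPPI(enriched, edges, config@ppiMinConfidence))
  writeFilterReport(ppiReport, p("ppi_retained.txt"), p("ppi_report.json"))
  coexReport <- stage("filter-coexpr", suppressMessages(
    filterByCoexpression(retainedGenes(ppiReport), bundle,
                         config@coexprThreshold)))
  writeFilterReport(coexReport, p("coexpr_retained.txt"),
                    p("coexpr_report.json"))

  sites <- stage("map-expression",
                 mapGeneSet(retainedGenes(coexReport), bundle,
                            config@epochBoundaries))
  utils::write.table(sites, p("sites.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  assignments <- stage("assign-circuits",
                       suppressMessages(assignCircuits(sites, cmap)))
  flatAssign <- assignments
  flatAssign$circuits <- vapply(assignments$circuits, paste, character(1),
                                collapse = ",")
  utils::write.table(flatAssign, p("assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  scan <- stage("associate",
                runAssociationScan(cohort, assignments, cmap, annotation,
                                   config = config))
  tested <- scan[!nzchar(scan$skip_reason), , drop = FALSE]
  utils::write.table(tested, p("associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  counts <- c(initial = length(initial),
              post_enrichment = length(enriched),
              post_ppi = length(retainedGenes(ppiReport)),
              post_coexpression = length(retainedGenes(coexReport)),
              mapped = nrow(sites),
              circuit_assigned = sum(vapply(assignments$circuits, length,
                                            integer(1)) > 0))
  outputs <- c(cnv_genes = p("cnv_genes.txt"),
               initial_genes = p("initial_genes.txt"),
               enrichment = p("enrichment.tsv"),
               enriched_genes = p("enriched_genes.txt"),
               ppi_retained = p("ppi_retained.txt"),
               ppi_report = p("ppi_report.json"),
               coexpr_retained = p("coexpr_retained.txt"),
               coexpr_report = p("coexpr_report.json"),
               sites = p("sites.tsv"),
               assignments = p("assignments.tsv"),
               associations = p("associations.tsv"),
               report = p("report.json"))
  report <- new("PipelineReport", stageCounts = as.integer(counts),
                config = config, outputs = outputs,
                results = list(enrichment = enr, ppi = ppiReport,
                               coexpression = coexReport, sites = sites,
                               assignments = assignments,
                               associations = scan))
  names(report@stageCounts) <- names(counts)
  jsonlite::write_json(list(
    stage_counts = as.list(counts),
    config = list(enrichment_alpha = config@enrichmentAlpha,
                  ppi_min_confidence = config@ppiMinConfidence,
                  coexpr_threshold = config@coexprThreshold,
                  min_overlap_bp = config@minOverlapBp,
                  epoch_boundaries = config@epochBoundaries,
                  test_method = config@testMethod,
                  mtc_method = config@mtcMethod),
    seed = config@rngSeed,
    outputs = as.list(vapply(outputs, basename, character(1)))),
    p("report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}
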