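## Readers and writers for the plain-text formats the pipeline touches.
## Every reader/writer pair is an identity on its own output.

#' @importFrom utils read.table write.table
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
NULL

#' Build a gene annotation GRanges
#'
#' Gene annotations are held as a \code{GRanges} (1-based closed
#' coordinates, the container's native convention) with gene symbols as
#' names. Symbols must be unique (case-insensitively).
#'
#' @param symbol Character vector of gene symbols.
#' @param chrom Chromosome labels.
#' @param start,end 1-based inclusive coordinates, \code{end >= start}.
#' @return Named \code{GRanges}.
#' @examples
#' geneAnnotation(c("G1", "G2"), "chr1", c(101, 501), c(200, 700))
#' @export
geneAnnotation <- function(symbol, chrom, start, end) {
  if (anyDuplicated(toupper(symbol)))
    stop("gene symbols must be unique within an annotation table")
  if (any(end < start)) stop("interval end < start")
  if (any(start < 1)) stop("coordinates must be positive")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  names(gr) <- symbol
  gr
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then one gene symbol per
#' field. Duplicate genes within a line are removed. The background is left
#' unset; supply it separately if the reference universe differs from the
#' union of the sets.
#'
#' @param path Path to a GMT file.
#' @return A [GeneSetCollection-class] (background unset).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("malformed GMT line ", i, ": no gene symbols")
    sets[[fields[[1]]]] <- genes
  }
  GeneSetCollection(sets)
}

#' Write gene sets to a GMT file
#'
#' @param x A [GeneSetCollection-class].
#' @param path Output path.
#' @param descriptions Optional per-set description column (defaults to the
#'   set names).
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(x, path, descriptions = names(geneSets(x))) {
  s <- geneSets(x)
  lines <- vapply(seq_along(s), function(i) {
    paste(c(names(s)[i], descriptions[i], s[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read named genomic intervals
#'
#' Two dialects are supported. \code{"bed"}: 0-based half-open (chrom,
#' start, end, name), converted on read to the container's 1-based closed
#' coordinates by \code{start + 1}. \code{"one_based_inclusive"}: a
#' headerless TSV with the same columns already 1-based inclusive, stored
#' unchanged.
#'
#' @param path Path to a headerless 4-column TSV.
#' @param dialect "bed" or "one_based_inclusive".
#' @return Named \code{GRanges} (names = 4th column).
#' @export
readIntervals <- function(path, dialect = c("bed", "one_based_inclusive")) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character"))
  if (any(df$start < 0) || any(df$end < 0))
    stop("coordinates must be non-negative")
  start1 <- if (dialect == "bed") df$start + 1 else df$start
  if (any(df$end < start1))
    stop("interval end < start after coordinate conversion")
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(start1, df$end))
  names(gr) <- df$name
  gr
}

#' Write named genomic intervals
#'
#' Inverse of [readIntervals()]: \code{"bed"} emits 0-based half-open
#' coordinates (\code{start - 1}); \code{"one_based_inclusive"} emits the
#' stored coordinates.
#'
#' @param gr Named \code{GRanges}.
#' @param path Output path.
#' @param dialect "bed" or "one_based_inclusive".
#' @return \code{path}, invisibly.
#' @export
writeIntervals <- function(gr, path,
                           dialect = c("bed", "one_based_inclusive")) {
  dialect <- match.arg(dialect)
  s <- GenomicRanges::start(gr)
  if (dialect == "bed") s <- s - 1
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = s, end = GenomicRanges::end(gr),
                   name = if (is.null(names(gr))) seq_along(gr) else names(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression bundle (matrix TSV + sample metadata TSV)
#'
#' The matrix file has gene symbols in the first column and one column per
#' sample; the metadata file has columns \code{sample_id},
#' \code{region_code}, \code{age_value}, \code{age_unit}. Sample ids must
#' match exactly (an error lists the symmetric difference); sample order
#' follows the matrix header.
#'
#' @param matrixPath Path to the expression matrix TSV.
#' @param metaPath Path to the sample metadata TSV.
#' @return A [BrainExpression-class] object.
#' @export
readExpressionBundle <- function(matrixPath, metaPath) {
  m <- utils::read.table(matrixPath, sep = "\t", header = TRUE,
                         row.names = 1, check.names = FALSE)
  m <- as.matrix(m)
  meta <- utils::read.table(metaPath, sep = "\t", header = TRUE,
                            colClasses = c(sample_id = "character",
                                           region_code = "character",
                                           age_value = "numeric",
                                           age_unit = "character"))
  BrainExpression(m, meta)
}

#' Write an expression bundle (matrix TSV + sample metadata TSV)
#'
#' @param x A [BrainExpression-class] object.
#' @param matrixPath,metaPath Output paths.
#' @return \code{c(matrixPath, metaPath)}, invisibly.
#' @export
writeExpressionBundle <- function(x, matrixPath, metaPath) {
  m <- expressionMatrix(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, matrixPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sampleMeta(x), metaPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrixPath, metaPath))
}

#' Read a circuit map (TSV or YAML)
#'
#' TSV format: two tab-separated columns, circuit name and comma-separated
#' region codes (no header). Files ending in \code{.yaml}/\code{.yml} are
#' parsed as a mapping circuit -> list of region codes.
#'
#' @param path Path to the circuit map file.
#' @return A [CircuitMap-class] object.
#' @export
readCircuitMap <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    lst <- yaml::read_yaml(path)
    return(CircuitMap(lapply(lst, as.character)))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("circuit", "regions"),
                          colClasses = "character")
  regions <- lapply(strsplit(df$regions, ","), trimws)
  names(regions) <- df$circuit
  CircuitMap(regions)
}

#' Write a circuit map as TSV
#' @param x A [CircuitMap-class] object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCircuitMap <- function(x, path) {
  cc <- circuitRegions(x)
  lines <- vapply(seq_along(cc), function(i)
    paste(names(cc)[i], paste(cc[[i]], collapse = ","), sep = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PPI edge list
#'
#' TSV with header columns \code{gene_a}, \code{gene_b}, \code{confidence}.
#' Confidence must lie in \[0,1\]; STRING-style integer scores in 0--1000
#' are detected (any value > 1) and divided by 1000 on read. Self-edges are
#' rejected.
#'
#' @param path Path to the edge list TSV.
#' @return data.frame with columns gene_a, gene_b, confidence.
#' @export
readPpiEdges <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(gene_a = "character",
                                         gene_b = "character",
                                         confidence = "numeric"))
  if (any(df$confidence > 1)) df$confidence <- df$confidence / 1000
  validatePpiEdges(df)
}

validatePpiEdges <- function(df) {
  if (!all(c("gene_a", "gene_b", "confidence") %in% colnames(df)))
    stop("PPI edges need columns gene_a, gene_b, confidence")
  if (any(toupper(df$gene_a) == toupper(df$gene_b)))
    stop("PPI self-edges are not allowed")
  if (any(df$confidence < 0 | df$confidence > 1))
    stop("PPI confidence must lie in [0, 1]")
  df
}

#' Write a PPI edge list as TSV
#' @param df data.frame with gene_a, gene_b, confidence in \[0,1\].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePpiEdges <- function(df, path) {
  utils::write.table(df[, c("gene_a", "gene_b", "confidence")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject table
#'
#' TSV with header; required columns \code{subject_id},
#' \code{microarray_status} ("normal"/"cnv") and \code{cnv_intervals}
#' (semicolon-separated \code{chrom:start-end} in 1-based inclusive
#' coordinates, empty for normal subjects). All remaining columns are taken
#' as behavioral scores (\code{pcq_*} ordinal, \code{vineland_*}
#' continuous).
#'
#' @param path Path to the subject TSV.
#' @return A [SubjectCohort-class] object.
#' @export
readSubjects <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  need <- c("subject_id", "microarray_status", "cnv_intervals")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("subject table missing column(s): ", paste(miss, collapse = ", "))
  cnv <- GenomicRanges::GRangesList(lapply(df$cnv_intervals, parseIntervalSpec))
  names(cnv) <- df$subject_id
  scoreCols <- setdiff(colnames(df), need)
  scores <- df[, scoreCols, drop = FALSE]
  rownames(scores) <- df$subject_id
  SubjectCohort(df[, c("subject_id", "microarray_status")], cnv, scores)
}

parseIntervalSpec <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) return(GenomicRanges::GRanges())
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([^:]+):([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed CNV interval spec: ", parts[bad][1])
  chrom <- vapply(m, `[`, character(1), 2)
  s <- as.numeric(vapply(m, `[`, character(1), 3))
  e <- as.numeric(vapply(m, `[`, character(1), 4))
  if (any(e < s)) stop("CNV interval end < start")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
}

formatIntervalSpec <- function(gr) {
  if (!length(gr)) return("")
  paste(sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr), GenomicRanges::end(gr)),
        collapse = ";")
}

#' Write a subject table as TSV
#' @param cohort A [SubjectCohort-class] object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSubjects <- function(cohort, path) {
  sub <- subjectTable(cohort)
  cnv <- vapply(as.list(cnvIntervals(cohort)), formatIntervalSpec, character(1))
  df <- cbind(sub, cnv_intervals = cnv, behaviorScores(cohort))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
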