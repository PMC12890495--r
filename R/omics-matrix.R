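#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, features x samples, with row and column names.
#' @param annotation optional data.frame of per-feature annotation, one row per
#'   feature in row order (e.g. `chrom`, `start`, `end` for CpGs, 0-based
#'   half-open; `gene_symbol` for genes).
#' @param type one of `"methylation"`, `"expression"`, `"expression_cpm"`,
#'   `"generic"`.
#' @return an [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), paste0("s", 1:2)))
#' om <- OmicsMatrix(m, type = "methylation")
#' featureIds(om)
#' @export
OmicsMatrix <- function(values,
                        annotation = NULL,
                        type = c("generic", "methylation", "expression",
                                 "expression_cpm")) {
  type <- match.arg(type)
  values <- as.matrix(values)
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("'values' must have feature IDs as rownames")
  if (ncol(values) > 0L && is.null(colnames(values)))
    stop("'values' must have sample IDs as colnames")
  if (is.null(colnames(values)))
    colnames(values) <- character(0)
  if (is.null(annotation))
    annotation <- S4Vectors::DataFrame(row.names = rownames(values))
  else {
    if (nrow(annotation) != nrow(values))
      stop("'annotation' must have one row per feature")
    annotation <- S4Vectors::DataFrame(annotation,
                                       row.names = rownames(values))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values), rowData = annotation)
  new("OmicsMatrix", se, omicsType = type)
}

#' @rdname OmicsMatrix-class
#' @export
setMethod("omicsType", "OmicsMatrix", function(x) x@omicsType)

#' @rdname OmicsMatrix-class
#' @export
setMethod("featureIds", "OmicsMatrix", function(x) rownames(x))

#' @rdname OmicsMatrix-class
#' @export
setMethod("sampleIds", "OmicsMatrix", function(x) colnames(x))

#' Extract the numeric matrix of an OmicsMatrix
#'
#' @param x an [OmicsMatrix-class] (a plain matrix passes through unchanged).
#' @return the features x samples numeric matrix.
#' @export
omicsValues <- function(x) {
  if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x, 1L)
  else as.matrix(x)
}

#' Per-feature annotation of an OmicsMatrix
#'
#' @param x an [OmicsMatrix-class].
#' @return a data.frame of feature annotation (possibly zero columns).
#' @export
featureAnnotation <- function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
}

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix [%s]: %d features x %d samples\n",
              object@omicsType, nrow(object), ncol(object)))
  if (ncol(SummarizedExperiment::rowData(object)))
    cat("annotation:",
        paste(colnames(SummarizedExperiment::rowData(object)),
              collapse = ", "), "\n")
})

#' Counts-per-million normalization
#'
#' Scales every sample (column) so that its counts sum to one million:
#' `cpm[g, s] = 1e6 * count[g, s] / library_size[s]`. This is the standard
#' library-size normalization for RNA-seq count matrices and is delegated to
#' edgeR, the tool of record for this step.
#'
#' @param counts an [OmicsMatrix-class] of type `"expression"` or a
#'   non-negative count matrix (features x samples).
#' @return an [OmicsMatrix-class] of type `"expression_cpm"` whose columns
#'   each sum to 1e6.
#' @examples
#' m <- matrix(c(1, 3, 6), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
#' omicsValues(computeCPM(m))  # 1e5, 3e5, 6e5
#' @export
computeCPM <- function(counts) {
  v <- omicsValues(counts)
  if (any(v < 0)) stop("counts must be non-negative")
  libs <- colSums(v)
  if (any(libs == 0))
    stop("zero-total sample(s): ",
         paste(colnames(v)[libs == 0], collapse = ", "))
  cpm <- edgeR::cpm(v, lib.size = libs)
  dimnames(cpm) <- dimnames(v)
  ann <- if (is(counts, "SummarizedExperiment"))
    as.data.frame(SummarizedExperiment::rowData(counts)) else NULL
  OmicsMatrix(cpm, annotation = ann, type = "expression_cpm")
}

# Analysis-scale transform used by detectDifferential / correlateCpgGene /
# the hypergraph: M-values for betas, log2(cpm + 1) for counts/cpm.
analysisScale <- function(x, scale = c("auto", "M-value", "log2cpm",
                                       "identity")) {
  scale <- match.arg(scale)
  v <- omicsValues(x)
  if (scale == "auto") {
    type <- if (is(x, "OmicsMatrix")) omicsType(x) else "generic"
    scale <- switch(type,
                    methylation = "M-value",
                    expression = "log2cpm",
                    expression_cpm = "log2cpm",
                    "identity")
    if (identical(type, "expression"))
      v <- omicsValues(computeCPM(x))
  }
  switch(scale,
         "M-value" = {
           b <- pmin(pmax(v, 1e-6), 1 - 1e-6)
           log2(b / (1 - b))
         },
         "log2cpm" = log2(v + 1),
         "identity" = v)
}

#' Read a TSV feature-by-sample matrix (plus optional BED annotation)
#'
#' @param valuesPath TSV file, first column feature IDs, remaining columns one
#'   per sample.
#' @param annotationPath optional BED file (0-based half-open) whose name
#'   column matches the feature IDs.
#' @param type passed to [OmicsMatrix()].
#' @return an [OmicsMatrix-class].
#' @export
readOmicsMatrix <- function(valuesPath, annotationPath = NULL,
                            type = "generic") {
  tab <- utils::read.delim(valuesPath, check.names = FALSE,
                           stringsAsFactors = FALSE)
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- as.character(tab[[1]])
  ann <- NULL
  if (!is.null(annotationPath)) {
    bed <- utils::read.delim(annotationPath, header = FALSE,
                             stringsAsFactors = FALSE)
    colnames(bed)[1:4] <- c("chrom", "start", "end", "name")
    ann <- bed[match(rownames(v), bed$name), c("chrom", "start", "end")]
    rownames(ann) <- rownames(v)
  }
  OmicsMatrix(v, annotation = ann, type = type)
}
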