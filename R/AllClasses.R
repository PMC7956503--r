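#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData assay<- assays<-
NULL

#' SpcExperiment: a spectral-count matrix with run/subject metadata
#'
#' An \linkS4class{SummarizedExperiment} holding a proteins-by-columns
#' spectral-count (SpC) matrix in the \code{"spc"} assay. Columns are
#' LC-MS/MS runs (\code{spcLevel == "run"}) or subjects after technical
#' replicates have been averaged (\code{spcLevel == "subject"}). When the
#' matrix has been total-count normalized, the pre-normalization counts are
#' kept in a \code{"raw"} assay so that detection-based operations (the
#' frequency filter, replicate QC) always see the original counts.
#'
#' @slot spcLevel either \code{"run"} or \code{"subject"}.
#' @slot normalized \code{TRUE} after total-SpC normalization.
#' @slot provenance character vector logging the transforms applied, one
#'   entry per operation, oldest first.
#'
#' @seealso [alignRuns()], [normalizeTotalSpc()], [filterByFrequency()],
#'   [averageReplicates()]
#' @export
setClass("SpcExperiment",
  contains = "SummarizedExperiment",
  representation(
    spcLevel   = "character",
    normalized = "logical",
    provenance = "character"
  ),
  prototype(spcLevel = "run", normalized = FALSE, provenance = character())
)

setValidity("SpcExperiment", function(object) {
  msg <- character()
  if (length(object@spcLevel) != 1L || !object@spcLevel %in% c("run", "subject"))
    msg <- c(msg, "spcLevel must be \"run\" or \"subject\"")
  if (!"spc" %in% assayNames(object))
    msg <- c(msg, "an assay named \"spc\" is required")
  else {
    m <- assay(object, "spc")
    if (any(m < 0, na.rm = TRUE))
      msg <- c(msg, "spc values must be non-negative")
    if (anyDuplicated(rownames(m)))
      msg <- c(msg, "protein accessions (rownames) must be unique")
    if (anyDuplicated(colnames(m)))
      msg <- c(msg, "column ids must be unique")
  }
  if (length(object@normalized) != 1L)
    msg <- c(msg, "normalized must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Construct an SpcExperiment
#'
#' @param values non-negative proteins x columns matrix with rownames
#'   (accessions) and colnames (run or subject ids).
#' @param colData a data.frame/DataFrame of column metadata. At run level it
#'   must carry \code{subject_id} and \code{replicate}.
#' @param rowData optional per-protein metadata (e.g. \code{gene_symbol}).
#' @param level \code{"run"} or \code{"subject"}.
#' @param normalized has total-SpC normalization been applied?
#' @param provenance character log of applied transforms.
#' @return an [SpcExperiment-class] object.
#' @export
SpcExperiment <- function(values, colData = NULL, rowData = NULL,
                          level = c("run", "subject"),
                          normalized = FALSE, provenance = character()) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(values))
  se <- SummarizedExperiment(
    assays = list(spc = values),
    colData = colData,
    rowData = if (is.null(rowData)) NULL else rowData
  )
  new("SpcExperiment", se, spcLevel = level, normalized = normalized,
      provenance = provenance)
}

#' @describeIn SpcExperiment the working SpC matrix (normalized if
#'   normalization has been applied).
#' @param x an SpcExperiment.
#' @export
spc <- function(x) assay(x, "spc")

#' @describeIn SpcExperiment the pre-normalization counts (identical to
#'   \code{spc(x)} if no normalization was applied).
#' @export
rawSpc <- function(x) {
  if ("raw" %in% assayNames(x)) assay(x, "raw") else assay(x, "spc")
}

#' @describeIn SpcExperiment the column level, \code{"run"} or
#'   \code{"subject"}.
#' @export
spcLevel <- function(x) x@spcLevel

#' @describeIn SpcExperiment whether total-SpC normalization was applied.
#' @export
isNormalized <- function(x) x@normalized

#' @describeIn SpcExperiment the transform log, one entry per operation.
#' @export
provenance <- function(x) x@provenance

addProvenance <- function(x, entry) {
  x@provenance <- c(x@provenance, entry)
  x
}

setMethod("show", "SpcExperiment", function(object) {
  cat(sprintf("SpcExperiment: %d proteins x %d %ss (%snormalized)\n",
              nrow(object), ncol(object), object@spcLevel,
              if (object@normalized) "" else "not "))
  if (length(object@provenance))
    cat("provenance:\n", paste0("  ", object@provenance, collapse = "\n"), "\n")
})

#' DepSet: differential-expression results over pairwise group comparisons
#'
#' Holds the full per-protein DAve/DCI table for every pairwise comparison
#' of proteome groups, the thresholds used, and the set of differentially
#' expressed proteins (DEPs): proteins passing both thresholds in at least
#' one comparison.
#'
#' @slot results data.frame with columns accession, comparison, aspc_x,
#'   aspc_y, dave, dci, pass (one row per protein per comparison).
#' @slot proteins accessions passing in >= 1 comparison.
#' @slot daveThreshold,dciThreshold the strict thresholds applied to
#'   |DAve| and |DCI|.
#' @export
setClass("DepSet",
  representation(
    results       = "data.frame",
    proteins      = "character",
    daveThreshold = "numeric",
    dciThreshold  = "numeric"
  )
)

setValidity("DepSet", function(object) {
  msg <- character()
  need <- c("accession", "comparison", "aspc_x", "aspc_y", "dave", "dci", "pass")
  if (!all(need %in% names(object@results)))
    msg <- c(msg, paste("results must have columns:", paste(need, collapse = ", ")))
  else {
    passers <- unique(object@results$accession[object@results$pass])
    if (!setequal(object@proteins, passers))
      msg <- c(msg, "proteins must equal the union of passers over comparisons")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DepSet accessions of the differentially expressed proteins.
#' @param x a DepSet.
#' @export
depProteins <- function(x) x@proteins

#' @describeIn DepSet the full per-comparison results table.
#' @export
depResults <- function(x) x@results

setMethod("show", "DepSet", function(object) {
  cat(sprintf(
    "DepSet: %d DEPs over %d comparisons (|DAve| > %g, |DCI| > %g)\n",
    length(object@proteins),
    length(unique(object@results$comparison)),
    object@daveThreshold, object@dciThreshold))
})

#' MarkerPanel: an ordered set of candidate marker proteins
#'
#' @slot proteins ordered accessions (most discriminant first when ranked).
#' @slot source one of \code{"lda_only"}, \code{"dep_only"},
#'   \code{"intersection"}.
#' @slot groupMeans per-group mean aSpC, proteins x groups (may be empty).
#' @slot counts named integer vector with elements \code{lda_only},
#'   \code{dep_only}, \code{intersection}.
#' @export
setClass("MarkerPanel",
  representation(
    proteins   = "character",
    source     = "character",
    groupMeans = "matrix",
    counts     = "integer"
  ),
  prototype(groupMeans = matrix(numeric(), 0, 0), counts = integer())
)

setValidity("MarkerPanel", function(object) {
  msg <- character()
  if (length(object@source) != 1L ||
      !object@source %in% c("lda_only", "dep_only", "intersection"))
    msg <- c(msg, "source must be lda_only, dep_only or intersection")
  if (anyDuplicated(object@proteins))
    msg <- c(msg, "panel proteins must be unique")
  if (nrow(object@groupMeans) > 0 &&
      !identical(rownames(object@groupMeans), object@proteins))
    msg <- c(msg, "groupMeans rows must match panel proteins")
  if (length(msg)) msg else TRUE
})

#' @describeIn MarkerPanel the panel accessions, in panel order.
#' @param x a MarkerPanel.
#' @export
panelProteins <- function(x) x@proteins

setMethod("show", "MarkerPanel", function(object) {
  cat(sprintf("MarkerPanel (%s): %d proteins\n",
              object@source, length(object@proteins)))
  if (length(object@proteins))
    cat("  ", paste(utils::head(object@proteins, 10), collapse = ", "),
        if (length(object@proteins) > 10) "..." else "", "\n")
  if (length(object@counts))
    cat(sprintf("  lda_only %d | intersection %d | dep_only %d\n",
                object@counts[["lda_only"]], object@counts[["intersection"]],
                object@counts[["dep_only"]]))
})

#' SpcLdaModel: linear discriminant model with common covariance
#'
#' Fitted by [fitLda()]: group centroids, shrinkage-regularized pooled
#' within-group covariance, and canonical discriminant axes. Subjects are
#' classified by minimal Mahalanobis distance to the centroids under the
#' common covariance ([classifyLda()]).
#'
#' @slot proteins feature accessions, in model order.
#' @slot groups group labels (canonical order).
#' @slot centroids groups x proteins matrix of group mean profiles.
#' @slot covariance regularized pooled within-group covariance.
#' @slot lambda shrinkage weight toward the diagonal, in [0, 1].
#' @slot scaling proteins x axes canonical discriminant axes.
#' @slot scores per-training-subject canonical scores with group labels.
#' @export
setClass("SpcLdaModel",
  representation(
    proteins   = "character",
    groups     = "character",
    centroids  = "matrix",
    covariance = "matrix",
    lambda     = "numeric",
    scaling    = "matrix",
    scores     = "data.frame"
  )
)

setValidity("SpcLdaModel", function(object) {
  msg <- character()
  p <- length(object@proteins)
  if (!identical(dim(object@covariance), c(p, p)))
    msg <- c(msg, "covariance must be proteins x proteins")
  if (ncol(object@centroids) != p)
    msg <- c(msg, "centroids must have one column per protein")
  if (nrow(object@centroids) != length(object@groups))
    msg <- c(msg, "centroids must have one row per group")
  if (object@lambda < 0 || object@lambda > 1)
    msg <- c(msg, "lambda must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpcLdaModel", function(object) {
  cat(sprintf(
    "SpcLdaModel: %d groups, %d proteins, %d canonical axes (lambda = %g)\n",
    length(object@groups), length(object@proteins),
    ncol(object@scaling), object@lambda))
})
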