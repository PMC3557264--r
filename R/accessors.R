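#' Accessors for TypologyTable, StabilityMatrix and SimulatedWorld
#'
#' \code{featureValues} returns the features x languages character matrix;
#' \code{languageData} and \code{featureData} the metadata DataFrames;
#' \code{languageIds}, \code{featureIds} and \code{methodIds} the respective
#' identifier vectors; \code{rankMatrix} and \code{rawMatrix} the numeric
#' assays of a \linkS4class{StabilityMatrix}; \code{worldTable},
#' \code{worldTruth} and \code{worldTrees} the parts of a
#' \linkS4class{SimulatedWorld}.
#'
#' @param x a typostab data object
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "TypologyTable", function(x)
  SummarizedExperiment::assay(x, "values"))

#' @rdname accessors
#' @export
setGeneric("languageData", function(x) standardGeneric("languageData"))
#' @rdname accessors
#' @export
setMethod("languageData", "TypologyTable", function(x)
  SummarizedExperiment::colData(x))

#' @rdname accessors
#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))
#' @rdname accessors
#' @export
setMethod("featureData", "TypologyTable", function(x)
  SummarizedExperiment::rowData(x))
#' @rdname accessors
#' @export
setMethod("featureData", "StabilityMatrix", function(x)
  SummarizedExperiment::rowData(x))

#' @rdname accessors
#' @export
setGeneric("languageIds", function(x) standardGeneric("languageIds"))
#' @rdname accessors
#' @export
setMethod("languageIds", "TypologyTable", function(x)
  as.character(SummarizedExperiment::colData(x)$language_id))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setMethod("featureIds", "TypologyTable", function(x)
  SummarizedExperiment::rowData(x)$feature_id)
#' @rdname accessors
#' @export
setMethod("featureIds", "StabilityMatrix", function(x)
  SummarizedExperiment::rowData(x)$feature_id)

#' @rdname accessors
#' @export
setGeneric("methodIds", function(x) standardGeneric("methodIds"))
#' @rdname accessors
#' @export
setMethod("methodIds", "StabilityMatrix", function(x)
  as.character(SummarizedExperiment::colData(x)$method_id))

#' @rdname accessors
#' @export
setGeneric("rankMatrix", function(x) standardGeneric("rankMatrix"))
#' @rdname accessors
#' @export
setMethod("rankMatrix", "StabilityMatrix", function(x)
  SummarizedExperiment::assay(x, "rank"))

#' @rdname accessors
#' @export
setGeneric("rawMatrix", function(x) standardGeneric("rawMatrix"))
#' @rdname accessors
#' @export
setMethod("rawMatrix", "StabilityMatrix", function(x)
  SummarizedExperiment::assay(x, "raw"))

#' @rdname accessors
#' @export
setGeneric("worldTable", function(x) standardGeneric("worldTable"))
#' @rdname accessors
#' @export
setMethod("worldTable", "SimulatedWorld", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("worldTruth", function(x) standardGeneric("worldTruth"))
#' @rdname accessors
#' @export
setMethod("worldTruth", "SimulatedWorld", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("worldTrees", function(x) standardGeneric("worldTrees"))
#' @rdname accessors
#' @export
setMethod("worldTrees", "SimulatedWorld", function(x) x@trees)

# internal: values for one feature (by feature_id), named by language_id
.featureRow <- function(table, f) {
  ids <- featureIds(table)
  i <- match(f, ids)
  if (is.na(i)) stop("unknown feature: ", f)
  v <- featureValues(table)[i, ]
  names(v) <- languageIds(table)
  v
}
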