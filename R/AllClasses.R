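#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @import SummarizedExperiment
NULL

#' TypologyTable: languages by categorical structural features
#'
#' A \linkS4class{SummarizedExperiment} holding one character assay
#' \code{"values"} with features as rows and languages as columns.  A cell is a
#' category code (one of the feature's value labels) or \code{NA} for an
#' unattested value; missingness is always explicit, never encoded as a
#' category.  \code{colData} carries per-language metadata
#' (\code{language_id}, \code{name}, \code{family}, \code{genus}, \code{area},
#' optionally \code{macroarea}, \code{lat}, \code{lon}); \code{rowData}
#' carries per-feature metadata (\code{feature_id}, \code{name},
#' \code{area_code}).
#'
#' @section Validity:
#' Language ids and feature ids must be unique, the assay must be a character
#' matrix, and empty strings are disallowed (use \code{NA} for a missing
#' value).
#'
#' @export
setClass("TypologyTable", contains = "SummarizedExperiment")

setValidity("TypologyTable", function(object) {
  msg <- character()
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  else {
    v <- SummarizedExperiment::assay(object, "values")
    if (!is.character(v)) msg <- c(msg, "assay 'values' must be a character matrix")
    else if (any(!is.na(v) & v == "")) msg <- c(msg, "empty strings are not allowed; use NA for missing values")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"language_id" %in% colnames(cd)) msg <- c(msg, "colData must contain 'language_id'")
  else if (anyDuplicated(cd$language_id)) {
    dup <- unique(cd$language_id[duplicated(cd$language_id)])
    msg <- c(msg, paste0("duplicate language_id: ", paste(dup, collapse = ", ")))
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"feature_id" %in% colnames(rd)) msg <- c(msg, "rowData must contain 'feature_id'")
  else if (anyDuplicated(rd$feature_id)) msg <- c(msg, "duplicate feature_id")
  if (nrow(object) == 0) msg <- c(msg, "a TypologyTable needs at least one feature")
  if (length(msg)) msg else TRUE
})

#' Construct a TypologyTable
#'
#' @param values character matrix of category codes, features in rows and
#'   languages in columns (\code{NA} = unattested).
#' @param languages data.frame (or DataFrame) of language metadata, one row
#'   per column of \code{values}; must contain \code{language_id} and, for the
#'   genealogical estimators, non-empty \code{family} and \code{genus}
#'   columns.  An \code{area} column is needed by the areal estimators.
#' @param features data.frame of feature metadata, one row per row of
#'   \code{values}; must contain \code{feature_id}.  Optional columns
#'   \code{name} and \code{area_code} (WALS domain code).
#' @return A \linkS4class{TypologyTable}.
#' @examples
#' v <- matrix(c("a", "b", "a", NA, "x", "x"), nrow = 2, byrow = TRUE)
#' tt <- TypologyTable(v,
#'   languages = data.frame(language_id = c("l1", "l2", "l3"),
#'                          family = "F", genus = "G", area = "A"),
#'   features  = data.frame(feature_id = 1:2))
#' featureValues(tt)
#' @export
TypologyTable <- function(values, languages, features) {
  values <- as.matrix(values)
  storage.mode(values) <- "character"
  languages <- S4Vectors::DataFrame(languages)
  features <- S4Vectors::DataFrame(features)
  for (col in c("family", "genus", "area", "macroarea")) {
    if (!col %in% colnames(languages)) languages[[col]] <- NA_character_
  }
  if (!"name" %in% colnames(features)) features$name <- paste0("F", features$feature_id)
  if (!"area_code" %in% colnames(features)) features$area_code <- NA_character_
  rownames(values) <- as.character(features$feature_id)
  colnames(values) <- as.character(languages$language_id)
  rownames(features) <- as.character(features$feature_id)
  rownames(languages) <- as.character(languages$language_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(values = values),
    rowData = features, colData = languages)
  methods::new("TypologyTable", se)
}

#' StabilityMatrix: per-feature stability scores across methods
#'
#' A \linkS4class{SummarizedExperiment} with features as rows and estimation
#' methods as columns, holding two numeric assays: \code{"raw"} (the method's
#' own score, already sign-oriented so that higher = more stable) and
#' \code{"rank"} (relative ranks in [0, 1], 0 = most unstable feature covered
#' by the method, 1 = most stable).  \code{NA} marks features a method does
#' not cover.  \code{colData} has \code{method_id} and \code{orientation}
#' (the sign that was applied to the method's native score); \code{rowData}
#' mirrors the feature metadata of the source table.
#'
#' @export
setClass("StabilityMatrix", contains = "SummarizedExperiment")

setValidity("StabilityMatrix", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("raw", "rank") %in% an)) msg <- c(msg, "assays 'raw' and 'rank' are required")
  else {
    rk <- SummarizedExperiment::assay(object, "rank")
    if (!is.numeric(rk)) msg <- c(msg, "assay 'rank' must be numeric")
    else if (any(rk < -1e-9 | rk > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "relative ranks must lie in [0, 1]")
  }
  if (!"method_id" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain 'method_id'")
  if (!"feature_id" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain 'feature_id'")
  if (nrow(object) == 0) msg <- c(msg, "a StabilityMatrix needs at least one feature")
  if (length(msg)) msg else TRUE
})

#' Construct a StabilityMatrix
#'
#' @param rank numeric matrix of relative ranks in [0, 1] (features x
#'   methods), \code{NA} where a method does not cover a feature.
#' @param raw numeric matrix of oriented raw scores, same shape; defaults to
#'   all-\code{NA} when only ranks are available (as for the packaged
#'   fixture).
#' @param methods data.frame of method metadata with \code{method_id};
#'   defaults to the column names of \code{rank}.
#' @param features data.frame of feature metadata with \code{feature_id};
#'   defaults to the row names of \code{rank}.
#' @return A \linkS4class{StabilityMatrix}.
#' @export
StabilityMatrix <- function(rank, raw = NULL, methods = NULL, features = NULL) {
  rank <- as.matrix(rank)
  storage.mode(rank) <- "double"
  if (is.null(raw)) raw <- matrix(NA_real_, nrow(rank), ncol(rank), dimnames = dimnames(rank))
  raw <- as.matrix(raw)
  storage.mode(raw) <- "double"
  if (is.null(methods))
    methods <- data.frame(method_id = colnames(rank) %||% paste0("m", seq_len(ncol(rank))))
  methods <- S4Vectors::DataFrame(methods)
  if (!"orientation" %in% colnames(methods)) methods$orientation <- 1
  if (is.null(features))
    features <- data.frame(feature_id = rownames(rank) %||% as.character(seq_len(nrow(rank))))
  features <- S4Vectors::DataFrame(features)
  if (!"name" %in% colnames(features)) features$name <- as.character(features$feature_id)
  if (!"area_code" %in% colnames(features)) features$area_code <- NA_character_
  rownames(rank) <- rownames(raw) <- as.character(features$feature_id)
  colnames(rank) <- colnames(raw) <- as.character(methods$method_id)
  rownames(features) <- as.character(features$feature_id)
  rownames(methods) <- as.character(methods$method_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(raw = raw, rank = rank),
    rowData = features, colData = methods)
  methods::new("StabilityMatrix", se)
}

#' SimulatedWorld: a synthetic typological dataset with known ground truth
#'
#' Holds the generated \linkS4class{TypologyTable}, the per-feature truth
#' (number of states, change rate per unit branch length, borrowing
#' probability), the per-family trees (\code{ape::phylo}) and the generating
#' configuration.
#'
#' @slot table the generated \linkS4class{TypologyTable}.
#' @slot truth data.frame with columns \code{feature_id}, \code{k},
#'   \code{change_rate}, \code{borrow_rate}, \code{root_entropy}.
#' @slot trees named list of \code{phylo} objects, one per family.
#' @slot config the \code{\link{simulationConfig}} list used.
#' @export
setClass("SimulatedWorld",
         representation(table = "TypologyTable", truth = "data.frame",
                        trees = "list", config = "list"))

setValidity("SimulatedWorld", function(object) {
  msg <- character()
  if (!all(c("feature_id", "change_rate", "borrow_rate") %in% colnames(object@truth)))
    msg <- c(msg, "truth needs feature_id, change_rate, borrow_rate columns")
  if (nrow(object@truth) != nrow(object@table))
    msg <- c(msg, "truth must have one row per feature of the table")
  if (length(msg)) msg else TRUE
})

#' @rdname TypologyTable-class
#' @param object a \linkS4class{TypologyTable}
#' @export
setMethod("show", "TypologyTable", function(object) {
  v <- SummarizedExperiment::assay(object, "values")
  cat("TypologyTable:", ncol(object), "languages x", nrow(object), "features\n")
  cat("  families:", length(unique(SummarizedExperiment::colData(object)$family)),
      " genera:", length(unique(SummarizedExperiment::colData(object)$genus)),
      " areas:", length(unique(SummarizedExperiment::colData(object)$area)), "\n")
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(v))))
})

#' @rdname StabilityMatrix-class
#' @param object a \linkS4class{StabilityMatrix}
#' @export
setMethod("show", "StabilityMatrix", function(object) {
  rk <- SummarizedExperiment::assay(object, "rank")
  cat("StabilityMatrix:", nrow(object), "features x", ncol(object), "methods (",
      paste(colnames(rk), collapse = ", "), ")\n")
  cov <- colSums(!is.na(rk))
  cat("  coverage:", paste(paste0(names(cov), "=", cov), collapse = " "), "\n")
})

#' @rdname SimulatedWorld-class
#' @param object a \linkS4class{SimulatedWorld}
#' @export
setMethod("show", "SimulatedWorld", function(object) {
  cat("SimulatedWorld:", length(object@trees), "families,",
      nrow(object@table), "features,", ncol(object@table), "languages\n")
  cat("  change rates:", paste(signif(range(object@truth$change_rate), 3), collapse = " .. "),
      " borrowing:", paste(signif(range(object@truth$borrow_rate), 3), collapse = " .. "), "\n")
})
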