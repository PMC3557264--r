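#' Read a typological table from a delimited text file
#'
#' Expects one row per language and one column per structural feature, plus
#' metadata columns.  Which columns are metadata, the field separator and the
#' missing-value tokens are configurable through \code{dialect}, since
#' WALS-style exports differ in their column naming.
#'
#' @param path path to a tab- or comma-delimited file with a header row.
#' @param dialect a list overriding any of: \code{sep} (\code{""} = guess from
#'   the extension/content), \code{language_col}, \code{name_col},
#'   \code{family_col}, \code{genus_col}, \code{area_col},
#'   \code{macroarea_col}, \code{lat_col}, \code{lon_col}, \code{missing}
#'   (tokens read as missing; empty cells, \code{"NA"}, \code{"?"} and the
#'   en-dash used in print are accepted by default).  All remaining columns
#'   are treated as features; a numeric WALS id is parsed from the column name
#'   when present (e.g. \code{"81A"} or \code{"F81"}), otherwise features are
#'   numbered in column order.
#' @return a validated \linkS4class{TypologyTable}.  Cells whose value is a
#'   missing token become \code{NA}; a count of such cells is reported via a
#'   message.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("language\tfamily\tgenus\tarea\tF1\tF2",
#'              "l1\tIE\tGermanic\tEurope\t1\t2",
#'              "l2\tIE\tGermanic\tEurope\t1\t-"), f)
#' tt <- readTypologyTable(f)
#' featureValues(tt)
#' @export
readTypologyTable <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::modifyList(typologyDialect(), dialect)
  sep <- d$sep
  if (identical(sep, "")) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "",
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop("no language rows in ", path)
  meta_map <- c(language_id = d$language_col, name = d$name_col,
                family = d$family_col, genus = d$genus_col, area = d$area_col,
                macroarea = d$macroarea_col, lat = d$lat_col, lon = d$lon_col)
  present <- meta_map[meta_map %in% colnames(df)]
  if (!"language_id" %in% names(present))
    stop("no language id column (looked for '", d$language_col, "')")
  lang <- as.data.frame(lapply(present, function(cn) df[[cn]]),
                        stringsAsFactors = FALSE)
  names(lang) <- names(present)
  if (anyDuplicated(lang$language_id)) {
    dup <- unique(lang$language_id[duplicated(lang$language_id)])
    stop("duplicate language_id: ", paste(dup, collapse = ", "))
  }
  feat_cols <- setdiff(colnames(df), present)
  if (length(feat_cols) == 0) stop("no feature columns in ", path)
  fid <- suppressWarnings(as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1", feat_cols)))
  if (anyNA(fid) || anyDuplicated(fid)) fid <- seq_along(feat_cols)
  values <- t(as.matrix(df[, feat_cols, drop = FALSE]))
  miss <- is.na(values) | values %in% d$missing
  n_miss <- sum(miss & !is.na(values))
  values[miss] <- NA_character_
  if (n_miss > 0) message(n_miss, " cells read as missing")
  TypologyTable(values,
                languages = lang,
                features = data.frame(feature_id = fid, name = feat_cols,
                                      stringsAsFactors = FALSE))
}

#' Default dialect for typological table files
#'
#' @return a list of reader settings; see \code{\link{readTypologyTable}}.
#' @export
typologyDialect <- function() {
  list(sep = "", language_col = "language", name_col = "name",
       family_col = "family", genus_col = "genus", area_col = "area",
       macroarea_col = "macroarea", lat_col = "lat", lon_col = "lon",
       missing = c("", "NA", "?", "–", "-"))
}

#' Drop languages with too few attested features
#'
#' Sparsely attested languages inflate the unattested-side distance (the
#' neutral 1 of the {0,1,2} rule) and add noise to every pairwise estimator.
#' This filter removes languages whose attested fraction falls below a
#' threshold.  No filter is applied by default anywhere in the package; at
#' full WALS scale raising the threshold is recommended, and the number of
#' dropped languages is reported via a message.
#'
#' @param table a \linkS4class{TypologyTable}.
#' @param min_fraction minimum fraction of attested features a language must
#'   have (default 0 = keep everything).
#' @return the filtered \linkS4class{TypologyTable}.
#' @export
dropSparseLanguages <- function(table, min_fraction = 0) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  frac <- colMeans(!is.na(featureValues(table)))
  keep <- frac >= min_fraction
  if (!any(keep)) stop("min_fraction ", min_fraction, " removes every language")
  if (any(!keep)) message("dropping ", sum(!keep), " language(s) below ",
                          min_fraction, " attested fraction")
  table[, keep]
}

#' Write a TypologyTable to a delimited text file
#'
#' Inverse of \code{\link{readTypologyTable}} under the default dialect:
#' missing values become empty cells.
#'
#' @param table a \linkS4class{TypologyTable}.
#' @param path output path; the extension decides the separator
#'   (\code{.csv} = comma, otherwise tab).
#' @return \code{path}, invisibly.
#' @export
writeTypologyTable <- function(table, path) {
  stopifnot(methods::is(table, "TypologyTable"))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  ld <- as.data.frame(languageData(table))
  fd <- featureData(table)
  v <- t(featureValues(table))
  colnames(v) <- paste0("F", fd$feature_id)
  keep <- c("language_id", "name", "family", "genus", "area", "macroarea", "lat", "lon")
  keep <- keep[keep %in% colnames(ld) & vapply(keep, function(k) !all(is.na(ld[[k]])) || k == "language_id", TRUE)]
  out <- cbind(ld[, keep, drop = FALSE], as.data.frame(v, stringsAsFactors = FALSE))
  names(out)[names(out) == "language_id"] <- "language"
  utils::write.table(out, path, sep = sep, quote = TRUE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged 142-feature stability rank matrix
#'
#' Loads the relative-rank stability matrix shipped with the package: 142 WALS
#' structural features by the eight estimate columns CM, CC, CR, D, P1, P2, W
#' and M, each converted to relative ranks in [0, 1] (0 = most unstable, 1 =
#' most stable; signs already aligned so that higher = more stable) with
#' missing entries where a method does not cover a feature.  Feature metadata
#' carries the WALS numeric id, the feature name and the WALS domain code
#' (P, M, NC, NS, VC, WO, SC, CS, L, SL, O).
#'
#' The values are stored exactly as printed (two decimals), so any statistic
#' recomputed from them carries up to 0.005 rounding noise per entry.
#'
#' @return a \linkS4class{StabilityMatrix} with 142 features and 8 methods;
#'   the \code{raw} assay is all-\code{NA} (only ranks are available).
#' @examples
#' sm <- loadTable1Fixture()
#' length(sharedFeatureSubset(sm))   # 62 features covered by every method
#' @export
loadTable1Fixture <- function() {
  path <- system.file("extdata", "table1_ranks.csv", package = "typostab",
                      mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  meths <- c("CM", "CC", "CR", "D", "P1", "P2", "W", "M")
  rank <- as.matrix(df[, meths])
  StabilityMatrix(rank,
                  methods = data.frame(method_id = meths, orientation = ifelse(meths %in% c("CR", "D"), -1, 1)),
                  features = data.frame(feature_id = df$feature_id,
                                        name = df$name, area_code = df$area,
                                        stringsAsFactors = FALSE))
}

#' Write a StabilityMatrix to CSV
#'
#' One row per feature: metadata columns, then \code{rank_<method>} and
#' \code{raw_<method>} columns in the matrix's method order.  Missing entries
#' are written as empty cells.
#'
#' @param matrix a validated \linkS4class{StabilityMatrix}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeEstimates <- function(matrix, path) {
  stopifnot(methods::is(matrix, "StabilityMatrix"))
  methods::validObject(matrix)
  rk <- rankMatrix(matrix); rw <- rawMatrix(matrix)
  colnames(rk) <- paste0("rank_", colnames(rk))
  colnames(rw) <- paste0("raw_", colnames(rw))
  fd <- featureData(matrix)
  out <- cbind(data.frame(feature_id = fd$feature_id, name = fd$name,
                          area = fd$area_code, stringsAsFactors = FALSE),
               as.data.frame(rk), as.data.frame(rw))
  ok <- tryCatch({utils::write.csv(out, path, row.names = FALSE, na = "",
                                   fileEncoding = "UTF-8"); TRUE},
                 error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a StabilityMatrix written by writeEstimates
#'
#' @param path CSV path produced by \code{\link{writeEstimates}}.
#' @return a \linkS4class{StabilityMatrix}.
#' @export
readEstimates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  rank_cols <- grep("^rank_", colnames(df), value = TRUE)
  if (length(rank_cols) == 0) stop("no rank_* columns in ", path)
  meths <- sub("^rank_", "", rank_cols)
  rank <- as.matrix(df[, rank_cols, drop = FALSE])
  raw_cols <- paste0("raw_", meths)
  raw <- if (all(raw_cols %in% colnames(df))) as.matrix(df[, raw_cols, drop = FALSE]) else NULL
  if (!is.null(raw)) dimnames(raw) <- list(NULL, meths)
  dimnames(rank) <- list(NULL, meths)
  StabilityMatrix(rank, raw = raw,
                  methods = data.frame(method_id = meths),
                  features = data.frame(feature_id = df$feature_id,
                                        name = if ("name" %in% colnames(df)) df$name else as.character(df$feature_id),
                                        area_code = if ("area" %in% colnames(df)) df$area else NA_character_,
                                        stringsAsFactors = FALSE))
}
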