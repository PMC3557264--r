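#' The twelve widely accepted language families
#'
#' Family names used by the accepted-families variant (P2) of the
#' homogeneity-ratio estimator.
#'
#' @return character vector of twelve family names.
#' @export
acceptedFamilies <- function() {
  c("Algonquian", "Austronesian", "Bantu", "Dravidian", "Indo-European",
    "Iroquoian", "Mayan", "Mongolic", "Semitic", "Sino-Tibetan", "Turkic",
    "Uralic")
}

#' Family/area homogeneity ratio (methods P1 and P2)
#'
#' Group homogeneity is the Herfindahl index sum of squared value shares over
#' the attested languages of a group (1 = uniform group, 1/k for k equally
#' frequent values).  The score is the ratio of the mean within-family
#' homogeneity to the mean within-area homogeneity; features scoring high are
#' those that related languages share while areal neighbours do not, i.e.
#' genealogically stable features resistant to borrowing.  Groups with fewer
#' than two attested languages are skipped.
#'
#' @param table a \linkS4class{TypologyTable} whose languages carry
#'   \code{family} and \code{area} columns.
#' @param f feature id.
#' @param family_set \code{"all"} families in the table, or
#'   \code{"accepted12"} to restrict to \code{\link{acceptedFamilies}}.
#' @return list with \code{p_ratio}, \code{h_family}, \code{h_area},
#'   \code{n_families}, \code{n_areas}, \code{family_set}; \code{p_ratio} is
#'   \code{NA} when no family or no area group qualifies.
#' @export
parkvallRatio <- function(table, f, family_set = c("all", "accepted12")) {
  family_set <- match.arg(family_set)
  v <- .featureRow(table, f)
  ld <- languageData(table)
  fam <- as.character(ld$family)
  area <- as.character(ld$area)
  att <- !is.na(v)
  herf <- function(x) {
    s <- table(x) / length(x)
    sum(s^2)
  }
  group_h <- function(groups, keep = unique(groups)) {
    hs <- c()
    for (g in keep) {
      x <- v[att & groups == g]
      if (length(x) >= 2) hs <- c(hs, herf(x))
    }
    hs
  }
  fams <- unique(fam)
  if (family_set == "accepted12") fams <- intersect(fams, acceptedFamilies())
  h_fam <- group_h(fam, fams)
  h_area <- group_h(area)
  if (length(h_fam) < 1 || length(h_area) < 1)
    return(list(p_ratio = NA_real_, h_family = NA_real_, h_area = NA_real_,
                n_families = length(h_fam), n_areas = length(h_area),
                family_set = family_set))
  list(p_ratio = mean(h_fam) / mean(h_area),
       h_family = mean(h_fam), h_area = mean(h_area),
       n_families = length(h_fam), n_areas = length(h_area),
       family_set = family_set)
}
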