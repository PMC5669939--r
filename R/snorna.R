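#' Union of the per-group top-N snoRNAs
#'
#' The per-group top-N lists (ranking and tie rules as in [topN()]) are
#' unioned into one species set, the quantity contrasted between library
#' types in the snoRNA cargo analysis.
#'
#' @param groupPercents percent matrix (snoRNA x group).
#' @param n per-group list length (default 20).
#' @return character vector of snoRNA ids (sorted).
#' @export
topNUnion <- function(groupPercents, n = 20L) {
  sort(unique(topN(groupPercents, n)$feature))
}

#' Box-class composition of a snoRNA set
#'
#' @param ids character vector of snoRNA ids.
#' @param annotation data.frame from [readSnoAnnotation()] (columns `id`,
#'   `box_class`).
#' @return named integer vector with counts for `CD`, `HACA`, `SCARNA`
#'   (zeros included); the counts sum to `length(ids)`.
#' @export
snoClassSummary <- function(ids, annotation) {
  miss <- setdiff(ids, annotation$id)
  if (length(miss))
    stop("unannotated snoRNA id(s): ", paste(miss, collapse = ", "))
  cls <- annotation$box_class[match(ids, annotation$id)]
  tab <- table(factor(cls, levels = SNO_CLASSES))
  setNames(as.integer(tab), SNO_CLASSES)
}

#' Overlap between the snoRNA sets of two library types
#'
#' @param setA,setB character vectors of snoRNA ids (e.g. the
#'   whole-transcriptome vs small-RNA top-20 unions).
#' @return list with `intersection` (size) and `jaccard`
#'   (`|A n B| / |A u B|`; 0 for two empty sets). Symmetric in its arguments.
#' @export
libraryOverlap <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  inter <- length(intersect(setA, setB))
  uni <- length(union(setA, setB))
  list(intersection = inter, jaccard = if (uni == 0L) 0 else inter / uni)
}

#' Dual-library snoRNA cargo profile
#'
#' Full snoRNA summary for a pair of count tables tagged by library type:
#' percent normalization, group means, per-library top-N union, box-class
#' composition, and the between-library overlap.
#'
#' @param countsWTA,countsSMALL integer count matrices (snoRNA x sample) for
#'   the whole-transcriptome and small-RNA libraries.
#' @param sheet sample sheet covering both tables' samples.
#' @param annotation snoRNA annotation data.frame.
#' @param n per-group top-N size (default 20).
#' @return list with per-library `union` and `class_summary`, plus `overlap`.
#' @export
snoProfile <- function(countsWTA, countsSMALL, sheet, annotation, n = 20L) {
  summar <- function(counts) {
    gp <- groupMean(percentOfTotal(counts), sheet)
    u <- topNUnion(gp, n)
    list(union = u, class_summary = snoClassSummary(u, annotation))
  }
  wta <- summar(countsWTA)
  small <- summar(countsSMALL)
  list(WTA = wta, SMALL = small,
       overlap = libraryOverlap(wta$union, small$union))
}
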