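#' Linked miRNA reference (matures placed on their hairpins)
#'
#' Holds mature and hairpin (pre-miRNA) sequences as DNA, with the 0-based
#' half-open coordinates of each mature on its hairpin. The hairpin context is
#' what lets the read assigner distinguish templated end variation (copied
#' from the precursor) from non-templated 3' tailing.
#'
#' @slot matures [Biostrings::DNAStringSet] of mature sequences, named by id.
#' @slot hairpins [Biostrings::DNAStringSet] of hairpin sequences, named by id.
#' @slot map [S4Vectors::DataFrame] with columns `mature_id`, `hairpin_id`,
#'   `start`, `end` (0-based, end-exclusive coordinates on the hairpin).
#'
#' @seealso [linkMatureToHairpin()], [buildIndex()]
#' @exportClass MirnaReference
setClass("MirnaReference",
  representation(matures = "DNAStringSet",
                 hairpins = "DNAStringSet",
                 map = "DataFrame"))

setValidity("MirnaReference", function(object) {
  map <- object@map
  need <- c("mature_id", "hairpin_id", "start", "end")
  if (!all(need %in% colnames(map)))
    return(sprintf("map must have columns %s", paste(need, collapse = ", ")))
  if (length(object@matures) != nrow(map))
    return("one map row per mature required")
  if (anyDuplicated(names(object@matures)))
    return("duplicate mature ids")
  if (anyDuplicated(names(object@hairpins)))
    return("duplicate hairpin ids")
  if (!all(map$mature_id %in% names(object@matures)))
    return("map references unknown mature ids")
  if (!all(map$hairpin_id %in% names(object@hairpins)))
    return("map references unknown hairpin ids")
  if (nrow(map) == 0L) return(TRUE)
  if (any(map$end <= map$start))
    return("mature coordinates must satisfy end > start")
  mat <- as.character(object@matures[map$mature_id])
  hp <- as.character(object@hairpins[map$hairpin_id])
  emb <- substr(hp, map$start + 1L, map$end)
  if (!all(emb == mat))
    return(sprintf("mature %s does not match its hairpin at (start, end)",
                   map$mature_id[which(emb != mat)[1L]]))
  len <- nchar(mat)
  if (any(len < 16L | len > 28L))
    return(sprintf("mature %s length outside [16, 28]",
                   map$mature_id[which(len < 16L | len > 28L)[1L]]))
  TRUE
})

#' @describeIn MirnaReference-class number of matures
#' @param x,object a `MirnaReference`
#' @export
setMethod("length", "MirnaReference", function(x) length(x@matures))

setMethod("show", "MirnaReference", function(object) {
  cat(sprintf("MirnaReference with %d matures on %d hairpins\n",
              length(object@matures), length(object@hairpins)))
  if (length(object@matures) > 0) {
    i <- seq_len(min(3L, length(object@matures)))
    cat(sprintf("  %s (%d nt) on %s [%d, %d)\n",
                object@map$mature_id[i],
                nchar(as.character(object@matures[object@map$mature_id[i]])),
                object@map$hairpin_id[i], object@map$start[i],
                object@map$end[i]), sep = "")
    if (length(object@matures) > 3L) cat("  ...\n")
  }
})

#' @describeIn MirnaReference-class mature sequences (`DNAStringSet`)
#' @export
matureSeqs <- function(x) x@matures

#' @describeIn MirnaReference-class hairpin sequences (`DNAStringSet`)
#' @export
hairpinSeqs <- function(x) x@hairpins

#' @describeIn MirnaReference-class mature-to-hairpin coordinate table
#' @export
matureMap <- function(x) x@map

#' Assignment index over a miRNA reference
#'
#' Opaque, content-sorted view of a [MirnaReference-class] used by
#' [assignRead()] and [assignLibrary()]. Matures are ordered by id so that
#' tie-breaking is a property of the reference content, not of file order.
#'
#' @slot ids character, mature ids in ascending order.
#' @slot hairpin character, the hairpin sequence backing each mature.
#' @slot start,end integer, 0-based half-open mature coordinates on `hairpin`.
#'
#' @seealso [buildIndex()]
#' @exportClass MirnaIndex
setClass("MirnaIndex",
  representation(ids = "character", hairpin = "character",
                 start = "integer", end = "integer"))

setValidity("MirnaIndex", function(object) {
  n <- length(object@ids)
  if (n == 0L) return("empty index")
  if (length(object@hairpin) != n || length(object@start) != n ||
      length(object@end) != n)
    return("slot lengths differ")
  if (is.unsorted(object@ids, strictly = TRUE))
    return("ids must be strictly ascending")
  TRUE
})

setMethod("show", "MirnaIndex", function(object) {
  cat(sprintf("MirnaIndex over %d matures (%d-%d nt)\n", length(object@ids),
              min(object@end - object@start), max(object@end - object@start)))
})
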