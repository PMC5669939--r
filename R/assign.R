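#' Assignment parameters
#'
#' Bounds on the placements [assignRead()] will consider. All bounds are
#' artifact-level choices (the upstream small-RNA pipeline of the emulated
#' study publishes none): up to 3 nt of (always templated) 5' displacement,
#' up to 5 nt of 3' displacement including any non-templated tail of at most
#' 3 nt, at most 2 internal substitutions, and a 16 nt minimum read length.
#'
#' @param max5pShift,max3pShift maximal |5'| / |3'| end offsets (nt).
#' @param maxTail maximal non-templated 3' tail length (nt).
#' @param maxSubs maximal number of internal substitutions.
#' @param minReadLen reads shorter than this are UNASSIGNED (never an error).
#' @return validated list of class `AssignmentParams`.
#' @export
assignmentParams <- function(max5pShift = 3L, max3pShift = 5L, maxTail = 3L,
                             maxSubs = 2L, minReadLen = 16L) {
  p <- list(max5pShift = as.integer(max5pShift),
            max3pShift = as.integer(max3pShift),
            maxTail = as.integer(maxTail), maxSubs = as.integer(maxSubs),
            minReadLen = as.integer(minReadLen))
  if (any(unlist(p) < 0L)) stop("assignment parameters must be >= 0")
  if (p$minReadLen < 16L) stop("minReadLen must be >= 16")
  class(p) <- "AssignmentParams"
  p
}

#' Build an assignment index from a linked reference
#'
#' Content-sorts the matures by id (so tie-breaking never depends on file
#' order) and materializes per-mature hairpin context. Candidate enumeration
#' through the index is behaviorally identical to brute force over all
#' matures and offsets.
#'
#' @param reference a [MirnaReference-class] with coordinates set.
#' @return a [MirnaIndex-class].
#' @export
buildIndex <- function(reference) {
  stopifnot(is(reference, "MirnaReference"))
  map <- matureMap(reference)
  if (nrow(map) == 0L) stop("empty reference: no matures to index")
  ord <- order(map$mature_id, method = "radix")
  map <- map[ord, , drop = FALSE]
  new("MirnaIndex", ids = map$mature_id,
      hairpin = as.character(hairpinSeqs(reference))[map$hairpin_id],
      start = as.integer(map$start), end = as.integer(map$end))
}

checkReadAlphabet <- function(seqs) {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("invalid character in read sequence: ",
         substr(seqs[bad][1L], 1L, 40L))
}

#' Assign a single read to its best-matching mature miRNA
#'
#' Among all placements within the parameter bounds, returns the one
#' minimizing `(n_subs, tail_length, |offset5| + |offset3|)`
#' lexicographically; ties are broken by ascending miRNA id, then ascending
#' 5' offset. Interior alignment is ungapped; mismatches in the templated
#' 3'-extension region are absorbed into the minimal non-templated tail
#' suffix, never counted as substitutions.
#'
#' @param read character, read sequence over A/C/G/T.
#' @param index a [MirnaIndex-class].
#' @param params an [assignmentParams()] object.
#' @return One-row data.frame with columns `mirna_id`, `offset5`, `offset3`,
#'   `subs` (semicolon-joined `pos:ref>alt`, `""` if none), `tail`. For an
#'   unassignable read `mirna_id` is `NA` (the read is UNASSIGNED).
#' @export
assignRead <- function(read, index, params = assignmentParams()) {
  stopifnot(is.character(read), length(read) == 1L)
  checkReadAlphabet(read)
  res <- .assign_reads_cpp(read, index@hairpin, index@start, index@end,
                           params$max5pShift, params$max3pShift,
                           params$maxTail, params$maxSubs, params$minReadLen)
  data.frame(mirna_id = ifelse(is.na(res$idx), NA_character_,
                               index@ids[res$idx]),
             offset5 = res$offset5, offset3 = res$offset3,
             subs = res$subs, tail = res$tail, stringsAsFactors = FALSE)
}

#' Assign a read library
#'
#' Vectorized [assignRead()] over a whole sample. Input may be a named
#' character vector, a [Biostrings::DNAStringSet], or a FASTQ/FASTA path.
#' Every read yields exactly one row; `assigned + unassigned` always equals
#' the number of reads.
#'
#' @param reads reads (see above).
#' @param index a [MirnaIndex-class].
#' @param params an [assignmentParams()] object.
#' @return list with `assignments` (data.frame: read_id, mirna_id, offset5,
#'   offset3, subs, tail) and `counters` (named integer: assigned,
#'   unassigned).
#' @export
assignLibrary <- function(reads, index, params = assignmentParams()) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- readReadFile(reads)
  if (is(reads, "DNAStringSet")) {
    ids <- names(reads)
    seqs <- as.character(reads)
  } else {
    ids <- names(reads)
    seqs <- as.character(reads)
  }
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  if (length(seqs) == 0L)
    return(list(assignments = data.frame(read_id = character(0),
                                         mirna_id = character(0),
                                         offset5 = integer(0),
                                         offset3 = integer(0),
                                         subs = character(0),
                                         tail = character(0)),
                counters = c(assigned = 0L, unassigned = 0L)))
  checkReadAlphabet(seqs)
  res <- .assign_reads_cpp(seqs, index@hairpin, index@start, index@end,
                           params$max5pShift, params$max3pShift,
                           params$maxTail, params$maxSubs, params$minReadLen)
  asg <- data.frame(read_id = ids,
                    mirna_id = ifelse(is.na(res$idx), NA_character_,
                                      index@ids[res$idx]),
                    offset5 = res$offset5, offset3 = res$offset3,
                    subs = res$subs, tail = res$tail,
                    stringsAsFactors = FALSE)
  nA <- sum(!is.na(asg$mirna_id))
  list(assignments = asg,
       counters = c(assigned = nA, unassigned = nrow(asg) - nA))
}

readReadFile <- function(path) {
  firstChar <- substr(readLines(path, n = 1L), 1L, 1L)
  fmt <- if (identical(firstChar, "@")) "fastq" else "fasta"
  x <- Biostrings::readBStringSet(path, format = fmt)
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write an assignment table as TSV
#'
#' Columns: read_id, mirna_id, offset5, offset3, subs (`-` when none), tail
#' (`-` when none); unassigned reads carry `-` in every assignment column.
#'
#' @param assignments data.frame from [assignLibrary()].
#' @param path output TSV path.
#' @export
writeAssignmentsTsv <- function(assignments, path) {
  out <- assignments
  out$mirna_id[is.na(out$mirna_id)] <- "-"
  out$subs[is.na(out$subs) | out$subs == ""] <- "-"
  out$tail[is.na(out$tail) | out$tail == ""] <- "-"
  out$offset5 <- ifelse(is.na(out$offset5), "-", out$offset5)
  out$offset3 <- ifelse(is.na(out$offset3), "-", out$offset3)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}
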