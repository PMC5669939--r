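#' Classify isomiR keys into the six variant classes
#'
#' An isomiR key is the canonical-collapsed identity of an assigned read:
#' `(mirna_id, offset5, offset3, substitutions, tail)`. The six classes
#' partition key space: `CANONICAL` (no deviation), `FIVE_PRIME_ONLY`,
#' `THREE_PRIME_ONLY` (3' offset and/or tail), `BOTH_ENDS`,
#' `SUBSTITUTION_ONLY`, and `SUBSTITUTION_AND_END`. A non-templated tail
#' counts as 3'-end variation, never as a substitution.
#'
#' @param offset5,offset3 integer end offsets (positive 3' = extension).
#' @param subs substitution strings (`"pos:ref>alt;..."`, `""` when none).
#' @param tail non-templated tail strings (`""` when none).
#' @return character vector over
#'   `c("CANONICAL","FIVE_PRIME_ONLY","THREE_PRIME_ONLY","BOTH_ENDS",
#'   "SUBSTITUTION_ONLY","SUBSTITUTION_AND_END")`.
#' @export
classifyVariant <- function(offset5, offset3, subs = "", tail = "") {
  n <- max(length(offset5), length(offset3), length(subs), length(tail))
  offset5 <- rep_len(offset5, n); offset3 <- rep_len(offset3, n)
  subs <- rep_len(as.character(subs), n); tail <- rep_len(as.character(tail), n)
  subs[is.na(subs)] <- ""; tail[is.na(tail)] <- ""
  end5 <- offset5 != 0L
  end3 <- offset3 != 0L | nzchar(tail)
  hasSub <- nzchar(subs)
  out <- rep("CANONICAL", n)
  out[end5 & !end3 & !hasSub] <- "FIVE_PRIME_ONLY"
  out[!end5 & end3 & !hasSub] <- "THREE_PRIME_ONLY"
  out[end5 & end3 & !hasSub] <- "BOTH_ENDS"
  out[hasSub & !end5 & !end3] <- "SUBSTITUTION_ONLY"
  out[hasSub & (end5 | end3)] <- "SUBSTITUTION_AND_END"
  out
}

fmtSigned <- function(x) ifelse(x > 0L, sprintf("+%d", x), sprintf("%d", x))

#' Name an isomiR with the deterministic naming grammar
#'
#' Canonical keys keep the bare miRNA id. Any other key is rendered as
#' `mirna_id|5e{off}|3e{off}|s:{pos}{ref}>{alt};...|t:{tail}` with `s:-` /
#' `t:-` for empty fields and explicit `+` on positive offsets. Distinct
#' keys always receive distinct names and [parseIsomirName()] inverts the
#' grammar exactly.
#'
#' @inheritParams classifyVariant
#' @param mirna_id canonical miRNA id(s).
#' @return character vector of names.
#' @export
nameIsomir <- function(mirna_id, offset5, offset3, subs = "", tail = "") {
  n <- max(length(mirna_id), length(offset5), length(offset3),
           length(subs), length(tail))
  mirna_id <- rep_len(mirna_id, n)
  offset5 <- rep_len(offset5, n); offset3 <- rep_len(offset3, n)
  subs <- rep_len(as.character(subs), n); tail <- rep_len(as.character(tail), n)
  subs[is.na(subs)] <- ""; tail[is.na(tail)] <- ""
  canonical <- offset5 == 0L & offset3 == 0L & !nzchar(subs) & !nzchar(tail)
  sPart <- ifelse(nzchar(subs), gsub("(-?[0-9]+):", "\\1", subs), "-")
  tPart <- ifelse(nzchar(tail), tail, "-")
  ifelse(canonical, mirna_id,
         sprintf("%s|5e%s|3e%s|s:%s|t:%s", mirna_id, fmtSigned(offset5),
                 fmtSigned(offset3), sPart, tPart))
}

#' Parse an isomiR name back into its key
#'
#' Inverse of [nameIsomir()]: `parseIsomirName(nameIsomir(key)) == key` for
#' every key. Malformed names are an error.
#'
#' @param name character vector of isomiR names.
#' @return data.frame with columns `mirna_id`, `offset5`, `offset3`, `subs`
#'   (internal `pos:ref>alt;...` form, `""` when none), `tail`.
#' @export
parseIsomirName <- function(name) {
  parseOne <- function(nm) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) {
      if (!nzchar(nm)) stop("malformed isomiR name: empty")
      return(list(mirna_id = nm, offset5 = 0L, offset3 = 0L,
                  subs = "", tail = ""))
    }
    if (length(parts) != 5L) stop("malformed isomiR name: ", nm)
    o5 <- regmatches(parts[2L], regexec("^5e(0|[+-][0-9]+)$", parts[2L]))[[1L]]
    o3 <- regmatches(parts[3L], regexec("^3e(0|[+-][0-9]+)$", parts[3L]))[[1L]]
    if (length(o5) == 0L || length(o3) == 0L)
      stop("malformed isomiR name: ", nm)
    if (!grepl("^s:", parts[4L]) || !grepl("^t:", parts[5L]))
      stop("malformed isomiR name: ", nm)
    sRaw <- sub("^s:", "", parts[4L])
    tRaw <- sub("^t:", "", parts[5L])
    subs <- ""
    if (sRaw != "-") {
      ent <- strsplit(sRaw, ";", fixed = TRUE)[[1L]]
      m <- regmatches(ent, regexec("^(-?[0-9]+)([ACGT])>([ACGT])$", ent))
      if (any(lengths(m) == 0L)) stop("malformed isomiR name: ", nm)
      subs <- paste(vapply(m, function(x)
        sprintf("%s:%s>%s", x[2L], x[3L], x[4L]), ""), collapse = ";")
    }
    tail <- if (tRaw == "-") "" else tRaw
    if (nzchar(tail) && grepl("[^ACGT]", tail))
      stop("malformed isomiR name: ", nm)
    o5v <- as.integer(o5[2L]); o3v <- as.integer(o3[2L])
    if (o5v == 0L && o3v == 0L && !nzchar(subs) && !nzchar(tail))
      stop("malformed isomiR name (canonical key must use the bare id): ", nm)
    list(mirna_id = parts[1L], offset5 = o5v, offset3 = o3v,
         subs = subs, tail = tail)
  }
  rows <- lapply(name, parseOne)
  data.frame(mirna_id = vapply(rows, `[[`, "", "mirna_id"),
             offset5 = vapply(rows, `[[`, 1L, "offset5"),
             offset3 = vapply(rows, `[[`, 1L, "offset3"),
             subs = vapply(rows, `[[`, "", "subs"),
             tail = vapply(rows, `[[`, "", "tail"),
             stringsAsFactors = FALSE)
}

#' Collapse assignments into an isomiR count table
#'
#' Distinct isomiR keys define distinct isomiRs; each key is named with the
#' grammar of [nameIsomir()] and counted per sample.
#'
#' @param assignments data.frame with columns `sample_id`, `mirna_id`,
#'   `offset5`, `offset3`, `subs`, `tail` (unassigned rows, `mirna_id` NA,
#'   are dropped).
#' @return data.frame: `name`, `mirna_id`, `class`, then one count column
#'   per sample, ordered by mirna_id then name.
#' @export
isomirCountTable <- function(assignments) {
  a <- assignments[!is.na(assignments$mirna_id), , drop = FALSE]
  a$subs[is.na(a$subs)] <- ""; a$tail[is.na(a$tail)] <- ""
  nm <- nameIsomir(a$mirna_id, a$offset5, a$offset3, a$subs, a$tail)
  samples <- sort(unique(a$sample_id))
  tab <- table(nm, factor(a$sample_id, levels = samples))
  key <- a[!duplicated(nm), , drop = FALSE]
  keyNm <- nm[!duplicated(nm)]
  ord <- match(rownames(tab), keyNm)
  out <- data.frame(name = rownames(tab),
                    mirna_id = key$mirna_id[ord],
                    class = classifyVariant(key$offset5[ord], key$offset3[ord],
                                            key$subs[ord], key$tail[ord]),
                    stringsAsFactors = FALSE)
  cnt <- as.data.frame.matrix(tab)
  out <- cbind(out, cnt)
  out <- out[order(out$mirna_id, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-miRNA variant-class histogram
#'
#' Percentage of each variant class per (miRNA, sample). By default the
#' denominator is the miRNA's isomiR (non-canonical) reads only, so the five
#' variant classes sum to 100 for every miRNA with at least one isomiR read
#' and miRNAs with none are absent; `denominator = "all"` instead uses all
#' reads of the miRNA (six classes including `CANONICAL`).
#'
#' @param assignments data.frame as in [isomirCountTable()].
#' @param denominator `"isomir"` (default) or `"all"`.
#' @return data.frame: `mirna_id`, `sample_id`, `class`, `percent`.
#' @export
variantClassHistogram <- function(assignments,
                                  denominator = c("isomir", "all")) {
  denominator <- match.arg(denominator)
  a <- assignments[!is.na(assignments$mirna_id), , drop = FALSE]
  a$class <- classifyVariant(a$offset5, a$offset3, a$subs, a$tail)
  if (denominator == "isomir")
    a <- a[a$class != "CANONICAL", , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(mirna_id = character(0), sample_id = character(0),
                      class = character(0), percent = numeric(0)))
  agg <- as.data.frame(table(mirna_id = a$mirna_id, sample_id = a$sample_id,
                             class = a$class), stringsAsFactors = FALSE)
  names(agg)[4L] <- "count"
  tot <- tapply(agg$count, list(agg$mirna_id, agg$sample_id), sum)
  agg$total <- tot[cbind(agg$mirna_id, agg$sample_id)]
  agg <- agg[agg$total > 0, , drop = FALSE]
  agg$percent <- 100 * agg$count / agg$total
  out <- agg[order(agg$mirna_id, agg$sample_id, agg$class),
             c("mirna_id", "sample_id", "class", "percent")]
  rownames(out) <- NULL
  out
}
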