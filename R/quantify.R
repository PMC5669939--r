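#' Percent-of-total normalization
#'
#' Expresses each count as a percentage of its sample's total, the abundance
#' unit used throughout the pipeline. Columns of the result sum to 100.
#'
#' @param counts numeric matrix (features x samples); every column total must
#'   be positive.
#' @return numeric matrix of percentages with the same dimnames.
#' @export
percentOfTotal <- function(counts) {
  tot <- colSums(counts)
  if (any(tot <= 0))
    stop("zero-total sample: ",
         paste(colnames(counts)[tot <= 0], collapse = ", "))
  if (any(counts < 0)) stop("negative counts")
  sweep(counts, 2L, tot / 100, "/")
}

#' Average percent profiles over replicates within groups
#'
#' Arithmetic mean of the replicate columns of each group; column sums of 100
#' are preserved.
#'
#' @param percents percent matrix (features x samples).
#' @param sheet sample sheet covering every column of `percents`.
#' @return percent matrix (features x groups), groups in first-appearance
#'   order of the sheet.
#' @export
groupMean <- function(percents, sheet) {
  sheet <- validateSampleSheet(sheet)
  miss <- setdiff(colnames(percents), sheet$sample_id)
  if (length(miss)) stop("sample sheet missing sample: ", miss[1L])
  groups <- unique(sheet$group_id)
  out <- vapply(groups, function(g) {
    cols <- sheet$sample_id[sheet$group_id == g]
    cols <- intersect(cols, colnames(percents))
    if (length(cols) == 0L) stop("group with no samples: ", g)
    rowMeans(percents[, cols, drop = FALSE])
  }, numeric(nrow(percents)))
  out <- matrix(out, nrow = nrow(percents),
                dimnames = list(rownames(percents), groups))
  out
}

#' Threshold filter on group-level percent profiles
#'
#' Retains a feature iff its maximal group-level percentage meets the
#' threshold (inclusive `>=`, i.e. "at least"). The default 0.05 (percent)
#' is the expression floor used to exclude poorly expressed RNAs.
#'
#' @param groupPercents percent matrix (features x groups).
#' @param threshold retention threshold in percent units.
#' @return character vector of retained feature ids, input order preserved.
#' @export
thresholdFilter <- function(groupPercents, threshold = 0.05) {
  if (threshold < 0) stop("threshold must be >= 0")
  keep <- apply(groupPercents, 1L, max) >= threshold
  rownames(groupPercents)[keep]
}

#' Top-N features per group with shared/unique flags
#'
#' Ranks features by descending percentage within each group (ties by
#' ascending feature id, so the listing is deterministic and independent of
#' input order). A feature is flagged `shared` when it occurs in the top-N of
#' at least two groups; otherwise it is unique to its group.
#'
#' @param groupPercents percent matrix (features x groups).
#' @param n list length per group (truncated when fewer features exist).
#' @return data.frame: `group`, `rank`, `feature`, `percent`, `shared`.
#' @export
topN <- function(groupPercents, n) {
  if (n < 1L) stop("n must be >= 1")
  n <- min(n, nrow(groupPercents))
  ids <- rownames(groupPercents)
  per <- lapply(colnames(groupPercents), function(g) {
    ord <- order(-groupPercents[, g], ids, method = "radix")[seq_len(n)]
    data.frame(group = g, rank = seq_len(n), feature = ids[ord],
               percent = groupPercents[ord, g], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  occ <- table(out$feature)
  out$shared <- occ[out$feature] >= 2L
  out$shared <- as.logical(out$shared)
  rownames(out) <- NULL
  out
}

#' Cumulative share of the N most abundant features
#'
#' Sum of the top-N percentages per group; monotone non-decreasing in N and
#' equal to 100 when N covers all features.
#'
#' @inheritParams topN
#' @return named numeric vector, one percentage per group.
#' @export
cumulativeTopShare <- function(groupPercents, n) {
  tn <- topN(groupPercents, n)
  vapply(colnames(groupPercents),
         function(g) sum(tn$percent[tn$group == g]), 0)
}

#' Per-sample isomiR fraction
#'
#' Fraction of miRNA-assigned reads that are isomiRs (non-canonical):
#' `isomiR / (canonical + isomiR)`.
#'
#' @param assignments data.frame with `sample_id` and assignment columns (as
#'   in [isomirCountTable()]); unassigned reads are ignored.
#' @return named numeric vector of fractions in `[0, 1]`, one per sample.
#' @export
isomirFraction <- function(assignments) {
  a <- assignments[!is.na(assignments$mirna_id), , drop = FALSE]
  samples <- sort(unique(assignments$sample_id))
  vapply(samples, function(s) {
    x <- a[a$sample_id == s, , drop = FALSE]
    if (nrow(x) == 0L) stop("no miRNA-assigned reads in sample ", s)
    cls <- classifyVariant(x$offset5, x$offset3, x$subs, x$tail)
    mean(cls != "CANONICAL")
  }, 0)
}

#' Summarize retained features by gene type
#'
#' @param features character vector of retained feature ids.
#' @param typeMap named character vector, feature id -> gene type.
#' @return named integer vector of counts per type (sums to
#'   `length(features)`).
#' @export
summarizeByGeneType <- function(features, typeMap) {
  miss <- setdiff(features, names(typeMap))
  if (length(miss))
    stop("feature(s) without a gene type: ", paste(miss, collapse = ", "))
  if (length(features) == 0L) return(integer(0))
  tab <- table(typeMap[features])
  setNames(as.integer(tab), names(tab))
}

#' Canonical miRNA count matrix from assignments
#'
#' Counts every assigned read towards its canonical miRNA (isomiRs included),
#' one column per sample over a fixed feature universe.
#'
#' @param assignments data.frame with `sample_id`, `mirna_id` columns.
#' @param mirna_ids feature universe (rows of the result).
#' @return integer matrix (miRNA x sample).
#' @export
mirnaCountMatrix <- function(assignments, mirna_ids) {
  a <- assignments[!is.na(assignments$mirna_id), , drop = FALSE]
  samples <- sort(unique(assignments$sample_id))
  tab <- table(factor(a$mirna_id, levels = mirna_ids),
               factor(a$sample_id, levels = samples))
  m <- matrix(as.integer(tab), nrow = length(mirna_ids),
              dimnames = list(mirna_ids, samples))
  m
}
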