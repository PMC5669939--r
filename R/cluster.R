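#' Log2 transform of percent expression values
#'
#' `log2(percent + pseudocount)`; the default pseudocount of 0.01 percent
#' sits well below the 0.05 expression floor, so zero counts map to a finite
#' baseline without disturbing retained features.
#'
#' @param percents non-negative matrix of percent values.
#' @param pseudocount positive offset in percent units.
#' @return matrix of log2 values.
#' @export
log2Transform <- function(percents, pseudocount = 0.01) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(percents < 0)) stop("negative expression values")
  log2(percents + pseudocount)
}

#' Hierarchical clustering of expression profiles
#'
#' Clusters samples (columns) with pairwise distance `1 - Pearson
#' correlation` over features and average linkage. Samples are ordered by id
#' before clustering so the result is invariant to input column order, and
#' ties resolve deterministically. Distances lie in `[0, 2]`.
#'
#' @param mat numeric matrix (features x samples), typically
#'   [log2Transform()] output; needs >= 2 samples and >= 2 features.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return an [ape] `phylo` tree over the samples, with the `hclust` object
#'   in `attr(, "hclust")`.
#' @export
hierarchicalCluster <- function(mat, linkage = "average") {
  if (ncol(mat) < 2L) stop("need >= 2 samples to cluster")
  if (nrow(mat) < 2L) stop("need >= 2 features to cluster")
  mat <- mat[, order(colnames(mat), method = "radix"), drop = FALSE]
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant expression profile (undefined correlation) in sample: ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(mat)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  phy <- ape::as.phylo(hc)
  attr(phy, "hclust") <- hc
  phy
}

#' Serialize a sample tree as Newick
#'
#' @param tree `phylo` object from [hierarchicalCluster()].
#' @param path output path.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Replicate coherence of a sample dendrogram
#'
#' A group is coherent when its replicates form a clade: a subtree containing
#' all of them and no other leaf. Groups with a single replicate are
#' trivially coherent.
#'
#' @param tree `phylo` object (or Newick string/path readable by
#'   [ape::read.tree()]) whose tips are sample ids.
#' @param sheet sample sheet covering exactly the tree's tips.
#' @return named logical vector, one entry per group.
#' @export
replicateCoherence <- function(tree, sheet) {
  if (is.character(tree))
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  sheet <- validateSampleSheet(sheet)
  if (!setequal(tree$tip.label, sheet$sample_id))
    stop("tree tips and sample sheet disagree")
  groups <- unique(sheet$group_id)
  vapply(setNames(groups, groups), function(g) {
    tips <- sheet$sample_id[sheet$group_id == g]
    if (length(tips) <= 1L) return(TRUE)
    ape::is.monophyletic(tree, tips)
  }, TRUE)
}
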