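#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic small-RNA EV
#' cargo generator. Defaults describe the emulated study design: 4 cell lines
#' x 2 biological replicates, 100 miRNAs of which a core of 14 is abundant in
#' every line and 3 per line are line-specific, long-tailed lognormal
#' abundances, 50,000 reads per sample, and an isomiR variation process with
#' predominant 3'-end variation, occasional internal substitutions and
#' non-templated A/U 3' tails. Under the defaults the expected isomiR
#' fraction, [expectedIsomirFraction()], is about 0.29, and roughly a third
#' of isomiRs carry a substitution.
#'
#' @param seed integer master seed; all simulator randomness flows from it.
#' @param n_groups,n_replicates study design (groups = cell lines).
#' @param n_mirnas,n_shared_core,n_group_specific reference size; shared-core
#'   miRNAs are abundant in all groups, group-specific miRNAs only in theirs.
#' @param lognormal_mu,lognormal_sigma abundance law on the log scale.
#' @param reads_per_sample small-RNA reads per sample.
#' @param p_5p_shift probability of a (templated) 5' offset of +-1 nt.
#' @param dist_3p_offset named numeric, probability over 3' offsets (names are
#'   signed integers); must sum to 1.
#' @param sub_rate per-nucleotide substitution probability over the canonical
#'   body positions covered by the read.
#' @param tail_rate probability that a 3'-extended read carries a
#'   non-templated tail replacing the outermost templated bases.
#' @param tail_max maximal tail length (nt), bases drawn from A/T (A/U
#'   tailing).
#' @param n_snornas,sno_length_range snoRNA population (full-length 60-300 nt
#'   by default).
#' @param sno_fragment_length_range length range of snoRNA fragments seen in
#'   the size-selected small-RNA library.
#' @param sno_read_fraction fraction of small-RNA reads drawn from snoRNA
#'   fragments.
#' @param sno_reads_per_sample depth of the direct snoRNA count tables
#'   (whole-transcriptome and small-RNA library types).
#' @param wta_class_weights,small_class_weights relative box-class abundance
#'   multipliers for the two library types (whole-transcriptome libraries
#'   H/ACA-rich, small-RNA libraries C/D-rich).
#' @return validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      n_groups = 4L, n_replicates = 2L,
                      n_mirnas = 100L, n_shared_core = 14L,
                      n_group_specific = 3L,
                      lognormal_mu = 0, lognormal_sigma = 1.0,
                      reads_per_sample = 50000L,
                      p_5p_shift = 0.06,
                      dist_3p_offset = c("-2" = 0.035, "-1" = 0.08,
                                         "0" = 0.845, "1" = 0.028,
                                         "2" = 0.012),
                      sub_rate = 0.005, tail_rate = 0.10, tail_max = 2L,
                      n_snornas = 60L, sno_length_range = c(60L, 300L),
                      sno_fragment_length_range = c(18L, 40L),
                      sno_read_fraction = 0.05,
                      sno_reads_per_sample = 20000L,
                      wta_class_weights = c(CD = 1, HACA = 2.5, SCARNA = 1),
                      small_class_weights = c(CD = 3, HACA = 0.5,
                                              SCARNA = 1)) {
  cfg <- list(seed = as.integer(seed), n_groups = as.integer(n_groups),
              n_replicates = as.integer(n_replicates),
              n_mirnas = as.integer(n_mirnas),
              n_shared_core = as.integer(n_shared_core),
              n_group_specific = as.integer(n_group_specific),
              lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
              reads_per_sample = as.integer(reads_per_sample),
              p_5p_shift = p_5p_shift, dist_3p_offset = dist_3p_offset,
              sub_rate = sub_rate, tail_rate = tail_rate,
              tail_max = as.integer(tail_max),
              n_snornas = as.integer(n_snornas),
              sno_length_range = as.integer(sno_length_range),
              sno_fragment_length_range = as.integer(sno_fragment_length_range),
              sno_read_fraction = sno_read_fraction,
              sno_reads_per_sample = as.integer(sno_reads_per_sample),
              wta_class_weights = wta_class_weights,
              small_class_weights = small_class_weights)
  probs <- c(cfg$p_5p_shift, cfg$sub_rate, cfg$tail_rate,
             cfg$sno_read_fraction, cfg$dist_3p_offset)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$dist_3p_offset) - 1) > 1e-9)
    stop("dist_3p_offset must sum to 1")
  if (is.null(names(cfg$dist_3p_offset)) ||
      anyNA(suppressWarnings(as.integer(names(cfg$dist_3p_offset)))))
    stop("dist_3p_offset must be named by signed integer offsets")
  if (cfg$n_shared_core + cfg$n_groups * cfg$n_group_specific > cfg$n_mirnas)
    stop("n_shared_core + n_groups * n_group_specific must be <= n_mirnas")
  if (cfg$n_groups < 1L || cfg$n_replicates < 1L || cfg$n_mirnas < 1L)
    stop("n_groups, n_replicates and n_mirnas must be >= 1")
  if (cfg$tail_max < 1L) stop("tail_max must be >= 1")
  if (diff(cfg$sno_length_range) < 0 || cfg$sno_length_range[1] <= 0)
    stop("invalid sno_length_range")
  if (cfg$sno_fragment_length_range[1] < 16L)
    stop("sno fragments shorter than 16 nt are not generated")
  for (w in list(cfg$wta_class_weights, cfg$small_class_weights))
    if (!all(SNO_CLASSES %in% names(w)) || any(w < 0))
      stop("class weights must be non-negative and named CD, HACA, SCARNA")
  class(cfg) <- "SimConfig"
  cfg
}

#' Expected isomiR fraction under a simulation configuration
#'
#' Closed-form probability that a simulated miRNA read is non-canonical:
#' a read is canonical iff it has no 5' offset, a 3' offset of zero (hence no
#' tail) and no substitution at any of its L canonical body positions, with
#' mature length L uniform over 20-23 nt.
#'
#' @param config a [simConfig()] object.
#' @return expected fraction of miRNA reads that are isomiRs, in `[0, 1]`.
#' @export
expectedIsomirFraction <- function(config) {
  d0 <- config$dist_3p_offset[names(config$dist_3p_offset) == "0"]
  d0 <- if (length(d0)) unname(d0) else 0
  pCanon <- (1 - config$p_5p_shift) * d0 *
    mean((1 - config$sub_rate)^(20:23))
  1 - pCanon
}

randSeq <- function(n) {
  vapply(n, function(k) paste(sample(c("A", "C", "G", "T"), k,
                                     replace = TRUE), collapse = ""), "")
}

#' Simulate a miRNA + snoRNA reference
#'
#' Generates `n_mirnas` hairpins each embedding exactly one mature (uniform
#' 20-23 nt, flanks of 5-30 nt per side) and `n_snornas` full-length snoRNAs
#' with box classes drawn CD/HACA/SCARNA at 0.5/0.4/0.1. Seeds the global
#' generator from `config$seed`; downstream simulator calls consume the same
#' stream.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `reference` ([MirnaReference-class]),
#'   `sno_annotation` (data.frame id/box_class/length/host_gene) and
#'   `sno_seqs` ([Biostrings::DNAStringSet]).
#' @export
simulateReference <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_mirnas
  mlen <- sample(20:23, n, replace = TRUE)
  left <- sample(5:30, n, replace = TRUE)
  right <- sample(5:30, n, replace = TRUE)
  mseq <- randSeq(mlen)
  hseq <- paste0(randSeq(left), mseq, randSeq(right))
  mid <- sprintf("sim-mir-%04d", seq_len(n))
  hid <- sprintf("sim-hairpin-%04d", seq_len(n))
  matures <- Biostrings::DNAStringSet(setNames(mseq, mid))
  hairpins <- Biostrings::DNAStringSet(setNames(hseq, hid))
  map <- S4Vectors::DataFrame(mature_id = mid, hairpin_id = hid,
                              start = left, end = left + mlen)
  ref <- new("MirnaReference", matures = matures, hairpins = hairpins,
             map = map)

  ns <- config$n_snornas
  cls <- sample(SNO_CLASSES, ns, replace = TRUE, prob = c(0.5, 0.4, 0.1))
  slen <- sample(seq(config$sno_length_range[1], config$sno_length_range[2]),
                 ns, replace = TRUE)
  sid <- sprintf("sim-sno-%04d", seq_len(ns))
  sno <- data.frame(id = sid, box_class = cls, length = slen,
                    host_gene = NA_character_, stringsAsFactors = FALSE)
  list(reference = ref, sno_annotation = sno,
       sno_seqs = Biostrings::DNAStringSet(setNames(randSeq(slen), sid)))
}

#' Simulate group-structured miRNA abundance profiles
#'
#' Per group, expected read proportions over miRNAs: the shared core and the
#' group's own specific miRNAs are drawn from the boosted upper abundance
#' tail (log-scale offset of +3 sigma over a background truncated at +2.5
#' sigma, so boosted features always outrank the background); a group's
#' specific miRNAs have proportion exactly 0 in other groups; columns are
#' normalized to sum to 1. Consumes the generator stream seeded by
#' [simulateReference()].
#'
#' @param config a [simConfig()] object.
#' @param mirna_ids character vector of miRNA ids (rows of the result).
#' @return matrix (miRNA x group) of proportions with attributes `role`
#'   (`core`/`specific`/`background`) and `specific_group`.
#' @export
simulateAbundances <- function(config, mirna_ids) {
  stopifnot(inherits(config, "SimConfig"),
            length(mirna_ids) == config$n_mirnas)
  n <- config$n_mirnas; G <- config$n_groups
  groups <- sprintf("line%s", LETTERS[seq_len(G)])
  role <- rep("background", n)
  role[seq_len(config$n_shared_core)] <- "core"
  specific_group <- rep(NA_character_, n)
  if (config$n_group_specific > 0) {
    idx <- config$n_shared_core +
      seq_len(G * config$n_group_specific)
    role[idx] <- "specific"
    specific_group[idx] <- rep(groups, each = config$n_group_specific)
  }
  # shared + line-specific log-abundance components: EV cargoes share a
  # similar background across lines while keeping line-specific structure
  z <- 0.8 * rnorm(n) + 0.6 * matrix(rnorm(n * G), n, G)
  mu <- config$lognormal_mu; sg <- config$lognormal_sigma
  val <- exp(mu + sg * pmin(z, 2.5))          # truncated background tail
  boost <- exp(mu + sg * (3 + abs(z)))        # upper-tail boosted features
  ab <- matrix(0, n, G, dimnames = list(mirna_ids, groups))
  for (g in seq_len(G)) {
    v <- val[, g]
    v[role == "core"] <- boost[role == "core", g]
    v[role == "specific"] <- 0
    own <- role == "specific" & specific_group == groups[g]
    v[own] <- boost[own, g]
    ab[, g] <- v / sum(v)
  }
  attr(ab, "role") <- setNames(role, mirna_ids)
  attr(ab, "specific_group") <- setNames(specific_group, mirna_ids)
  ab
}

#' Simulate snoRNA abundance profiles for both library types
#'
#' Lognormal abundances with per-library-type box-class multipliers: the
#' whole-transcriptome (WTA) pool is H/ACA-enriched, the small-RNA fragment
#' pool C/D-enriched. Each snoRNA has a shared log-abundance component plus
#' a smaller group-specific one, so per-group top lists overlap heavily
#' across cell lines (as EV snoRNA cargoes do) while keeping line-specific
#' entries. Consumes the seeded generator stream.
#'
#' @param config a [simConfig()] object.
#' @param sno_annotation data.frame as returned by [simulateReference()].
#' @return list with `WTA` and `SMALL` proportion matrices (snoRNA x group).
#' @export
simulateSnoAbundances <- function(config, sno_annotation) {
  G <- config$n_groups
  groups <- sprintf("line%s", LETTERS[seq_len(G)])
  ns <- nrow(sno_annotation)
  out <- list()
  for (lib in c("WTA", "SMALL")) {
    w <- if (lib == "WTA") config$wta_class_weights else
      config$small_class_weights
    zShared <- rnorm(ns)
    raw <- w[sno_annotation$box_class] *
      exp(0.7 * zShared + 0.4 * matrix(rnorm(ns * G), ns, G))
    out[[lib]] <- sweep(raw, 2, colSums(raw), "/")
    dimnames(out[[lib]]) <- list(sno_annotation$id, groups)
  }
  out
}

# inline truth classifier: deliberately independent of classifyVariant()
truthClass <- function(offset5, offset3, nsubs, tail) {
  end5 <- offset5 != 0L
  end3 <- offset3 != 0L | nzchar(tail)
  sub <- nsubs > 0L
  ifelse(sub & (end5 | end3), "SUBSTITUTION_AND_END",
  ifelse(sub, "SUBSTITUTION_ONLY",
  ifelse(end5 & end3, "BOTH_ENDS",
  ifelse(end3, "THREE_PRIME_ONLY",
  ifelse(end5, "FIVE_PRIME_ONLY", "CANONICAL")))))
}

#' Simulate small-RNA reads with per-read ground truth
#'
#' Per sample draws read sources from the group's miRNA abundance profile
#' (plus a configurable fraction of snoRNA fragments), applies the isomiR
#' process -- templated 5' offsets of +-1 with probability `p_5p_shift`,
#' 3' offsets from `dist_3p_offset` (templated from the hairpin when
#' extending, with probability `tail_rate` the outermost extension bases
#' replaced by a non-templated A/T tail), and per-base substitutions over the
#' covered canonical body -- and records every event in a truth table.
#' Substitutions never fall on templated extensions or tails, so a read's
#' variant identity is unambiguous. Reads shorter than 16 nt cannot arise
#' (mature >= 20 nt, trims bounded at 1 + 2). Consumes the seeded stream.
#'
#' @param config a [simConfig()] object.
#' @param simref output of [simulateReference()].
#' @param abundances output of [simulateAbundances()].
#' @param sno_abundances optional output of [simulateSnoAbundances()]; its
#'   `SMALL` component drives fragment sources. When `NULL` no snoRNA reads
#'   are generated.
#' @return list with `samples` (named list of [Biostrings::DNAStringSet]),
#'   `truth` (data.frame: sample_id, read_id, source_id, offset5, offset3,
#'   substitutions, tail, true_class) and `sheet` (sample sheet data.frame).
#' @export
simulateReads <- function(config, simref, abundances, sno_abundances = NULL) {
  ref <- simref$reference
  map <- matureMap(ref)
  hp <- as.character(hairpinSeqs(ref))[map$hairpin_id]
  mat <- as.character(matureSeqs(ref))[map$mature_id]
  mstart <- map$start; mend <- map$end; mlen <- mend - mstart
  offs <- as.integer(names(config$dist_3p_offset))
  G <- config$n_groups
  groups <- colnames(abundances)
  useSno <- !is.null(sno_abundances) && config$sno_read_fraction > 0 &&
    config$n_snornas > 0
  snoSeq <- if (useSno) as.character(simref$sno_seqs) else character(0)

  samples <- list(); truths <- list()
  sheet <- data.frame(sample_id = character(0), group_id = character(0),
                      replicate = integer(0))
  for (g in seq_len(G)) for (r in seq_len(config$n_replicates)) {
    sampleId <- sprintf("%s_r%d", groups[g], r)
    nTot <- config$reads_per_sample
    nSno <- if (useSno) rbinom(1L, nTot, config$sno_read_fraction) else 0L
    nMir <- nTot - nSno

    src <- sample.int(config$n_mirnas, nMir, replace = TRUE,
                      prob = abundances[, g])
    o5 <- integer(nMir)
    shift <- runif(nMir) < config$p_5p_shift
    o5[shift] <- sample(c(-1L, 1L), sum(shift), replace = TRUE)
    o3 <- sample(offs, nMir, replace = TRUE, prob = config$dist_3p_offset)
    tlen <- integer(nMir)
    canTail <- o3 >= 1L & runif(nMir) < config$tail_rate
    tlen[canTail] <- pmin(sample.int(config$tail_max, sum(canTail),
                                     replace = TRUE), o3[canTail])
    pstart <- mstart[src] + o5
    readEnd <- mend[src] + o3          # exclusive, on hairpin
    seqs <- substr(hp[src], pstart + 1L, readEnd - tlen)
    tails <- rep("", nMir)
    wtail <- which(tlen > 0L)
    for (i in wtail)
      tails[i] <- paste(sample(c("A", "T"), tlen[i], replace = TRUE),
                        collapse = "")

    # substitutions over covered canonical body positions
    pLo <- pmax(0L, o5)                         # first canonical body pos
    pHi <- mlen[src] - 1L + pmin(o3, 0L)        # last canonical body pos
    nPos <- pHi - pLo + 1L
    k <- rbinom(nMir, nPos, config$sub_rate)
    subs <- rep("", nMir)
    for (i in which(k > 0L)) {
      pos <- sort(sample(seq(pLo[i], pHi[i]), k[i]))
      s <- seqs[i]
      ent <- character(k[i])
      for (j in seq_len(k[i])) {
        ri <- pos[j] - o5[i] + 1L               # 1-based position in read
        refb <- substr(s, ri, ri)
        alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
        substr(s, ri, ri) <- alt
        ent[j] <- sprintf("%d:%s>%s", pos[j], refb, alt)
      }
      seqs[i] <- s
      subs[i] <- paste(ent, collapse = ";")
    }
    seqs <- paste0(seqs, tails)

    mirTruth <- data.frame(
      source_id = map$mature_id[src], offset5 = o5, offset3 = o3,
      substitutions = subs, tail = tails,
      true_class = truthClass(o5, o3, k, tails),
      stringsAsFactors = FALSE)

    if (nSno > 0L) {
      ssrc <- sample.int(config$n_snornas, nSno, replace = TRUE,
                         prob = sno_abundances$SMALL[, g])
      flr <- config$sno_fragment_length_range
      fl <- pmin(sample(seq(flr[1], flr[2]), nSno, replace = TRUE),
                 nchar(snoSeq)[ssrc])
      fs <- vapply(seq_len(nSno), function(i)
        sample.int(nchar(snoSeq[ssrc[i]]) - fl[i] + 1L, 1L), 1L)
      sseqs <- substr(snoSeq[ssrc], fs, fs + fl - 1L)
      snoTruth <- data.frame(
        source_id = names(simref$sno_seqs)[ssrc],
        offset5 = NA_integer_, offset3 = NA_integer_,
        substitutions = "", tail = "", true_class = "SNO_FRAGMENT",
        stringsAsFactors = FALSE)
      seqs <- c(seqs, sseqs)
      mirTruth <- rbind(mirTruth, snoTruth)
    }

    perm <- sample.int(nTot)
    seqs <- seqs[perm]
    mirTruth <- mirTruth[perm, , drop = FALSE]
    ids <- sprintf("%s_read%06d", sampleId, seq_len(nTot))
    dss <- Biostrings::DNAStringSet(setNames(seqs, ids))
    samples[[sampleId]] <- dss
    truths[[sampleId]] <- cbind(sample_id = sampleId, read_id = ids,
                                mirTruth, stringsAsFactors = FALSE)
    sheet <- rbind(sheet, data.frame(sample_id = sampleId,
                                     group_id = groups[g], replicate = r))
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  list(samples = samples, truth = truth, sheet = sheet)
}

#' Simulate direct snoRNA count tables for both library types
#'
#' Multinomial counts at `sno_reads_per_sample` depth per sample, from the
#' per-library-type abundance profiles.
#'
#' @param config a [simConfig()] object.
#' @param sno_abundances output of [simulateSnoAbundances()].
#' @param sheet sample sheet data.frame.
#' @return list with `WTA` and `SMALL` integer count matrices
#'   (snoRNA x sample).
#' @export
simulateSnoCounts <- function(config, sno_abundances, sheet) {
  out <- list()
  for (lib in c("WTA", "SMALL")) {
    ab <- sno_abundances[[lib]]
    m <- vapply(seq_len(nrow(sheet)), function(i)
      rmultinom(1L, config$sno_reads_per_sample,
                ab[, sheet$group_id[i]])[, 1L],
      integer(nrow(ab)))
    dimnames(m) <- list(rownames(ab), sheet$sample_id)
    out[[lib]] <- m
  }
  out
}

#' Run the full synthetic-data generator
#'
#' Seeds the global generator once from `config$seed` (via
#' [simulateReference()]) and produces references, abundance profiles,
#' per-sample reads with ground truth, and snoRNA count tables for the two
#' library types, all from one stream.
#'
#' @param config a [simConfig()] object.
#' @return list: `reference`, `sno_annotation`, `sno_seqs`, `abundances`,
#'   `sno_abundances`, `reads` (see [simulateReads()]), `sno_counts`.
#' @export
simulateDataset <- function(config) {
  simref <- simulateReference(config)
  ab <- simulateAbundances(config, names(matureSeqs(simref$reference)))
  snoAb <- simulateSnoAbundances(config, simref$sno_annotation)
  reads <- simulateReads(config, simref, ab, snoAb)
  snoCounts <- simulateSnoCounts(config, snoAb, reads$sheet)
  c(simref, list(abundances = ab, sno_abundances = snoAb, reads = reads,
                 sno_counts = snoCounts))
}

#' Write simulated reads as FASTQ
#'
#' Four-line records, Phred+33, constant quality `I` (quality is not used by
#' the pipeline).
#'
#' @param reads named [Biostrings::DNAStringSet].
#' @param path output FASTQ path.
#' @export
writeSampleFastq <- function(reads, path) {
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = qual)
  invisible(path)
}
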