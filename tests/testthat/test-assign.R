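test_that("a read identical to its mature maps with zero deviation", {
  ref <- toyReference()
  idx <- buildIndex(ref)
  a <- assignRead("TAGCTAGCATCGGATCCGATCG", idx)
  expect_identical(a$mirna_id, "mirA")
  expect_identical(c(a$offset5, a$offset3), c(0L, 0L))
  expect_identical(c(a$subs, a$tail), c("", ""))
})

test_that("3' trimming and non-templated tails are recorded as such", {
  ref <- toyReference()
  idx <- buildIndex(ref)
  mat <- "TAGCTAGCATCGGATCCGATCG"
  trim2 <- substr(mat, 1, nchar(mat) - 2)
  a <- assignRead(trim2, idx)
  expect_identical(a$offset3, -2L)
  expect_identical(c(a$subs, a$tail), c("", ""))
  # hairpin continues "TT" after the mature, so "AA" cannot be templated
  b <- assignRead(paste0(mat, "AA"), idx)
  expect_identical(b$offset3, 2L)
  expect_identical(b$tail, "AA")
  expect_identical(b$subs, "")
  # a templated extension is preferred over a tail
  d <- assignRead(paste0(mat, "TT"), idx)
  expect_identical(d$offset3, 2L)
  expect_identical(d$tail, "")
})

test_that("ties between identical matures resolve to the lowest id", {
  m <- Biostrings::DNAStringSet(c(mirB = "TAGCTAGCATCGGATCCGATCG",
                                  mirA = "TAGCTAGCATCGGATCCGATCG"))
  h <- Biostrings::DNAStringSet(c(hpB = "AATAGCTAGCATCGGATCCGATCGTT",
                                  hpA = "GGTAGCTAGCATCGGATCCGATCGCC"))
  ref <- linkMatureToHairpin(m, h, c(mirB = "hpB", mirA = "hpA"))
  a <- assignRead("TAGCTAGCATCGGATCCGATCG", buildIndex(ref))
  expect_identical(a$mirna_id, "mirA")
})

test_that("assignment equals the brute-force oracle on random reads", {
  set.seed(42)
  cfg <- simConfig(seed = 61, n_mirnas = 100, n_shared_core = 10,
                   n_group_specific = 0)
  simref <- simulateReference(cfg)
  idx <- buildIndex(simref$reference)
  map <- matureMap(simref$reference)
  hp <- as.character(hairpinSeqs(simref$reference))[map$hairpin_id]
  params <- assignmentParams()
  # random perturbations of true matures plus fully random reads
  mk <- function() {
    if (runif(1) < 0.15) return(paste(sample(c("A", "C", "G", "T"), 21,
                                             replace = TRUE), collapse = ""))
    i <- sample.int(nrow(map), 1)
    s <- map$start[i] + sample(-4:4, 1)
    e <- map$end[i] + sample(-6:6, 1)
    s <- max(0, s)
    e <- min(nchar(hp[i]), e)
    if (e - s < 16) return(NULL)
    r <- substr(hp[i], s + 1, e)
    if (runif(1) < 0.5) {
      p <- sample.int(nchar(r), 1)
      substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (runif(1) < 0.3)
      r <- paste0(r, paste(sample(c("A", "T"), sample(1:4, 1),
                                  replace = TRUE), collapse = ""))
    r
  }
  reads <- character(0)
  while (length(reads) < 300) {
    r <- mk()
    if (!is.null(r)) reads <- c(reads, r)
  }
  got <- assignLibrary(reads, idx, params)$assignments
  for (i in seq_along(reads)) {
    o <- oracleAssign(reads[i], map$mature_id, hp, map$start, map$end,
                      params)
    if (is.null(o)) {
      expect_true(is.na(got$mirna_id[i]), label = reads[i])
    } else {
      expect_identical(
        list(got$mirna_id[i], got$offset5[i], got$offset3[i], got$subs[i],
             got$tail[i]),
        list(o$mirna_id, o$offset5, o$offset3, o$subs, o$tail),
        label = reads[i])
    }
  }
})

test_that("recorded offsets, substitutions and tail reconstruct the read", {
  set.seed(8)
  cfg <- smallSimConfig(seed = 55, reads_per_sample = 1500)
  ds <- simulateDataset(cfg)
  idx <- buildIndex(ds$reference)
  map <- matureMap(ds$reference)
  hp <- setNames(as.character(hairpinSeqs(ds$reference))[map$hairpin_id],
                 map$mature_id)
  s1 <- names(ds$reads$samples)[1]
  reads <- ds$reads$samples[[s1]]
  a <- assignLibrary(reads, idx)$assignments
  ok <- which(!is.na(a$mirna_id))
  i0 <- match(a$mirna_id[ok], map$mature_id)
  rec <- vapply(seq_along(ok), function(j) {
    k <- ok[j]
    reconstructRead(hp[[a$mirna_id[k]]], map$start[i0[j]], map$end[i0[j]],
                    a$offset5[k], a$offset3[k], a$subs[k], a$tail[k])
  }, "")
  expect_identical(rec, unname(as.character(reads))[ok])
})

test_that("assignments are invariant to reference ordering", {
  cfg <- simConfig(seed = 71, n_mirnas = 20, n_shared_core = 4,
                   n_group_specific = 0)
  simref <- simulateReference(cfg)
  ref <- simref$reference
  set.seed(1)
  perm <- sample(length(matureSeqs(ref)))
  refPerm <- linkMatureToHairpin(
    matureSeqs(ref)[perm], hairpinSeqs(ref)[perm],
    setNames(matureMap(ref)$hairpin_id, matureMap(ref)$mature_id))
  reads <- as.character(matureSeqs(ref))
  a1 <- assignLibrary(reads, buildIndex(ref))$assignments
  a2 <- assignLibrary(reads, buildIndex(refPerm))$assignments
  expect_identical(a1[-1], a2[-1])
})

test_that("library assignment conserves read counts and handles edge inputs", {
  ref <- toyReference()
  idx <- buildIndex(ref)
  empty <- assignLibrary(character(0), idx)
  expect_identical(unname(empty$counters), c(0L, 0L))
  expect_identical(nrow(empty$assignments), 0L)

  res <- assignLibrary(c(r1 = "TAGCTAGCATCGGATCCGATCG", r2 = "ACGTACGTACGT",
                         r3 = strrep("G", 22)), idx)
  expect_identical(sum(res$counters), 3L)
  expect_identical(nrow(res$assignments), 3L)
  expect_true(is.na(res$assignments$mirna_id[2]))  # short: UNASSIGNED
  expect_true(is.na(res$assignments$mirna_id[3]))
  expect_error(assignLibrary("ACGTNACGTACGTACGTACGT", idx), "invalid")
  expect_error(buildIndex(new("MirnaReference",
                              matures = Biostrings::DNAStringSet(),
                              hairpins = Biostrings::DNAStringSet(),
                              map = S4Vectors::DataFrame(
                                mature_id = character(0),
                                hairpin_id = character(0),
                                start = integer(0), end = integer(0)))),
               "empty")
})

test_that("simulated reads are recovered to their true source miRNA", {
  ds <- simulateDataset(smallSimConfig(seed = 37, reads_per_sample = 5000,
                                       sno_read_fraction = 0))
  idx <- buildIndex(ds$reference)
  s1 <- names(ds$reads$samples)[1]
  a <- assignLibrary(ds$reads$samples[[s1]], idx)
  tr <- ds$reads$truth[ds$reads$truth$sample_id == s1, ]
  expect_identical(a$assignments$read_id, tr$read_id)
  hit <- !is.na(a$assignments$mirna_id) &
    a$assignments$mirna_id == tr$source_id
  expect_gte(mean(hit), 0.99)
})

test_that("FASTA and FASTQ libraries load through the same entry point", {
  ds <- simulateDataset(smallSimConfig(seed = 12, reads_per_sample = 200))
  reads <- ds$reads$samples[[1]]
  fq <- withr::local_tempfile(fileext = ".fastq")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeSampleFastq(reads, fq)
  Biostrings::writeXStringSet(reads, fa)
  idx <- buildIndex(ds$reference)
  expect_identical(assignLibrary(fq, idx)$assignments,
                   assignLibrary(fa, idx)$assignments)
})
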