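test_that("reference simulation is deterministic and self-consistent", {
  cfg <- simConfig(seed = 5, n_mirnas = 5, n_shared_core = 2,
                   n_group_specific = 0, n_snornas = 8)
  a <- simulateReference(cfg)
  b <- simulateReference(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  Biostrings::writeXStringSet(matureSeqs(a$reference), f1)
  Biostrings::writeXStringSet(matureSeqs(b$reference), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_length(matureSeqs(a$reference), 5)
  expect_length(hairpinSeqs(a$reference), 5)
  map <- matureMap(a$reference)
  emb <- substr(as.character(hairpinSeqs(a$reference))[map$hairpin_id],
                map$start + 1, map$end)
  expect_identical(unname(emb),
                   unname(as.character(matureSeqs(a$reference))))
  expect_true(all(nchar(as.character(matureSeqs(a$reference))) %in% 20:23))
  expect_true(all(a$sno_annotation$box_class %in%
                    c("CD", "HACA", "SCARNA")))
  expect_true(all(a$sno_annotation$length >= 60 &
                    a$sno_annotation$length <= 300))
})

test_that("abundance profiles have the planted group structure", {
  for (seed in c(2, 31)) {
    cfg <- smallSimConfig(seed = seed)
    simref <- simulateReference(cfg)
    ab <- simulateAbundances(cfg, names(matureSeqs(simref$reference)))
    expect_equal(unname(colSums(ab)), rep(1, cfg$n_groups),
                 tolerance = 1e-12)
    role <- attr(ab, "role")
    spg <- attr(ab, "specific_group")
    for (g in colnames(ab)) {
      foreign <- !is.na(spg) & spg != g
      expect_true(all(ab[foreign, g] < 1e-4))   # absent elsewhere
      topk <- cfg$n_shared_core + cfg$n_group_specific
      topIds <- rownames(ab)[order(-ab[, g])][seq_len(topk)]
      expect_true(all(names(role)[role == "core"] %in% topIds))
      expect_true(all(names(spg)[!is.na(spg) & spg == g] %in% topIds))
    }
  }
})

test_that("degenerate variation parameters yield only canonical reads", {
  cfg <- simConfig(seed = 3, n_mirnas = 10, n_shared_core = 2,
                   n_group_specific = 0, n_groups = 2, n_replicates = 1,
                   reads_per_sample = 500, p_5p_shift = 0,
                   dist_3p_offset = c("0" = 1), sub_rate = 0, tail_rate = 0,
                   sno_read_fraction = 0)
  ds <- simulateDataset(cfg)
  expect_true(all(ds$reads$truth$true_class == "CANONICAL"))
})

test_that("read simulation is deterministic given the seed", {
  cfg <- smallSimConfig(seed = 77, reads_per_sample = 500)
  r1 <- simulateDataset(cfg)$reads
  r2 <- simulateDataset(cfg)$reads
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeSampleFastq(r1$samples[[1]], f1)
  writeSampleFastq(r2$samples[[1]], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("3' offset frequencies match the configured distribution", {
  cfg <- simConfig(seed = 19, n_mirnas = 20, n_shared_core = 4,
                   n_group_specific = 0, n_groups = 1, n_replicates = 1,
                   reads_per_sample = 10000, p_5p_shift = 0,
                   dist_3p_offset = c("-1" = 0.5, "0" = 0.5), sub_rate = 0,
                   tail_rate = 0, sno_read_fraction = 0)
  ds <- simulateDataset(cfg)
  frac <- mean(ds$reads$truth$offset3 != 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("truth classes agree with the classifier on every read", {
  ds <- simulateDataset(smallSimConfig(seed = 23))
  tr <- ds$reads$truth
  mir <- tr$true_class != "SNO_FRAGMENT"
  recls <- classifyVariant(tr$offset5[mir], tr$offset3[mir],
                           tr$substitutions[mir], tr$tail[mir])
  expect_identical(recls, tr$true_class[mir])
})

test_that("per-miRNA read fractions converge to configured abundances", {
  cfg <- simConfig(seed = 13, n_mirnas = 10, n_shared_core = 2,
                   n_group_specific = 0, n_groups = 1, n_replicates = 1,
                   reads_per_sample = 20000, sno_read_fraction = 0)
  ds <- simulateDataset(cfg)
  obs <- table(factor(ds$reads$truth$source_id,
                      levels = rownames(ds$abundances))) /
    nrow(ds$reads$truth)
  p <- ds$abundances[, 1]
  sd3 <- 3 * sqrt(p * (1 - p) / 20000)
  expect_true(all(abs(as.numeric(obs) - p) <= pmax(sd3, 1e-4)))
})

test_that("no simulated read is shorter than 16 nt", {
  ds <- simulateDataset(smallSimConfig(seed = 4, reads_per_sample = 2000))
  widths <- unlist(lapply(ds$reads$samples, Biostrings::width))
  expect_gte(min(widths), 16)
})

test_that("FASTQ output is 4-line Phred+33 with constant quality", {
  ds <- simulateDataset(smallSimConfig(seed = 9, reads_per_sample = 100))
  f <- withr::local_tempfile(fileext = ".fastq")
  writeSampleFastq(ds$reads$samples[[1]], f)
  lines <- readLines(f)
  expect_identical(length(lines), 400L)
  expect_true(all(startsWith(lines[seq(1, 400, 4)], "@")))
  expect_true(all(grepl("^I+$", lines[seq(4, 400, 4)])))
  back <- Biostrings::readDNAStringSet(f, format = "fastq")
  expect_identical(as.character(back),
                   as.character(ds$reads$samples[[1]]))
})

test_that("configuration validation rejects inconsistent parameters", {
  expect_error(simConfig(dist_3p_offset = c("0" = 0.5)), "sum to 1")
  expect_error(simConfig(n_mirnas = 10, n_shared_core = 8,
                         n_group_specific = 1, n_groups = 4), "<=")
  expect_error(simConfig(p_5p_shift = 1.2), "\\[0, 1\\]")
  expect_error(simConfig(sno_fragment_length_range = c(10, 40)), "16")
})

test_that("expected isomiR fraction matches a direct enumeration", {
  cfg <- simConfig(p_5p_shift = 0.1, dist_3p_offset = c("0" = 0.8,
                                                        "1" = 0.2),
                   sub_rate = 0)
  expect_equal(expectedIsomirFraction(cfg), 1 - 0.9 * 0.8)
  cfg2 <- simConfig(sub_rate = 0.01)
  expect_equal(expectedIsomirFraction(cfg2),
               1 - (1 - cfg2$p_5p_shift) * 0.845 * mean(0.99^(20:23)))
})
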