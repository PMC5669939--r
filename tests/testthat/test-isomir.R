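test_that("variant classification matches the six-class definitions", {
  expect_identical(classifyVariant(0L, 0L, "", ""), "CANONICAL")
  expect_identical(classifyVariant(0L, -2L, "", ""), "THREE_PRIME_ONLY")
  expect_identical(classifyVariant(0L, 2L, "", "AA"), "THREE_PRIME_ONLY")
  expect_identical(classifyVariant(-1L, 0L, "", ""), "FIVE_PRIME_ONLY")
  expect_identical(classifyVariant(1L, 1L, "10:C>T", ""),
                   "SUBSTITUTION_AND_END")
  expect_identical(classifyVariant(0L, 0L, "5:A>G", ""),
                   "SUBSTITUTION_ONLY")
  expect_identical(classifyVariant(-1L, 1L, "", ""), "BOTH_ENDS")
})

test_that("the six classes partition enumerated key space", {
  grid <- expand.grid(o5 = -1:1, o3 = -1:1, subs = c("", "5:A>G"),
                      tail = c("", "A"), stringsAsFactors = FALSE)
  cls <- classifyVariant(grid$o5, grid$o3, grid$subs, grid$tail)
  expect_true(all(cls %in% c("CANONICAL", "FIVE_PRIME_ONLY",
                             "THREE_PRIME_ONLY", "BOTH_ENDS",
                             "SUBSTITUTION_ONLY", "SUBSTITUTION_AND_END")))
  expect_identical(length(unique(cls)), 6L)
  expect_identical(sum(cls == "CANONICAL"), 1L)  # only the null key
})

test_that("the naming grammar renders keys as specified", {
  expect_identical(nameIsomir("mir-1-5p", 0L, 0L, "", ""), "mir-1-5p")
  expect_identical(nameIsomir("mir-1-5p", 0L, -2L, "", ""),
                   "mir-1-5p|5e0|3e-2|s:-|t:-")
  expect_identical(nameIsomir("mir-1-5p", 1L, 2L, "10:C>T", "AA"),
                   "mir-1-5p|5e+1|3e+2|s:10C>T|t:AA")
  expect_identical(nameIsomir("m", 0L, 0L, "3:G>A;7:T>C", ""),
                   "m|5e0|3e0|s:3G>A;7T>C|t:-")
})

test_that("name parsing inverts the grammar and rejects malformed names", {
  k <- parseIsomirName("mir-1-5p")
  expect_identical(k$mirna_id, "mir-1-5p")
  expect_identical(c(k$offset5, k$offset3), c(0L, 0L))
  expect_error(parseIsomirName("mir-1-5p|bogus"), "malformed")
  expect_error(parseIsomirName("m|5e0|3e0|s:10C-T|t:-"), "malformed")
  expect_error(parseIsomirName("m|5e1|3e0|s:-|t:-"), "malformed")  # bad sign
  expect_error(parseIsomirName("m|5e0|3e0|s:-|t:-"), "canonical")
})

test_that("name/parse round trip is the identity over random keys", {
  set.seed(99)
  n <- 1000
  bases <- c("A", "C", "G", "T")
  keys <- data.frame(
    mirna_id = sprintf("mir-%d-5p", sample.int(500, n, replace = TRUE)),
    offset5 = sample(-3:3, n, replace = TRUE),
    offset3 = sample(-5:5, n, replace = TRUE),
    subs = vapply(seq_len(n), function(i) {
      k <- sample(0:2, 1)
      if (k == 0) return("")
      pos <- sort(sample(0:21, k))
      paste(vapply(pos, function(p) {
        rb <- sample(bases, 1)
        sprintf("%d:%s>%s", p, rb, sample(setdiff(bases, rb), 1))
      }, ""), collapse = ";")
    }, ""),
    tail = vapply(seq_len(n), function(i) {
      t <- sample(0:2, 1)
      paste(sample(c("A", "T"), t, replace = TRUE), collapse = "")
    }, ""),
    stringsAsFactors = FALSE)
  back <- parseIsomirName(nameIsomir(keys$mirna_id, keys$offset5,
                                     keys$offset3, keys$subs, keys$tail))
  canonical <- keys$offset5 == 0 & keys$offset3 == 0 &
    keys$subs == "" & keys$tail == ""
  expect_identical(back$mirna_id, keys$mirna_id)
  expect_identical(back$offset5[!canonical], keys$offset5[!canonical])
  expect_identical(back$offset3[!canonical], keys$offset3[!canonical])
  expect_identical(back$subs[!canonical], keys$subs[!canonical])
  expect_identical(back$tail[!canonical], keys$tail[!canonical])
})

mkAssign <- function(sample_id, mirna_id, offset5, offset3, subs = "",
                     tail = "", times = 1) {
  df <- data.frame(sample_id = sample_id, mirna_id = mirna_id,
                   offset5 = offset5, offset3 = offset3, subs = subs,
                   tail = tail, stringsAsFactors = FALSE)
  df[rep(seq_len(nrow(df)), times), , drop = FALSE]
}

test_that("isomiR count tables collapse distinct keys per sample", {
  a <- rbind(mkAssign("s1", "mirA", 0L, 0L, times = 4),
             mkAssign("s1", "mirA", 0L, -2L, times = 3),
             mkAssign("s2", "mirA", 0L, -2L, times = 1),
             mkAssign("s1", "mirB", 1L, 0L, times = 2))
  tab <- isomirCountTable(a)
  expect_identical(nrow(tab), 3L)
  canonical <- tab[tab$name == "mirA", ]
  expect_identical(canonical$class, "CANONICAL")
  expect_identical(canonical$s1, 4L)
  trimmed <- tab[tab$name == "mirA|5e0|3e-2|s:-|t:-", ]
  expect_identical(c(trimmed$s1, trimmed$s2), c(3L, 1L))
})

test_that("variant histograms are percentages over isomiR reads", {
  a <- rbind(mkAssign("s1", "mirA", 0L, -1L, times = 3),    # 3' only
             mkAssign("s1", "mirA", -1L, 1L, times = 1),    # both ends
             mkAssign("s1", "mirA", 0L, 0L, times = 6),     # canonical
             mkAssign("s1", "mirB", 0L, 0L, times = 5))     # canonical only
  h <- variantClassHistogram(a)
  expect_setequal(unique(h$mirna_id), "mirA")  # mirB has no isomiR reads
  expect_equal(h$percent[h$class == "THREE_PRIME_ONLY"], 75)
  expect_equal(h$percent[h$class == "BOTH_ENDS"], 25)
  expect_equal(sum(h$percent), 100)

  hAll <- variantClassHistogram(a, denominator = "all")
  expect_setequal(unique(hAll$mirna_id), c("mirA", "mirB"))
  expect_equal(hAll$percent[hAll$mirna_id == "mirA" &
                              hAll$class == "CANONICAL"], 60)
  sums <- tapply(hAll$percent, hAll$mirna_id, sum)
  expect_equal(as.numeric(sums), c(100, 100))
})

test_that("histogram percentages sum to 100 on simulated data", {
  ds <- simulateDataset(smallSimConfig(seed = 29, reads_per_sample = 3000))
  idx <- buildIndex(ds$reference)
  s1 <- names(ds$reads$samples)[1]
  a <- cbind(sample_id = s1,
             assignLibrary(ds$reads$samples[[s1]], idx)$assignments,
             stringsAsFactors = FALSE)
  h <- variantClassHistogram(a)
  sums <- tapply(h$percent, h$mirna_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})
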