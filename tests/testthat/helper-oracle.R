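# Independent oracles and shared fixtures for the suite.

# Brute-force read assignment: enumerates every (mature, 5' offset,
# tail split) explicitly and scores placements exactly as specified:
# lexicographic (n_subs, tail_len, |offset5| + |offset3|), ties by ascending
# mature id then ascending offset5. Pure R, independent of the package's
# compiled path.
oracleAssign <- function(read, ids, hairpins, mstart, mend,
                         params = assignmentParams()) {
  read <- unname(read)
  L <- nchar(read)
  if (L < params$minReadLen) return(NULL)
  rb <- strsplit(read, "")[[1]]
  best <- NULL
  better <- function(a, b) {
    if (a$nsub != b$nsub) return(a$nsub < b$nsub)
    if (a$t != b$t) return(a$t < b$t)
    (abs(a$offset5) + abs(a$offset3)) < (abs(b$offset5) + abs(b$offset3))
  }
  ids <- unname(ids); hairpins <- unname(hairpins)
  mstart <- unname(mstart); mend <- unname(mend)
  for (m in order(ids)) {
    h <- strsplit(hairpins[m], "")[[1]]
    mlen <- mend[m] - mstart[m]
    for (o5 in seq(-params$max5pShift, params$max5pShift)) {
      o3 <- o5 + L - mlen
      if (abs(o3) > params$max3pShift) next
      pstart <- mstart[m] + o5
      if (pstart < 0) next
      for (t in 0:min(params$maxTail, max(o3, 0L))) {
        i <- seq_len(L - t)
        q <- pstart + i                       # 1-based hairpin positions
        if (length(i) > 0 && max(q) > length(h)) next
        mis <- h[q] != rb[i]
        inBody <- (q - 1L) < mend[m]
        if (any(mis & !inBody)) next          # only the tail may mismatch
        nsub <- sum(mis & inBody)
        if (nsub > params$maxSubs) next
        w <- which(mis & inBody)
        cand <- list(mirna_id = ids[m], offset5 = o5, offset3 = o3,
                     nsub = nsub, t = t,
                     subs = paste(sprintf("%d:%s>%s", q[w] - 1L - mstart[m],
                                          h[q[w]], rb[w]), collapse = ";"),
                     tail = if (t > 0) substr(read, L - t + 1L, L) else "")
        if (is.null(best) || better(cand, best)) best <- cand
      }
    }
  }
  best
}

# Rebuild a read from hairpin context + recorded offsets/substitutions/tail.
reconstructRead <- function(hairpin, mstart, mend, offset5, offset3,
                            subs, tail) {
  templ <- substr(hairpin, mstart + offset5 + 1L,
                  mend + offset3 - nchar(tail))
  if (nzchar(subs)) {
    for (ent in strsplit(subs, ";", fixed = TRUE)[[1L]]) {
      m <- regmatches(ent, regexec("^(-?[0-9]+):([ACGTN])>([ACGT])$",
                                   ent))[[1L]]
      ri <- as.integer(m[2L]) - offset5 + 1L
      substr(templ, ri, ri) <- m[4L]
    }
  }
  paste0(templ, tail)
}

# Naive unweighted average-linkage (UPGMA) agglomeration over an explicit
# distance matrix; returns the cophenetic distance matrix.
oracleUpgmaCophenetic <- function(d) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n)
  dist0 <- d
  cluDist <- function(a, b) {
    mean(dist0[members[[a]], members[[b]]])
  }
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    bestPair <- NULL; bestD <- Inf
    for (i in idx) for (j in idx) if (i < j) {
      dd <- cluDist(i, j)
      if (dd < bestD - 1e-12) { bestD <- dd; bestPair <- c(i, j) }
    }
    a <- bestPair[1L]; b <- bestPair[2L]
    coph[members[[a]], members[[b]]] <- bestD
    coph[members[[b]], members[[a]]] <- bestD
    members[[a]] <- c(members[[a]], members[[b]])
    active[b] <- FALSE
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# Tiny hand-built two-miRNA reference used across assignment tests.
toyReference <- function() {
  mat <- Biostrings::DNAStringSet(c(
    mirA = "TAGCTAGCATCGGATCCGATCG",
    mirB = "GGCATCGATTACGCTAGGCAAT"))
  hp <- Biostrings::DNAStringSet(c(
    hpA = "ACGTACGTTAGCTAGCATCGGATCCGATCGTTAGCAACGT",
    hpB = "TTACGGGCATCGATTACGCTAGGCAATCCGGTAACC"))
  linkMatureToHairpin(mat, hp, c(mirA = "hpA", mirB = "hpB"))
}

# Small simulation configuration for fast end-to-end tests.
smallSimConfig <- function(seed = 101L, ...) {
  defaults <- list(seed = seed, n_mirnas = 40L, n_shared_core = 8L,
                   n_group_specific = 2L, reads_per_sample = 4000L,
                   n_snornas = 30L, sno_reads_per_sample = 4000L)
  do.call(simConfig, modifyList(defaults, list(...)))
}
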